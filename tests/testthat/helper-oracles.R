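# Independent oracles and small fixture builders used across the suite.

# Naive pairwise JT statistic built directly from the kernel definition
# via outer products (independent of the package's block-sum pass).
jt_u_naive <- function(x, g, w = rep(1, length(x))) {
  sum(outer(g, g, "<") *
        (outer(x, x, "<") + 0.5 * outer(x, x, "==")) *
        outer(w, w))
}

# All permutations of 1..n by iterative insertion (independent of the
# package's recursive enumerator).
perms_naive <- function(n) {
  out <- matrix(1L, 1, 1)
  for (m in 2:n) {
    grown <- vector("list", m)
    for (pos in 1:m) {
      left <- if (pos > 1) out[, 1:(pos - 1), drop = FALSE] else NULL
      right <- if (pos <= m - 1) out[, pos:(m - 1), drop = FALSE] else NULL
      grown[[pos]] <- cbind(left, m, right)
    }
    out <- do.call(rbind, grown)
  }
  out
}

# Exact two-sided p by brute-force enumeration of label assignments.
jt_exact_p_naive <- function(x, g, w = rep(1, length(x))) {
  pm <- perms_naive(length(x))
  u_all <- apply(pm, 1, function(idx) jt_u_naive(x, g[idx], w[idx]))
  u <- jt_u_naive(x, g, w)
  m <- mean(u_all)
  mean(abs(u_all - m) >= abs(u - m) - 1e-9)
}

# Brute-force BH step-up: largest i with p_(i) <= i q / m, reject all
# p at or below that order statistic.
bh_reject_naive <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

# Minimal catalog in the schema aggregate_baskets() expects: one or
# more items with explicit energy density and all-zero nutrients
# (item NRFI 0) unless overridden.
toy_catalog <- function(item_id, group, energy_density,
                        nutrients = NULL) {
  cat <- tibble::tibble(item_id = item_id, group = group,
                        energy_density = energy_density,
                        price_multiplier = 1)
  for (nm in nutrient_names()) {
    cat[[nm]] <- if (is.null(nutrients)) 0 else nutrients[[nm]]
  }
  cat
}

toy_participants <- function(n, pia = rep(3L, n), loyalty = rep(90, n),
                             education = rep(2L, n),
                             sex = rep("female", n)) {
  tibble::tibble(id = sprintf("T%03d", seq_len(n)), sex = sex, age = 40L,
                 education = education, income_category = 4L,
                 household_size = 2L, pia = as.integer(pia),
                 loyalty_pct = loyalty)
}
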