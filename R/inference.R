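# Ordered-alternative trend inference: the Jonckheere-Terpstra test
# (unweighted asymptotic, exact enumeration, and weighted Monte-Carlo
# permutation), inverse-probability weights from a multinomial
# propensity model, Benjamini-Hochberg FDR control, the median-variance
# effect size, and Spearman price correlations.

jt_prepare <- function(values, groups, weights) {
  values <- as.numeric(values)
  if (anyNA(values)) {
    stop("values contain missing entries; filter them before testing",
         call. = FALSE)
  }
  lev <- sort(unique(groups))
  if (length(lev) < 2) {
    stop("at least 2 distinct ordered groups are required", call. = FALSE)
  }
  g <- match(groups, lev)
  if (is.null(weights)) {
    w <- rep(1, length(values))
    weighted <- FALSE
  } else {
    w <- as.numeric(weights)
    if (length(w) != length(values) || anyNA(w) || any(w <= 0)) {
      stop("weights must be positive and aligned with values",
           call. = FALSE)
    }
    weighted <- diff(range(w)) > 1e-12
    if (!weighted) w <- rep(1, length(values))  # constant weights drop out
  }
  list(x = values, g = as.integer(g), w = w, k = length(lev),
       weighted = weighted)
}

# Null moments of the classical (unit-weight) JT statistic with the
# standard tie correction.
jt_null_moments <- function(x, g, k) {
  n_i <- tabulate(g, nbins = k)
  N <- length(x)
  t_j <- as.numeric(table(x))
  mean0 <- (N^2 - sum(n_i^2)) / 4
  A <- N * (N - 1) * (2 * N + 5) -
    sum(n_i * (n_i - 1) * (2 * n_i + 5)) -
    sum(t_j * (t_j - 1) * (2 * t_j + 5))
  B <- sum(n_i * (n_i - 1) * (n_i - 2)) * sum(t_j * (t_j - 1) * (t_j - 2))
  C <- sum(n_i * (n_i - 1)) * sum(t_j * (t_j - 1))
  var0 <- A / 72 + B / (36 * N * (N - 1) * (N - 2)) +
    C / (8 * N * (N - 1))
  list(mean0 = mean0, var0 = var0)
}

#' Jonckheere-Terpstra statistic
#'
#' Pairwise-concordance statistic for a monotone trend across ordered
#' groups: `U` sums, over all observation pairs whose groups are
#' strictly ordered, a kernel of 1 when the lower-group value is
#' smaller, 0.5 on ties, 0 otherwise; with weights, each pair
#' contributes the product of its observation weights. With unit
#' weights this is the classical tie-corrected JT statistic, and the
#' closed-form null mean and (tie-corrected) variance are attached.
#'
#' @param values Numeric outcome, no missing values.
#' @param groups Ordinal group labels (any orderable type).
#' @param weights Optional positive observation weights; constant
#'   weights are equivalent to no weights.
#' @return A list of class `jt_result` with `u`, `mean0`, `var0`, `z`
#'   (NA for non-constant weights, whose null moments come from
#'   permutation in [jt_test()]), `n`, `k`, `weighted`.
#' @export
jt_statistic <- function(values, groups, weights = NULL) {
  d <- jt_prepare(values, groups, weights)
  u <- jt_u_cpp(d$x, d$g, d$w, d$k)
  if (!d$weighted) {
    m <- jt_null_moments(d$x, d$g, d$k)
    z <- if (m$var0 > 1e-12) {
      (u - m$mean0) / sqrt(m$var0)
    } else if (abs(u - m$mean0) < 1e-9) 0 else NA_real_  # degenerate null
  } else {
    m <- list(mean0 = NA_real_, var0 = NA_real_)
    z <- NA_real_
  }
  structure(list(u = u, mean0 = m$mean0, var0 = m$var0, z = z,
                 n = length(d$x), k = d$k, weighted = d$weighted),
            class = "jt_result")
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Two-sided Jonckheere-Terpstra trend test
#'
#' Three inference routes: `"asymptotic"` (unit weights only) uses the
#' normal approximation with the tie-corrected null variance;
#' `"permutation"` draws `n_perm` label permutations (weights travel
#' with their observations) and reports the add-one-corrected
#' two-sided tail proportion of `|U - mean0|`; `"exact"` enumerates
#' every label assignment (total n at most 9) and reports the exact
#' two-sided tail probability.
#'
#' @inheritParams jt_statistic
#' @param method `"asymptotic"`, `"permutation"` or `"exact"`.
#' @param strata Optional covariate stratum labels for the permutation
#'   route. When given, (label, weight) pairs are permuted within
#'   strata only, which tests the conditional null of no trend given
#'   the stratifying covariates; this is the appropriate reference
#'   distribution for inverse-probability weights estimated from those
#'   covariates, whereas unrestricted permutation is anti-conservative
#'   when weights and outcome share a confounder.
#' @param n_perm Number of Monte-Carlo permutations (at least 100).
#' @param seed Optional integer seed for the permutation draw.
#' @return A list of class `jt_result` with `u`, `mean0`, `var0`, `z`,
#'   `p`, `method`, and `n_perm`/`seed` for the permutation route.
#' @export
jt_test <- function(values, groups, weights = NULL,
                    method = c("asymptotic", "permutation", "exact"),
                    strata = NULL, n_perm = 10000, seed = NULL) {
  method <- match.arg(method)
  d <- jt_prepare(values, groups, weights)
  if (method == "asymptotic") {
    if (d$weighted) {
      stop("asymptotic null moments are defined for unit weights; use ",
           "method = \"permutation\" for weighted tests", call. = FALSE)
    }
    res <- jt_statistic(values, groups, weights)
    res$p <- if (is.na(res$z)) NA_real_ else 2 * pnorm(-abs(res$z))
    res$p <- min(res$p, 1)
    res$method <- "asymptotic"
    return(res)
  }
  if (method == "exact") {
    n <- length(d$x)
    if (n > 9) stop("exact enumeration supports total n <= 9", call. = FALSE)
    perms <- all_perms(n)
    u_all <- apply(perms, 1, function(idx)
      jt_u_cpp(d$x, d$g[idx], d$w[idx], d$k))
    u <- jt_u_cpp(d$x, d$g, d$w, d$k)
    m <- mean(u_all)
    p <- mean(abs(u_all - m) >= abs(u - m) - 1e-9)
    return(structure(list(u = u, mean0 = m, var0 = var(u_all) * (length(u_all) - 1) / length(u_all),
                          z = if (sd(u_all) > 0) (u - m) / sd(u_all) else NA_real_,
                          p = p, n = n, k = d$k, weighted = d$weighted,
                          method = "exact"), class = "jt_result"))
  }
  # Monte-Carlo permutation
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  if (is.null(strata)) {
    s <- rep(1L, length(d$x))
  } else {
    if (length(strata) != length(d$x)) {
      stop("strata must align with values", call. = FALSE)
    }
    s <- as.integer(factor(strata))
  }
  run <- function() jt_perm_cpp(d$x, d$g, d$w, d$k, as.integer(n_perm), s)
  pr <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  u <- pr$u
  u_perm <- pr$u_perm
  m <- if (d$weighted || !is.null(strata)) mean(u_perm)
       else jt_null_moments(d$x, d$g, d$k)$mean0
  s <- sd(u_perm)
  r <- sum(abs(u_perm - m) >= abs(u - m) - 1e-9)
  structure(list(u = u, mean0 = m, var0 = s^2,
                 z = if (s > 0) (u - m) / s else NA_real_,
                 p = (r + 1) / (n_perm + 1),
                 n = length(d$x), k = d$k, weighted = d$weighted,
                 method = "permutation", n_perm = as.integer(n_perm),
                 seed = seed),
            class = "jt_result")
}

#' @export
print.jt_result <- function(x, ...) {
  cat("Jonckheere-Terpstra trend test (", x$method %||% "statistic",
      if (isTRUE(x$weighted)) ", weighted" else "", ")\n",
      "U = ", format(x$u), ", z = ", format(x$z),
      if (!is.null(x$p)) paste0(", two-sided p = ", format(x$p)) else "",
      "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inverse-probability weights from a multinomial propensity model
#'
#' Estimates the probability of each participant's observed PIA level
#' given education (categorical 1-4) and sex, and returns the inverse
#' probabilities as weights. The default `"saturated"` model is the
#' cell-proportion MLE over the education-by-sex strata; the
#' `"additive"` alternative fits a main-effects multinomial logit.
#' Optional stabilization multiplies each weight by the marginal
#' proportion of the participant's PIA level.
#'
#' @param participants Tibble with `id`, `pia` (1-5), `education`,
#'   `sex`.
#' @param model `"saturated"` or `"additive"`.
#' @param stabilize Multiply weights by the marginal level
#'   probabilities.
#' @param continuity Add a pseudo-count to the cells of any stratum
#'   with an empty PIA level (with a warning); without it such strata
#'   would carry unusable zero probabilities for unobserved levels.
#' @param pseudo Pseudo-count used by the continuity correction.
#' @return A list of class `ipw_model` with `weights` (tibble `id`,
#'   `pia`, `prob`, `weight`), `model`, `stabilize`.
#' @export
fit_ipw_weights <- function(participants,
                            model = c("saturated", "additive"),
                            stabilize = FALSE, continuity = TRUE,
                            pseudo = 0.5) {
  model <- match.arg(model)
  p <- participants
  if (!all(p$pia %in% 1:5)) {
    stop("IPW requires PIA levels 1-5 only; filter level 6 first",
         call. = FALSE)
  }
  levels_present <- sort(unique(p$pia))
  if (model == "saturated") {
    stratum <- paste(p$education, p$sex, sep = ":")
    counts <- table(stratum, factor(p$pia, levels = levels_present))
    zero_strata <- rownames(counts)[apply(counts == 0, 1, any)]
    cm <- matrix(as.numeric(counts), nrow = nrow(counts),
                 dimnames = dimnames(counts))
    if (length(zero_strata)) {
      warning("stratum/level cell(s) with zero observations in: ",
              paste(zero_strata, collapse = ", "),
              if (continuity) " - applying pseudo-count correction" else "",
              call. = FALSE)
      if (continuity) {
        cm[zero_strata, ] <- cm[zero_strata, , drop = FALSE] + pseudo
      }
    }
    probs_m <- cm / rowSums(cm)
    prob <- probs_m[cbind(stratum, as.character(p$pia))]
  } else {
    fit <- nnet::multinom(
      factor(pia, levels = levels_present) ~ factor(education) + factor(sex),
      data = p, trace = FALSE)
    fitted_p <- stats::fitted(fit)
    if (length(levels_present) == 2) {
      fitted_p <- cbind(1 - fitted_p, fitted_p)
      colnames(fitted_p) <- as.character(levels_present)
    }
    prob <- fitted_p[cbind(seq_len(nrow(p)), match(as.character(p$pia),
                                                   colnames(fitted_p)))]
  }
  if (any(prob <= 0)) {
    stop("estimated propensity of 0; enable the continuity correction",
         call. = FALSE)
  }
  weight <- 1 / prob
  if (stabilize) {
    marg <- as.numeric(table(factor(p$pia, levels = levels_present))) /
      nrow(p)
    weight <- weight * marg[match(p$pia, levels_present)]
  }
  structure(list(weights = tibble::tibble(
    id = p$id, pia = p$pia,
    stratum = paste(p$education, p$sex, sep = ":"),
    prob = prob, weight = weight),
    model = model, stabilize = stabilize),
    class = "ipw_model")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values with rejection flags at FDR level `q`.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Tibble with `p`, `p_bh`, `reject`.
#' @export
bh_adjust <- function(p_values, q = 0.05) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p_bh <- p.adjust(p_values, method = "BH")
  tibble::tibble(p = p_values, p_bh = p_bh, reject = p_bh <= q)
}

#' Median-variance effect size per food group
#'
#' Relates each group's variability of level medians across PIA levels
#' to the overall variability of all group-by-level medians:
#' `ES_g = 100 * SS_within_g / SS_total`, where `SS_within_g` sums the
#' squared deviations of the group's level medians from their own
#' mean, and `SS_total` sums squared deviations of every cell median
#' from the grand mean. Values are percentages in `[0, 100]`.
#'
#' @param median_matrix A [median_by_pia()] result (columns `group`,
#'   `level`, `value`).
#' @return Tibble `group`, `effect_size_pct`.
#' @export
effect_size <- function(median_matrix) {
  mm <- median_matrix[!is.na(median_matrix$value), ]
  ss_total <- sum((mm$value - mean(mm$value))^2)
  out <- mm |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(ss_within = sum((.data$value - mean(.data$value))^2),
                     .groups = "drop")
  if (ss_total == 0) {
    warning("all cell medians identical: effect size undefined",
            call. = FALSE)
    return(tibble::tibble(group = out$group, effect_size_pct = NA_real_))
  }
  tibble::tibble(group = out$group,
                 effect_size_pct = 100 * out$ss_within / ss_total)
}

spearman_or_na <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) {
    warning("fewer than 3 complete pairs: correlation missing",
            call. = FALSE)
    return(list(n = sum(ok), rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
  list(n = sum(ok), rho = unname(ct$estimate), p = ct$p.value)
}

#' Spearman correlations of price per kg and price per MJ
#'
#' Within each group, correlates the two unit prices over participants;
#' across groups, correlates the group-level median prices (one pair
#' per food group). Ties use average ranks.
#'
#' @param summaries Basket summaries with both prices.
#' @return A list with `within` (tibble `group`, `n`, `rho`, `p`) and
#'   `across` (one-row tibble `n`, `rho`, `p`).
#' @export
price_correlations <- function(summaries) {
  within <- summaries |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      r <- spearman_or_na(d$price_per_kg, d$price_per_mj)
      tibble::tibble(n = r$n, rho = r$rho, p = r$p)
    }) |>
    dplyr::ungroup()
  med <- summaries |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(m_kg = median(.data$price_per_kg, na.rm = TRUE),
                     m_mj = median(.data$price_per_mj, na.rm = TRUE),
                     .groups = "drop")
  ac <- spearman_or_na(med$m_kg, med$m_mj)
  list(within = within,
       across = tibble::tibble(n = ac$n, rho = ac$rho, p = ac$p))
}

# participant-level outcome vectors per group: shares are zero-filled
# for non-purchasers (a true observed share), prices and NRFI are
# defined for purchasers only
outcome_values <- function(summaries, participants, outcome, group) {
  zero_fill <- outcome %in% c("energy_share", "expenditure_share")
  obs <- summaries[summaries$group == group,
                   c("participant_id", outcome)]
  names(obs) <- c("id", "value")
  d <- dplyr::left_join(participants[, c("id", "pia")], obs, by = "id")
  if (zero_fill) {
    d$value <- dplyr::coalesce(d$value, 0)
  } else {
    d <- d[!is.na(d$value), , drop = FALSE]
  }
  d
}

#' Run the full trend analysis
#'
#' For every retained food group and outcome, runs the unweighted
#' asymptotic JT test and the inverse-probability-weighted JT test
#' (Monte-Carlo permutation null), applies Benjamini-Hochberg FDR
#' control to the IPW p-values within each outcome family (one family
#' per outcome column by default, or one pooled family), and attaches
#' the median-variance effect sizes.
#'
#' @param summaries Basket summaries with shares (included cohort).
#' @param participants Included participants (PIA 1-5).
#' @param groups Food groups to test (default: all in `summaries`).
#' @param outcomes Outcome columns to test.
#' @param ipw An [fit_ipw_weights()] result, or `NULL` to fit the
#'   saturated default.
#' @param n_perm Permutations for the weighted null (default 2000).
#' @param seed Base seed; each group-by-outcome test derives its own.
#' @param q FDR level.
#' @param bh_family `"per_outcome"` or `"pooled"`.
#' @return Tibble with one row per group and outcome: `u`, `z`, `p`
#'   (unweighted), `u_w`, `z_w`, `p_w` (IPW), `p_bh`, `significant`,
#'   `effect_size_pct`, `n`, `n_perm`, `seed`.
#' @export
run_trend_analysis <- function(summaries, participants,
                               groups = sort(unique(summaries$group)),
                               outcomes = c("energy_share",
                                            "expenditure_share",
                                            "price_per_kg",
                                            "price_per_mj", "nrfi"),
                               ipw = NULL, n_perm = 2000, seed = 1L,
                               q = 0.05,
                               bh_family = c("per_outcome", "pooled")) {
  bh_family <- match.arg(bh_family)
  if (is.null(ipw)) ipw <- fit_ipw_weights(participants)
  wtab <- ipw$weights[, c("id", "stratum", "weight")]
  rows <- list()
  idx <- 0L
  for (outcome in outcomes) {
    es <- effect_size(median_by_pia(summaries, participants, outcome,
                                    groups = groups))
    for (group in groups) {
      idx <- idx + 1L
      d <- outcome_values(summaries, participants, outcome, group)
      d <- dplyr::inner_join(d, wtab, by = "id")
      test_seed <- as.integer(seed) + idx
      unw <- jt_test(d$value, d$pia, method = "asymptotic")
      wgt <- jt_test(d$value, d$pia, weights = d$weight,
                     method = "permutation", strata = d$stratum,
                     n_perm = n_perm, seed = test_seed)
      rows[[idx]] <- tibble::tibble(
        group = group, outcome = outcome,
        u = unw$u, z = unw$z, p = unw$p,
        u_w = wgt$u, z_w = wgt$z, p_w = wgt$p,
        effect_size_pct =
          es$effect_size_pct[match(group, es$group)],
        n = unw$n, n_perm = as.integer(n_perm), seed = test_seed)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (bh_family == "per_outcome") {
    out <- out |>
      dplyr::group_by(.data$outcome) |>
      dplyr::mutate(p_bh = bh_adjust(.data$p_w, q)$p_bh) |>
      dplyr::ungroup()
  } else {
    out$p_bh <- bh_adjust(out$p_w, q)$p_bh
  }
  out$significant <- out$p_bh <= q
  dplyr::relocate(out, "p_bh", "significant", .after = "p_w")
}
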