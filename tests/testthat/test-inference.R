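# Jonckheere-Terpstra machinery against enumeration oracles, IPW
# weights, BH adjustment, effect sizes, and Spearman correlations.

test_that("U matches hand-enumerated pairwise counts", {
  expect_equal(jt_statistic(c(1, 2, 3, 4), c(1, 1, 2, 2))$u, 4)
  expect_equal(jt_statistic(c(10, 20, 30), c(1, 2, 3))$u, 3)
  # all values tied: U equals half the cross-pair count (the null mean)
  r <- jt_statistic(rep(7, 6), c(1, 1, 2, 2, 3, 3))
  expect_equal(r$u, 0.5 * (4 + 4 + 4))
  expect_equal(r$u, r$mean0)
  expect_equal(r$z, 0)
})

test_that("exact enumeration reproduces hand-computed two-sided p", {
  expect_equal(jt_test(c(1, 2, 3, 4), c(1, 1, 2, 2), method = "exact")$p,
               1 / 3)
  expect_equal(jt_test(c(10, 20, 30), c(1, 2, 3), method = "exact")$p,
               1 / 3)
})

test_that("implementation agrees with independent oracles for n <= 8", {
  set.seed(77)
  for (i in 1:12) {
    n <- sample(4:8, 1)
    g <- sort(sample(1:3, n, replace = TRUE))
    if (length(unique(g)) < 2) g[1] <- 0L
    x <- sample(1:4, n, replace = TRUE)  # ties likely
    expect_equal(jt_statistic(x, g)$u, jt_u_naive(x, g))
    expect_equal(jt_test(x, g, method = "exact")$p, jt_exact_p_naive(x, g))
    # weighted statistic against the naive kernel sum
    w <- runif(n, 0.5, 3)
    expect_equal(jt_statistic(x, g, weights = w)$u, jt_u_naive(x, g, w))
  }
})

test_that("closed-form tie-corrected null moments match enumeration", {
  set.seed(12)
  for (i in 1:6) {
    n <- sample(5:8, 1)
    g <- sort(sample(1:3, n, replace = TRUE))
    if (length(unique(g)) < 2) g[1] <- 0L
    x <- sample(1:3, n, replace = TRUE)
    ex <- jt_test(x, g, method = "exact")
    st <- jt_statistic(x, g)
    expect_equal(st$mean0, ex$mean0)
    expect_equal(st$var0, ex$var0)
  }
})

test_that("permutation p converges to the exact p", {
  x <- c(3, 1, 4, 1, 5, 9, 2)
  g <- c(1, 1, 2, 2, 2, 3, 3)
  p_exact <- jt_test(x, g, method = "exact")$p
  p_perm <- jt_test(x, g, method = "permutation", n_perm = 20000,
                    seed = 4)$p
  expect_equal(p_perm, p_exact, tolerance = 0.02)
})

test_that("uniform weights are equivalent to no weights", {
  set.seed(5)
  x <- rnorm(40); g <- rep(1:4, each = 10)
  a <- jt_test(x, g, method = "asymptotic")
  b <- jt_test(x, g, weights = rep(2.5, 40), method = "asymptotic")
  expect_equal(a$u, b$u)
  expect_equal(a$z, b$z)
  expect_equal(a$p, b$p)
  pa <- jt_test(x, g, method = "permutation", n_perm = 500, seed = 9)
  pb <- jt_test(x, g, weights = rep(0.3, 40), method = "permutation",
                n_perm = 500, seed = 9)
  expect_equal(pa$p, pb$p)
})

test_that("U is invariant under strictly increasing transforms", {
  set.seed(6)
  x <- rlnorm(30); g <- rep(1:3, each = 10)
  u0 <- jt_statistic(x, g)$u
  expect_equal(jt_statistic(log(x), g)$u, u0)
  expect_equal(jt_statistic(rank(x), g)$u, u0)
})

test_that("degenerate and invalid inputs error", {
  expect_error(jt_statistic(1:4, rep(1, 4)), "2 distinct")
  expect_error(jt_statistic(c(1, NA, 3), c(1, 2, 3)), "missing")
  expect_error(jt_test(1:4, c(1, 1, 2, 2), weights = c(1, 1, -1, 1)),
               "positive")
  expect_error(jt_test(1:4, c(1, 1, 2, 2), method = "permutation",
                       n_perm = 50), "at least 100")
  expect_error(jt_test(rnorm(10), rep(1:2, 5), weights = runif(10, 1, 2),
                       method = "asymptotic"), "permutation")
})

test_that("saturated IPW weights are inverse cell proportions", {
  p <- toy_participants(10, pia = c(3, 3, 3, 3, 1, 1, 2, 4, 5, 5))
  m <- fit_ipw_weights(p)
  w3 <- m$weights$weight[m$weights$pia == 3]
  expect_equal(w3, rep(2.5, 4))  # p-hat = 0.4
  # uniform PIA independent of covariates: all weights 5
  p2 <- toy_participants(20, pia = rep(1:5, 4),
                         education = rep(1:2, each = 10),
                         sex = rep("male", 20))
  m2 <- fit_ipw_weights(p2)
  expect_equal(m2$weights$weight, rep(5, 20))
  # stabilized weights cancel to 1 under no confounding
  m3 <- fit_ipw_weights(p2, stabilize = TRUE)
  expect_equal(m3$weights$weight, rep(1, 20))
})

test_that("additive propensity model tracks the saturated one when correctly specified", {
  set.seed(30)
  n <- 3000
  edu <- sample(1:4, n, TRUE)
  # PIA depends on education only, so the additive logit is saturated
  # in the covariate that matters
  pia <- vapply(edu, function(e)
    sample(1:5, 1, prob = exp(0.3 * e * (1:5 - 3))), integer(1))
  p <- toy_participants(n, pia = pia, education = edu,
                        sex = sample(c("female", "male"), n, TRUE))
  m <- fit_ipw_weights(p, model = "additive")
  expect_true(all(m$weights$prob > 0))
  expect_true(all(m$weights$weight > 0))
  m_sat <- suppressWarnings(fit_ipw_weights(p))
  expect_gt(cor(m$weights$weight, m_sat$weights$weight), 0.9)
  expect_lt(max(abs(m$weights$prob - m_sat$weights$prob)), 0.05)
})

test_that("empty stratum-level cells trigger the continuity correction", {
  p <- toy_participants(12, pia = c(rep(1L, 6), rep(2:5, c(2, 2, 1, 1))),
                        education = rep(1:2, each = 6))
  expect_warning(fit_ipw_weights(p), "zero observations")
  m <- suppressWarnings(fit_ipw_weights(p))
  expect_true(all(is.finite(m$weights$weight)))
})

test_that("BH adjustment matches the brute-force step-up rule", {
  r <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))
  r1 <- bh_adjust(rep(1, 5))
  expect_false(any(r1$reject))
  expect_true(all(r1$p_bh == 1))
  r2 <- bh_adjust(0.04, q = 0.05)
  expect_true(r2$reject)
  expect_equal(r2$p_bh, 0.04)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(15)
  for (i in 1:50) {
    p <- runif(sample(3:20, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    r <- bh_adjust(p, q)
    expect_identical(r$reject, bh_reject_naive(p, q))
    expect_true(all(r$p_bh >= p))
  }
})

test_that("BH rejections are monotone in q", {
  set.seed(16)
  p <- runif(20)^2
  prev <- rep(FALSE, 20)
  for (q in c(0.01, 0.05, 0.1, 0.2, 0.5)) {
    cur <- bh_adjust(p, q)$reject
    expect_true(all(prev <= cur))
    prev <- cur
  }
})

test_that("effect size is the within-group share of total median variability", {
  mm <- tibble::tibble(group = rep(c("g1", "g2"), each = 2),
                       level = rep(1:2, 2), value = c(1, 3, 2, 2),
                       n = 5L)
  es <- effect_size(mm)
  expect_equal(es$effect_size_pct[es$group == "g1"], 100)
  expect_equal(es$effect_size_pct[es$group == "g2"], 0)
  # constant within groups (different between): ES 0 everywhere
  mm2 <- tibble::tibble(group = rep(c("g1", "g2"), each = 2),
                        level = rep(1:2, 2), value = c(5, 5, 9, 9), n = 5L)
  expect_true(all(effect_size(mm2)$effect_size_pct == 0))
  # level order is irrelevant
  mm3 <- mm
  mm3$value <- c(3, 1, 2, 2)
  expect_equal(effect_size(mm3), es)
  # fully degenerate matrix: undefined, flagged
  mm4 <- mm
  mm4$value <- 4
  expect_warning(es4 <- effect_size(mm4), "undefined")
  expect_true(all(is.na(es4$effect_size_pct)))
})

test_that("effect sizes lie in [0, 100] and within-SS sums below total", {
  set.seed(19)
  mm <- tidyr::expand_grid(group = letters[1:6], level = 1:5)
  mm$value <- rnorm(nrow(mm))
  mm$n <- 10L
  es <- effect_size(mm)
  expect_true(all(es$effect_size_pct >= 0 & es$effect_size_pct <= 100))
  expect_lte(sum(es$effect_size_pct), 100)
})

test_that("Spearman correlations handle monotone and tied cases", {
  s <- tibble::tibble(group = "Bread",
                      price_per_kg = c(1, 2, 3, 4),
                      price_per_mj = c(2, 4, 6, 8))
  r <- price_correlations(s)
  expect_equal(r$within$rho, 1)
  s$price_per_mj <- rev(s$price_per_mj)
  expect_equal(price_correlations(s)$within$rho, -1)
  s3 <- tibble::tibble(group = "Bread",
                       price_per_kg = c(1, 2, 3),
                       price_per_mj = c(2, 1, 3))
  expect_equal(price_correlations(s3)$within$rho, 0.5)
})

test_that("trend analysis emits one row per group and outcome with valid BH", {
  d <- simulate_dataset(sim_config(n_participants = 250, seed = 23,
                                   annual_expenditure_scale = 250))
  flt <- apply_inclusion_filters(d$participants, d$transactions)
  tx <- d$transactions[d$transactions$participant_id %in% flt$included$id, ]
  s <- compute_shares(aggregate_baskets(tx, d$catalog))
  res <- suppressWarnings(
    run_trend_analysis(s, flt$included, n_perm = 200, seed = 11))
  expect_equal(nrow(res), length(unique(s$group)) * 5)
  expect_true(all(res$p_bh >= res$p_w))
  expect_true(all(res$p_w > 0 & res$p_w <= 1))
  # forcing unit weights reproduces the unweighted U
  ipw1 <- suppressWarnings(fit_ipw_weights(flt$included))
  ipw1$weights$weight <- 1
  ipw1$weights$stratum <- "all"
  res1 <- suppressWarnings(
    run_trend_analysis(s, flt$included, outcomes = "price_per_kg",
                       ipw = ipw1, n_perm = 500, seed = 12))
  expect_equal(res1$u_w, res1$u)
  expect_equal(res1$z_w, res1$z, tolerance = 0.1)
})
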