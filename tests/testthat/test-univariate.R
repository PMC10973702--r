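test_that("normality routing sends Gaussian features to the t-test and skewed ones to Mann-Whitney", {
  set.seed(31)
  n <- 114
  X <- cbind(gauss = rnorm(n), lognorm = rlnorm(n, sdlog = 1))
  tab <- feature_table(X, rep_len(c(1L, 0L), n))
  routing <- route_by_normality(tab)
  expect_identical(routing$routed_test[routing$feature == "lognorm"], "mann-whitney")
  # at alpha = 0 nothing can be rejected
  r0 <- route_by_normality(tab, alpha = 0)
  expect_true(all(r0$routed_test == "t-test"))
  # Gaussian features routed to the t-test at about rate 1 - alpha
  set.seed(32)
  Xg <- matrix(rnorm(200 * 100), 200, 100)
  tg <- feature_table(Xg, rep_len(c(1L, 0L), 200))
  rg <- route_by_normality(tg)
  expect_gt(mean(rg$routed_test == "t-test"), 0.88)
})

test_that("pooled t reproduces the education-row statistic from exact group moments", {
  r <- t_from_moments(12.41, 2.91, 58, 13.40, 2.54, 56)
  expect_equal(round(r$statistic, 2), 1.93)
  expect_equal(round(r$p_value, 3), 0.056)
  # identical groups -> t = 0, p = 1; near-separation -> p ~ 0
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  sep <- two_sample_t(c(0, 0) + rnorm(2, sd = 1e-6), c(1, 1) + rnorm(2, sd = 1e-6))
  expect_gt(abs(sep$statistic), 1e3)
  expect_lt(sep$p_value, 1e-4)
})

test_that("t statistic is invariant under affine feature transformation", {
  set.seed(33)
  x1 <- rnorm(40, 1); x0 <- rnorm(35)
  a <- two_sample_t(x1, x0)
  b <- two_sample_t(3 * x1 - 7, 3 * x0 - 7)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("Mann-Whitney matches exact enumeration on small samples and has the U identity", {
  # all case above all control, 3 vs 3: U = 9, two-sided exact p = 0.1
  r <- mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
  expect_equal(unname(r$statistic), 9)
  expect_equal(r$p_value, 0.1)
  expect_equal(mw_exact_p(c(4, 5, 6), c(1, 2, 3)), 0.1)
  # enumeration oracle agrees on an asymmetric case
  set.seed(34)
  xc <- rnorm(5, 0.5); xo <- rnorm(4)
  expect_equal(mann_whitney_u(xc, xo)$p_value, mw_exact_p(xc, xo),
               tolerance = 1e-12)
  # U + mirrored U = n1 * n2
  r2 <- mann_whitney_u(xo, xc)
  expect_equal(unname(r$statistic) + unname(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$statistic), 9)
  expect_equal(unname(mann_whitney_u(xc, xo)$statistic) + unname(r2$statistic), 20)
  # interleaved identical samples -> p = 1
  expect_equal(mann_whitney_u(c(1, 3, 5), c(1, 3, 5))$p_value, 1)
})

test_that("Mann-Whitney p is invariant under strictly monotone transformation", {
  set.seed(35)
  xc <- rlnorm(25); xo <- rlnorm(20, 0.4)
  a <- mann_whitney_u(xc, xo)
  b <- mann_whitney_u(log(xc), log(xo))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("feature ranking is ascending in p with deterministic tie-breaks and threshold semantics", {
  res <- data.frame(feature = c("b", "c", "a"),
                    p_value = c(0.01, 0.20, 0.04))
  sel <- rank_features(res, 0.05)
  expect_identical(sel$feature, c("b", "a"))
  expect_equal(nrow(rank_features(res, 0)), 0)
  tie <- data.frame(feature = c("z", "a"), p_value = c(0.02, 0.02))
  expect_identical(rank_features(tie, 0.05)$feature, c("a", "z"))
})

test_that("chi-square without continuity correction reproduces the printed sex statistic", {
  r <- chi_square_2x2(matrix(c(35, 23, 29, 27), 2, byrow = TRUE))
  expect_equal(round(r$statistic, 2), 0.85)
  expect_equal(round(r$p_value, 3), 0.357)
  prop <- chi_square_2x2(matrix(c(10, 20, 30, 60), 2, byrow = TRUE))
  expect_equal(prop$statistic, 0, tolerance = 1e-12)
  expect_equal(prop$p_value, 1)
  r2 <- chi_square_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(unname(r2$statistic), 20)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
})

test_that("under the null both test paths reject at about the nominal level", {
  tab <- renormalize(simulate_table(sim_config(
    n_per_class = 60, n_regions = 200, heavy_tail_fraction = 0.2, seed = 41)))
  res <- univariate_selection(tab)
  for (path in c("t-test", "mann-whitney")) {
    p <- res$p_value[res$routed_test == path]
    rej <- mean(p < 0.05)
    se <- sqrt(0.05 * 0.95 / length(p))
    expect_lt(abs(rej - 0.05), 3 * se + 0.01)
  }
})

test_that("planted effects are recovered by the routed selection", {
  tab <- make_effect_table(n_per_class = 100, n_regions = 49, delta = 1,
                           n_effects = 5, seed = 42)
  res <- univariate_selection(tab)
  sel <- rank_features(res, 0.05)
  planted <- tab$feature_names[1:5]
  expect_true(all(planted %in% sel$feature))
  # planted features occupy the very top of the ranking
  expect_true(all(planted %in% res$feature[order(res$p_value)][1:10]))
})
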