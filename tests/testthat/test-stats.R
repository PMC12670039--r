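test_that("one-sample t matches hand arithmetic and the t distribution", {
  r0 <- one_sample_t(c(-1, 1), 0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  r <- one_sample_t(c(1, 2, 3), 0)
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2)
  # p from numerical integration of the t density
  quad <- stats::integrate(function(u) stats::dt(u, 2), r$statistic, Inf,
                           rel.tol = 1e-12)$value * 2
  expect_equal(r$p_value, quad, tolerance = 1e-8)
  r1 <- one_sample_t(c(1, 2, 3), 0, tails = "one")
  expect_equal(r1$p_value, r$p_value / 2, tolerance = 1e-12)
  expect_error(one_sample_t(c(2, 2, 2), 0), "zero variance")
  expect_error(one_sample_t(3, 0), "at least 2")
})

test_that("one-sample t calibrates its type-I error rate", {
  set.seed(50)
  mu <- 0.3
  rej <- vapply(1:10000, function(i)
    one_sample_t(rnorm(20, mean = mu), mu0 = mu)$p_value < 0.05, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.01)
})

test_that("BH step-up rejections follow the printed thresholds", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))
  expect_true(bh_fdr(0.04, 0.05)$reject)
  expect_false(any(bh_fdr(c(0.04, 0.9), 0.05)$reject))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(0.5, q = 1.3), "\\(0, 1\\)")
})

test_that("Holm adjustment follows the step-down maxima", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  set.seed(51)
  p <- runif(12)
  expect_true(all(holm_adjust(p) >= p))
})

test_that("BH and Holm match brute-force implementations exactly", {
  set.seed(52)
  for (i in 1:100) {
    m <- sample(1:15, 1)
    p <- round(runif(m), 3)  # ties occur
    q <- runif(1, 0.01, 0.2)
    got <- bh_fdr(p, q)
    want <- oracle_bh(p, q)
    expect_equal(got$p_adjusted, want$p_adjusted, tolerance = 1e-10)
    expect_identical(got$reject, want$reject)
    expect_equal(holm_adjust(p), oracle_holm(p), tolerance = 1e-10)
    # Holm-adjusted dominates BH-adjusted everywhere
    expect_true(all(holm_adjust(p) >= got$p_adjusted - 1e-12))
  }
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  m0 <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3)  # identical conditions
  r0 <- rm_anova_oneway(m0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  set.seed(53)
  # textbook-sized tables against the explicit SS decomposition
  for (i in 1:100) {
    n <- sample(3:8, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, mean = rep(rnorm(k), each = n)), n, k)
    got <- rm_anova_oneway(m)
    want <- oracle_rm_anova(m)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
    expect_equal(got$df, want$df)
  }
  # with two conditions, F is the squared paired-t statistic
  for (i in 1:20) {
    m <- matrix(rnorm(12), 6, 2)
    f <- rm_anova_oneway(m)$statistic
    t2 <- unname(stats::t.test(m[, 1], m[, 2], paired = TRUE)$statistic^2)
    expect_equal(f, t2, tolerance = 1e-10)
  }
  expect_error(rm_anova_oneway(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("partial Spearman recovers monotone association and the oracle", {
  set.seed(54)
  x <- sort(rnorm(30)); cov <- rnorm(30)
  r_up <- partial_spearman(x, 2 * x + 5, cov)
  expect_equal(r_up$estimate, 1, tolerance = 1e-10)
  r_dn <- partial_spearman(x, -x^3, cov)
  expect_equal(r_dn$estimate, -1, tolerance = 1e-10)
  for (i in 1:100) {
    n <- 50
    x <- rnorm(n); y <- rnorm(n)
    covariate <- if (i %% 2 == 0) rnorm(n)
                 else sample(c("d1", "d2", "d3"), n, replace = TRUE)
    got <- partial_spearman(x, y, covariate)
    want <- oracle_partial_spearman(x, y, covariate)
    expect_equal(got$estimate, want$estimate, tolerance = 1e-12)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  }
  expect_error(partial_spearman(1:3, 1:3, 1:3), "at least 4")
  expect_error(partial_spearman(rep(1, 10), rnorm(10), rnorm(10)),
               "constant")
})

test_that("a constant covariate reduces partial to plain Spearman", {
  set.seed(55)
  x <- rnorm(25); y <- rnorm(25)
  plain <- stats::cor(x, y, method = "spearman")
  got <- partial_spearman(x, y, rep(1, 25))
  expect_equal(got$estimate, plain, tolerance = 1e-10)
  got_f <- partial_spearman(x, y, factor(rep("a", 25)))
  expect_equal(got_f$estimate, plain, tolerance = 1e-10)
})
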