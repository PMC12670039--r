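test_that("configuration invariants are enforced", {
  expect_error(ground_truth_config(window_s = 0.2, srate = 250),
               "at least 64")
  expect_error(ground_truth_config(window_s = 0.601), "integer sample")
  expect_error(ground_truth_config(osc_mod_depth = 1), "\\[0, 1\\)")
  expect_error(ground_truth_config(beta = -0.1), "non-negative")
  expect_error(ground_truth_config(n_conditions = 3), "2 or 8")
})

test_that("background generator is deterministic under a fixed seed", {
  x1 <- generate_aperiodic_background(1.5, 0.5, 256, 250, seed = 42)
  x2 <- generate_aperiodic_background(1.5, 0.5, 256, 250, seed = 42)
  expect_identical(x1, x2)
  expect_error(generate_aperiodic_background(1, 0, 32, 250), "at least 64")
  expect_error(generate_aperiodic_background(-1, 0, 256, 250),
               "non-negative")
})

test_that("background spectrum follows the requested power law", {
  set.seed(101)
  # fit on the periodogram averaged over 20 seeds (low-noise oracle)
  avg_psd <- function(beta) {
    p <- rowMeans(replicate(20, unname(
      compute_psd(generate_aperiodic_background(beta, 0, 500, 250), 250))))
    setNames(p, 1:35)
  }
  # white-noise limit: flat spectrum, slope ~ 0
  expect_lt(abs(fit_aperiodic(avg_psd(0))["slope"]), 0.1)
  sl2 <- fit_aperiodic(avg_psd(2))["slope"]
  expect_gt(sl2, -2.15)
  expect_lt(sl2, -1.85)
})

test_that("seed-averaged band power matches the analytic target within 10%", {
  set.seed(7)
  srate <- 250; n <- 4000
  beta <- 1.5; off <- 1.2
  acc <- matrix(0, 29, 50)
  for (s in 1:50) {
    x <- generate_aperiodic_background(beta, off, n, srate)
    p <- boxcar_periodogram(x, srate)
    f <- attr(p, "freqs")
    acc[, s] <- vapply(2:30, function(f0)
      mean(p[abs(f - f0) <= 0.375 + 1e-9]), numeric(1))
  }
  target <- 10^off * (2:30)^(-beta)
  ratio <- rowMeans(acc) / target
  expect_true(all(ratio > 0.9 & ratio < 1.1))
})

test_that("attention epochs have the declared label and shape structure", {
  mont <- small_montage()
  cf8 <- ground_truth_config(n_trials_per_condition = 3, n_conditions = 8,
                             n_channels = 10, seed = 3)
  ep <- generate_attention_epochs(cf8, mont)
  expect_identical(sort(unique(ep$labels)), 1:8)
  expect_true(all(table(ep$labels) == 3))
  expect_identical(dim(ep$data), c(24L, 10L, 150L))
  # determinism: bit-identical regeneration
  ep2 <- generate_attention_epochs(cf8, mont)
  expect_identical(ep$data, ep2$data)
  # montage mismatch
  expect_error(generate_attention_epochs(
    ground_truth_config(n_channels = 4), mont), "does not match")
})

test_that("null epochs are balanced and deterministic", {
  mont <- small_montage()
  cf <- small_config(seed = 9)
  ep <- generate_null_epochs(cf, mont)
  expect_true(max(table(ep$labels)) - min(table(ep$labels)) <= 1)
  ep2 <- generate_null_epochs(cf, mont)
  expect_identical(ep$labels, ep2$labels)
  expect_identical(ep$data, ep2$data)
  # labels differ from the systematic assignment with high probability
  expect_false(all(ep$labels == rep(1:2, each = 8)))
})

test_that("labels are exchangeable at zero modulation", {
  # permutation p-values of a lateralisation statistic on null epochs are
  # uniform across seeds
  mont <- small_montage()
  li <- match(mont$left_posterior, mont$channel_names)
  ri <- match(mont$right_posterior, mont$channel_names)
  pvals <- vapply(1:200, function(s) {
    cf <- small_config(seed = s, osc_mod_depth = 0, ap_mod_depth = 0)
    ep <- generate_null_epochs(cf, mont)
    alpha_pow <- vapply(seq_len(dim(ep$data)[1]), function(i) {
      lat <- function(ch) mean(vapply(ch, function(c)
        band_power(compute_psd(ep$data[i, c, ], ep$srate), 8, 13),
        numeric(1)))
      lat(li) - lat(ri)
    }, numeric(1))
    stat <- function(lab) abs(mean(alpha_pow[lab == 1]) -
                                mean(alpha_pow[lab == 2]))
    obs <- stat(ep$labels)
    perm <- replicate(99, stat(sample(ep$labels)))
    (1 + sum(perm >= obs)) / 100
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
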