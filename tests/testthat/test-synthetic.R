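# Synthetic-data generator: AR(1) panels, planted networks, null pairs.

test_that("ar1_panel is deterministic, stationary, and matches the AR(1) closed form", {
  a <- ar1_panel(5, 200, 0.6, seed = 11)
  b <- ar1_panel(5, 200, 0.6, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, ar1_panel(5, 200, 0.6, seed = 12)))

  # phi = 0 degenerates to white noise: lag-1 autocorrelation within 3/sqrt(T)
  w <- ar1_panel(1, 10000, 0, seed = 2)[1, ]
  r1 <- cor(w[-1], w[-length(w)])
  expect_lt(abs(r1), 3 / sqrt(10000))

  # lag-1 autocorrelation of AR(1) is phi
  x <- ar1_panel(1, 10000, 0.6, seed = 3)[1, ]
  expect_lt(abs(cor(x[-1], x[-length(x)]) - 0.6), 0.02)

  # unit marginal variance by construction
  big <- ar1_panel(200, 2000, 0.8, seed = 4)
  expect_lt(abs(mean(apply(big, 1, var)) - 1), 0.05)
})

test_that("ar1_panel rejects invalid inputs", {
  expect_error(ar1_panel(3, 5, 0.5, seed = 1), "at least 10")
  expect_error(ar1_panel(3, 100, 1.0, seed = 1), "stationary")
  expect_error(ar1_panel(3, 100, -1.2, seed = 1), "stationary")
})

test_that("planted networks hit their target correlations (construction oracle, no smoothing)", {
  d <- generate_dataset(synth_config(grid_shape = c(16, 16), n_frames = 300,
                                     spatial_sigma = 0, seed = 5))
  R <- cor(t(d$series))
  same <- outer(d$block, d$block, `==`) & lower.tri(R)
  diff <- outer(d$block, d$block, `!=`) & lower.tri(R)
  expect_lt(abs(mean(R[same]) - 0.7), 0.1)
  expect_lt(abs(mean(R[diff]) - (-0.3)), 0.1)

  # independence case: one network, zero correlation
  d0 <- generate_dataset(synth_config(grid_shape = c(12, 12), n_networks = 1,
                                      within_network_corr = 0,
                                      between_network_corr = 0,
                                      spatial_sigma = 0, seed = 6))
  R0 <- cor(t(d0$series))
  expect_lt(abs(mean(R0[lower.tri(R0)])), 0.02)
})

test_that("block-level correlations converge to truth at large T", {
  d <- generate_dataset(synth_config(grid_shape = c(10, 10), n_frames = 10000,
                                     spatial_sigma = 0, seed = 7))
  R <- cor(t(d$series))
  same <- outer(d$block, d$block, `==`) & lower.tri(R)
  diff <- outer(d$block, d$block, `!=`) & lower.tri(R)
  expect_lt(abs(mean(R[same]) - d$truth_within), 0.03)
  expect_lt(abs(mean(R[diff]) - d$truth_between), 0.03)
})

test_that("dataset structure is coherent and deterministic", {
  cfg <- synth_config(grid_shape = c(14, 14), seed = 9)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$series, d2$series)
  expect_equal(nrow(d1$series), d1$mask$n_pixels)
  expect_true(isSymmetric(d1$truth_corr))
  expect_equal(diag(d1$truth_corr), rep(1, cfg$n_networks))
  expect_true(all(d1$truth_tau >= 1))
  expect_setequal(unique(d1$block), seq_len(cfg$n_networks))
  # parcellation labels exactly the planted blocks
  expect_equal(d1$parcellation$pixel_labels, d1$block)
})

test_that("non-PSD network structure is rejected at construction with a helpful message", {
  expect_error(synth_config(n_networks = 4, within_network_corr = 0.3,
                            between_network_corr = -0.25),
               "positive semi-definite")
  expect_error(synth_config(within_network_corr = 0.2,
                            between_network_corr = 0.5),
               "positive semi-definite")
  expect_error(synth_config(within_network_corr = 0,
                            between_network_corr = 0.2), "must be 0")
  expect_error(synth_config(n_frames = 5), "at least 10")
})

test_that("null pairs are independent, symmetric in the seeds, and refuse equal seeds", {
  cfg <- synth_config(grid_shape = c(12, 12), spatial_sigma = 0, seed = 1)
  pair <- generate_null_pair(cfg, 101, 202)
  C <- cor(t(pair$a$series), t(pair$b$series))
  Tn <- cfg$n_frames
  expect_lt(abs(mean(C)), 3 / sqrt(Tn * length(C)) + 0.01)

  swapped <- generate_null_pair(cfg, 202, 101)
  expect_identical(swapped$a$series, pair$b$series)
  expect_identical(swapped$b$series, pair$a$series)

  expect_error(generate_null_pair(cfg, 7, 7), "must differ")
})

test_that("cross-dataset naive p-values are uniform for white-noise nulls", {
  cfg <- synth_config(grid_shape = c(12, 12), ar_coeff = 0,
                      n_networks = 1, within_network_corr = 0,
                      between_network_corr = 0, spatial_sigma = 0)
  pair <- generate_null_pair(cfg, 31, 41)
  a <- normalize_series(as_raw_series(pair$a))
  b <- normalize_series(as_raw_series(pair$b))
  fit <- fc_null_fit(a, b, estimator = "naive")
  frac <- mean(fit$P < 0.05)
  # ~5% of naive p-values below 0.05 when the variance is calibrated
  expect_lt(abs(frac - 0.05), 0.01)
})

test_that("white-noise option dilutes the autocorrelation time as predicted", {
  cfg <- synth_config(grid_shape = c(16, 16), noise = "white",
                      spatial_sigma = 0, n_frames = 2000, seed = 13)
  d <- generate_dataset(cfg)
  ac <- autocorr_map(normalize_series(as_raw_series(d)))
  expect_lt(abs(ac$mean_tau - d$truth_tau[1]) / d$truth_tau[1], 0.10)
  expect_lt(d$truth_tau[1], 1 / (1 - cfg$ar_coeff^2))
})
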