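# Autocorrelation times, effective DOF, and the three variance estimators.

test_that("tapered autocorrelation sequence has the Tukey endpoints and tracks AR(1)", {
  x <- ar1_panel(1, 10000, 0.6, seed = 1)[1, ]
  rho <- tapered_autocorr(x, max_lag = 50)
  expect_equal(rho[1], 1)                      # w_0 = 1, rho_0 = 1
  expect_equal(rho[51], 0)                     # w_M = 0
  w1 <- 0.5 * (1 + cos(pi / 50))
  expect_lt(abs(rho[2] - 0.6 * w1), 0.02)
  expect_error(tapered_autocorr(x[1:10], max_lag = 10), "smaller")
})

test_that("autocorrelation time approaches 1 for white noise and the geometric sum for AR(1)", {
  wn <- ar1_panel(1, 10000, 0, seed = 2)[1, ]
  tau_wn <- autocorr_time(wn, max_lag = 200)
  expect_gte(tau_wn, 1)
  expect_lte(tau_wn, 1.05)

  x <- ar1_panel(1, 1000, 0.5, seed = 3)[1, ]
  expect_lt(abs(autocorr_time(x) - 1 / (1 - 0.25)) / (1 / 0.75), 0.10)

  # long-memory regime: a periodic series keeps tau large; the brute-force
  # oracle is the tapered sum with the analytic cosine autocorrelation
  # rho_k ~ (1 - k/T) cos(2 pi k / 40)
  tt <- 1:1000
  per <- cos(2 * pi * tt / 40)
  M <- 60
  w <- 0.5 * (1 + cos(pi * (0:M) / M))
  rho_oracle <- c(1, (1 - (1:M) / 1000) * cos(2 * pi * (1:M) / 40))
  tau_oracle <- sum((w * rho_oracle)^2)        # = 11.45
  tau_per <- autocorr_time(per, max_lag = M)
  expect_lt(abs(tau_per - tau_oracle) / tau_oracle, 0.02)
  expect_gt(tau_per, M / 8)
})

test_that("autocorr_map is tight on homogeneous panels and ranks mixed panels correctly", {
  s <- make_ar1_series(250, 300, 0.5, seed = 4)
  ac <- autocorr_map(s)
  expect_lt(sd(ac$tau) / mean(ac$tau), 0.15)
  # mean recovers the analytic value within 10% averaged over >= 200 pixels
  expect_lt(abs(ac$mean_tau - 4 / 3) / (4 / 3), 0.10)

  phis <- rep(c(0, 0.3, 0.6, 0.8), each = 50)
  X <- ar1_panel(200, 1000, phis, seed = 5)
  acm <- autocorr_map(X)
  expect_gt(cor(acm$tau, 1 / (1 - phis^2), method = "spearman"), 0.9)

  single <- autocorr_map(X[1, , drop = FALSE])
  expect_equal(single$mean_tau, single$tau[1])
})

test_that("bartlett effective DOF follows both conversion conventions", {
  ac <- structure(list(tau = rep(3, 10), mean_tau = 3, median_tau = 3,
                       max_lag = 35, n_frames = 300, mask = NULL),
                  class = "autocorr_map")
  expect_equal(bartlett_edof(ac, two_sided = FALSE)$T_hat, 100)
  expect_equal(bartlett_edof(ac, two_sided = TRUE)$T_hat, 300 / 5)
  # white-noise limit: tau ~ 1 gives T_hat ~ T under either convention
  wn <- autocorr_map(make_ar1_series(100, 2000, 0, seed = 6))
  expect_lt(abs(bartlett_edof(wn)$T_hat - 2000) / 2000, 0.1)
  # the real-data arithmetic: T = 300 with <tau> = 6.652 gives 45.1
  ac2 <- ac; ac2$mean_tau <- 6.652
  expect_equal(bartlett_edof(ac2, two_sided = FALSE)$T_hat, 45.1,
               tolerance = 1e-3)
})

test_that("variance formulas match their arithmetic oracles", {
  expect_equal(variance_naive(0, 103), 0.01)
  expect_equal(variance_naive(1, 100), 0)
  expect_equal(variance_naive(0.5, 53), 0.75^2 / 50)
  expect_error(variance_naive(0.5, 3), "T > 3")

  ed <- structure(list(T_hat = 100, T = 300, mean_tau = 3,
                       two_sided = FALSE, tau_summary = "mean"),
                  class = "effective_dof")
  expect_equal(variance_bartlett(0, ed), 0.01)
  ed$T_hat <- 45.1
  expect_equal(variance_bartlett(0.5, ed), 0.5625 / 45.1)  # (1-0.25)^2/45.1
  # tau = 1 limit agrees with naive up to (T-3)/T
  ed$T_hat <- 300
  expect_equal(variance_bartlett(0.3, ed) / variance_naive(0.3, 300),
               297 / 300)
})

test_that("xDF floors white-noise pairs at the naive variance", {
  x <- ar1_panel(1, 300, 0, seed = 7)[1, ]
  y <- ar1_panel(1, 300, 0, seed = 8)[1, ]
  v <- variance_xdf(x, y)
  # raw plug-zeros value (T-2)/T^2 sits below the naive floor 1/(T-3)
  expect_lt(abs(v$V_raw - 298 / 300^2), 0.002)
  expect_true(v$floor_applied)
  expect_equal(v$V, variance_naive(v$r0, 300))
})

test_that("xDF exceeds the naive variance for strongly autocorrelated pairs", {
  n <- 200
  X <- ar1_panel(n, 300, 0.8, seed = 9)
  Y <- ar1_panel(n, 300, 0.8, seed = 10)
  res <- oisconn:::xdf_pairs(X, Y)
  ratio <- mean(res$V / variance_naive(res$r0, 300))
  expect_gt(ratio, 1.5)
  expect_lt(mean(res$floor_applied), 0.2)     # floor rarely binds here
})

test_that("pairwise, vectorized and matrix xDF agree; degenerate pairs stay finite", {
  s <- make_ar1_series(8, 200, 0.6, seed = 11)
  mat <- variance_xdf_matrix(s)
  for (pair in list(c(2, 1), c(5, 3), c(8, 7))) {
    single <- variance_xdf(s$data[pair[1], ], s$data[pair[2], ])
    expect_equal(mat$V[pair[1], pair[2]], single$V, tolerance = 1e-10)
    expect_equal(mat$floor_applied[pair[1], pair[2]], single$floor_applied)
  }
  expect_true(isSymmetric(mat$V))
  # elementwise floor contract
  expect_true(all(mat$V >= variance_naive(cor(t(s$data)), 200) - 1e-15))

  self <- variance_xdf(s$data[1, ], s$data[1, ])
  expect_true(is.finite(self$V))
  expect_equal(self$r0, 1)
  # the printed and product cross-term forms differ negligibly near the null
  alt <- oisconn:::xdf_pairs(s$data[1:4, ], s$data[5:8, ],
                             cross_term = "product")
  std <- oisconn:::xdf_pairs(s$data[1:4, ], s$data[5:8, ])
  expect_equal(std$V, alt$V, tolerance = 0.05)
})

test_that("z scores satisfy the naive closed form and estimator identities", {
  expect_equal(zscore(fisher_z(0.5), 0.5, variance_naive(0.5, 103)),
               0.549306 * 10, tolerance = 1e-5)
  expect_equal(zscore(0, 0, 0.01), 0)

  s <- make_ar1_series(15, 300, 0.6, seed = 12)
  fn <- fc_fit(s, estimator = "naive")
  lw <- lower.tri(fn$Z)
  expect_equal(fn$Z[lw], sqrt(297) * atanh(fn$R[lw]), tolerance = 1e-10)

  fb <- fc_fit(s, estimator = "bartlett")
  ratio <- fb$Z[lw] / fn$Z[lw]
  expect_equal(ratio, rep(sqrt(fb$edof$T_hat / 297), sum(lw)),
               tolerance = 1e-10)

  fx <- fc_fit(s, estimator = "xdf")
  expect_true(all(fx$V[lw] >= fn$V[lw] - 1e-15))
  expect_true(all(abs(fx$Z[lw]) <= abs(fn$Z[lw]) + 1e-10))
})

test_that("p-values follow the two-tailed normal CDF and its monotonicity", {
  expect_equal(pvalue(0), 1)
  expect_equal(pvalue(1.959964), 0.05, tolerance = 1e-6)
  z <- seq(0, 8, by = 0.25)
  expect_true(all(diff(pvalue(z)) < 0))
  expect_gt(pvalue(1000), 0)                  # clamped, not underflowed to 0
  expect_error(pvalue(Inf), "finite")
})

test_that("KS distance from normal matches closed-form oracles", {
  z <- with_seed_test(13, rnorm(1e5))
  expect_lt(ks_normality(z), 0.01)
  # sup |Phi(x) - Phi(x - 1)| attained at x = 1/2
  shifted <- z + 1
  d_true <- pnorm(0.5) - pnorm(-0.5)
  expect_lt(abs(ks_normality(shifted) - d_true), 0.01)
  expect_error(ks_normality(rnorm(10)), "at least 50")
})

test_that("parcel length regression recovers noiseless relations", {
  m <- brain_mask(matrix(TRUE, 10, 10))
  labels <- matrix(0L, 10, 10)
  labels[1:2, ] <- 1L; labels[3:5, ] <- 2L; labels[6:10, 1:6] <- 3L
  labels[6:10, 7:10] <- 4L
  parc <- parcellation(labels, m)

  flat <- parcel_length_regression(rep(2.5, 4), parc)
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  tau_lin <- 5 - 0.3 * sqrt(parc$areas)
  fit <- parcel_length_regression(tau_lin, parc)
  expect_equal(fit$slope, -0.3, tolerance = 1e-10)
  expect_equal(abs(fit$r), 1, tolerance = 1e-10)
})

test_that("calibrated estimators yield near-uniform null p-values", {
  # independent-pixel null: planted networks would make the cross pairs
  # share a handful of latent signals and the single-run p histogram lumpy
  pair <- generate_null_pair(synth_config(grid_shape = c(16, 16),
                                          n_networks = 1,
                                          within_network_corr = 0,
                                          between_network_corr = 0,
                                          spatial_sigma = 0), 51, 61)
  a <- normalize_series(as_raw_series(pair$a))
  b <- normalize_series(as_raw_series(pair$b))
  fit <- fc_null_fit(a, b, estimator = "bartlett")
  expect_gte(length(fit$P), 1e4)
  ks_p <- suppressWarnings(ks.test(as.vector(fit$P), "punif"))$statistic
  expect_lt(unname(ks_p), 0.05)
})
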