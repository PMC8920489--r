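# Preprocessing chain: smoothing, bandpass/decimation, GSR, normalization,
# parcel averaging, run concatenation.

make_masked_raw <- function(frame_values, mask_img, fs = 1) {
  m <- brain_mask(mask_img)
  data <- matrix(frame_values[m$pixel_index], ncol = 1)
  raw_series(data, fs = fs, mask = m)
}

test_that("spatial smoothing preserves constants and reproduces the kernel on an impulse", {
  mask_img <- matrix(TRUE, 9, 9)
  const <- matrix(3.7, 9, 9)
  sm <- spatial_smooth(make_masked_raw(const, mask_img))
  expect_equal(as.vector(sm$data), rep(3.7, 81), tolerance = 1e-12)

  # interior impulse: center output equals the normalized 5x5 Gaussian center
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  sm2 <- spatial_smooth(make_masked_raw(imp, mask_img))
  d <- exp(-(-2:2)^2 / 2)
  kern <- outer(d, d); kern <- kern / sum(kern)
  m <- brain_mask(mask_img)
  center_row <- which(m$pixel_index[, 1] == 5 & m$pixel_index[, 2] == 5)
  expect_equal(sm2$data[center_row, 1], kern[3, 3], tolerance = 1e-12)
})

test_that("smoothing at mask edges equals the brute-force mask-renormalized convolution", {
  set.seed(42)
  m <- ellipse_mask(c(11, 13), 0.55)
  frame <- matrix(0, 11, 13)
  frame[m$pixel_index] <- rnorm(m$n_pixels)
  raw <- raw_series(matrix(frame[m$pixel_index], ncol = 1), 1, m)
  sm <- spatial_smooth(raw)
  d <- exp(-(-2:2)^2 / 2)
  kern <- outer(d, d) / sum(outer(d, d))
  ref <- brute_force_masked_smooth(frame, m$image, kern)
  expect_equal(as.vector(sm$data), ref[m$pixel_index], tolerance = 1e-10)
  expect_error(spatial_smooth(raw, kernel_size = 4L), "odd")
})

test_that("bandpass passes 0.05 Hz, rejects 1 Hz and DC, and decimates to the target rate", {
  fs <- 30; t <- seq(0, 300 - 1 / fs, by = 1 / fs)
  m <- brain_mask(matrix(TRUE, 2, 1))
  mk <- function(x) raw_series(rbind(x, x), fs = fs, mask = m)

  pass <- bandpass_downsample(mk(sin(2 * pi * 0.05 * t)))
  mid <- seq(100, 200)                       # avoid filter edge transients
  expect_gt(max(abs(pass$data[1, mid])), 0.95)
  expect_equal(pass$fs, 1)
  expect_equal(ncol(pass$data), 300 / 30 * 30)   # 300 s at 1 Hz

  stop_ <- bandpass_downsample(mk(sin(2 * pi * 1 * t)))
  expect_lt(max(abs(stop_$data[1, mid])), 0.1)   # >= 20 dB attenuation

  dc <- bandpass_downsample(mk(rep(1, length(t))))
  expect_lt(max(abs(dc$data[1, mid])), 0.01)   # DC outside the passband

  expect_error(bandpass_downsample(mk(t), target_fs = 7), "integer multiple")
  expect_error(bandpass_downsample(mk(t), low = 0.1, high = 20), "fs/2")
})

test_that("global signal regression removes shared structure and leaves residuals orthogonal", {
  m <- brain_mask(matrix(TRUE, 6, 1))
  g <- sin(seq(0, 10, length.out = 200))
  same <- raw_series(matrix(rep(g, each = 6), 6), 1, m)
  out <- global_signal_regress(same)
  expect_lt(max(abs(out$data)), 1e-10)

  set.seed(7)
  X <- matrix(rnorm(6 * 200), 6)
  out2 <- global_signal_regress(raw_series(X, 1, m))
  gsig <- colMeans(X) - mean(colMeans(X))
  expect_lt(max(abs(out2$data %*% gsig)), 1e-8)

  flat <- raw_series(matrix(0.5, 6, 200) + rep(rnorm(6), 200) * 0, 1, m)
  expect_error(global_signal_regress(flat), "zero variance")
})

test_that("normalization yields exact zero-mean unit-SD rows and is affine invariant", {
  set.seed(8)
  m <- brain_mask(matrix(TRUE, 4, 1))
  X <- matrix(rnorm(4 * 150, mean = 5, sd = 3), 4)
  n1 <- normalize_series(raw_series(X, 1, m))
  expect_lt(max(abs(rowMeans(n1$data))), 1e-10)
  expect_lt(max(abs(apply(n1$data, 1, sd) - 1)), 1e-10)

  n2 <- normalize_series(raw_series(2.5 * X + 7, 1, m))
  expect_equal(n1$data, n2$data, tolerance = 1e-12)
  n3 <- normalize_series(raw_series(-X, 1, m))
  expect_equal(n3$data, -n1$data, tolerance = 1e-12)

  X[2, ] <- 4
  expect_error(normalize_series(raw_series(X, 1, m)), "zero-variance")
})

test_that("parcel averaging reduces to identity for singleton parcels and scales iid noise", {
  set.seed(9)
  m <- brain_mask(matrix(TRUE, 6, 1))
  s <- normalize_series(raw_series(matrix(rnorm(6 * 400), 6), 1, m))
  labels <- matrix(1:6, 6, 1)
  pav <- parcel_average(s, parcellation(labels, m))
  expect_equal(pav$data, s$data, tolerance = 1e-10)

  # all six iid pixels in one parcel: pre-normalization SD ~ 1/sqrt(6)
  one <- parcel_average(s, parcellation(matrix(1L, 6, 1), m))
  expect_lt(abs(pav$parcel_sd[1] - 1), 0.1)
  expect_lt(abs(one$parcel_sd[1] - 1 / sqrt(6)), 0.1)

  # two identical pixels in a parcel reproduce the pixel series
  dup <- s; dup$data <- s$data[c(1, 1, 2:4), , drop = FALSE]
  m5 <- brain_mask(matrix(TRUE, 5, 1))
  dup$mask <- m5
  pav2 <- parcel_average(dup, parcellation(matrix(c(1L, 1L, 2L, 3L, 4L), 5, 1), m5))
  expect_equal(pav2$data[1, ], s$data[1, ], tolerance = 1e-10)
})

test_that("run concatenation sums frames, keeps per-run normalization, and checks compatibility", {
  runs <- lapply(1:5, function(i) make_ar1_series(8, 300, 0.5, seed = 100 + i))
  cat5 <- concatenate_runs(runs)
  expect_equal(cat5$n_frames, 1500)          # 5 x 5-min runs = 25 min at 1 Hz
  expect_equal(cat5$run_boundaries, rep(300L, 5))

  expect_identical(concatenate_runs(runs[1]), runs[[1]])

  # concatenating a run with itself leaves the correlation matrix unchanged
  dupcat <- concatenate_runs(list(runs[[1]], runs[[1]]))
  expect_equal(correlation_matrix(dupcat)$R, correlation_matrix(runs[[1]])$R,
               tolerance = 1e-12)

  other <- make_ar1_series(9, 300, 0.5, seed = 1)
  expect_error(concatenate_runs(list(runs[[1]], other)), "same mask")
})

test_that("each preprocessing step refuses to run twice (provenance guard)", {
  m <- brain_mask(matrix(TRUE, 3, 3))
  raw <- raw_series(matrix(rnorm(9 * 120), 9), 1, m)
  sm <- spatial_smooth(raw)
  expect_error(spatial_smooth(sm), "already applied")
  g <- global_signal_regress(sm)
  expect_error(global_signal_regress(g), "already applied")
})

test_that("parcel averaging tightens the spread of estimated autocorrelation times", {
  # low-SNR regime: white idiosyncratic noise dilutes per-pixel tau unevenly;
  # parcel means recover the network signal's autocorrelation more stably
  cfg <- synth_config(grid_shape = c(20, 20), n_networks = 8,
                      between_network_corr = 0, noise = "white",
                      spatial_sigma = 0, seed = 21)
  d <- generate_dataset(cfg)
  s <- normalize_series(as_raw_series(d))
  pav <- parcel_average(s, d$parcellation)
  tau_pix <- autocorr_map(s)$tau
  tau_par <- autocorr_map(pav)$tau
  expect_lt(sd(tau_par) / mean(tau_par), sd(tau_pix) / mean(tau_pix))
})
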