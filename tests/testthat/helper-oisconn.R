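# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# Independent brute-force evaluation of the BY rule, written directly from
# its definition: k* is the largest k with p_(k) < (k/N) * gamma / H_N.
brute_force_by <- function(p, gamma) {
  n <- length(p)
  h <- sum(1 / seq_len(n))
  ord <- order(p, seq_along(p))
  ps <- p[ord]
  k_star <- 0L
  for (k in seq_len(n)) if (ps[k] < (k / n) * gamma / h) k_star <- k
  reject <- logical(n)
  if (k_star > 0L) reject[ord[seq_len(k_star)]] <- TRUE
  list(k_star = k_star, reject = reject)
}

# Brute-force mask-renormalized Gaussian convolution of one frame
# (reference for spatial_smooth).
brute_force_masked_smooth <- function(frame, mask_img, kernel) {
  half <- (nrow(kernel) - 1L) / 2L
  out <- matrix(NA_real_, nrow(frame), ncol(frame))
  for (r in seq_len(nrow(frame))) for (cc in seq_len(ncol(frame))) {
    if (!mask_img[r, cc]) next
    acc <- 0; wsum <- 0
    for (dr in -half:half) for (dc in -half:half) {
      rr <- r + dr; c2 <- cc + dc
      if (rr < 1 || rr > nrow(frame) || c2 < 1 || c2 > ncol(frame)) next
      if (!mask_img[rr, c2]) next
      w <- kernel[dr + half + 1L, dc + half + 1L]
      acc <- acc + w * frame[rr, c2]
      wsum <- wsum + w
    }
    out[r, cc] <- acc / wsum
  }
  out
}

# Run code under a local seed (tests do not need RNG-state restoration).
with_seed_test <- function(seed, code) {
  set.seed(seed)
  code
}

# Small normalized series of independent AR(1) pixels on a trivial mask.
make_ar1_series <- function(n_pixels, n_frames, phi, seed) {
  x <- ar1_panel(n_pixels, n_frames, phi, seed)
  m <- brain_mask(matrix(TRUE, n_pixels, 1L))
  normalize_series(raw_series(x, fs = 1, mask = m))
}

# Default-condition synthetic series, optionally without smoothing.
make_synth_series <- function(seed, grid = c(16L, 16L), sigma = 1, ...) {
  d <- generate_dataset(synth_config(grid_shape = grid,
                                     spatial_sigma = sigma, seed = seed, ...))
  list(dataset = d, series = normalize_series(as_raw_series(d)))
}
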