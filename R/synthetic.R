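# Synthetic OIS-like data with known temporal and network structure.
#
# The generator emulates the regime of preprocessed widefield hemodynamic
# recordings: 5-min runs sampled at 1 Hz after 0.01-0.1 Hz bandpass, with
# per-pixel temporal autocorrelation, spatial smoothness, and planted
# block-structured correlation networks (including anticorrelations). Every
# downstream statistic can therefore be checked against ground truth.

#' Panel of independent stationary AR(1) time series
#'
#' Each row follows \eqn{x_t = \phi x_{t-1} + \sqrt{1-\phi^2}\,\epsilon_t}
#' with standard-normal innovations and a stationary start, so the marginal
#' variance is exactly 1 and the lag-k autocorrelation is \eqn{\phi^k}.
#' The analytic autocorrelation time (sum of squared autocorrelations over
#' lags 0, 1, 2, ...) is \eqn{1/(1-\phi^2)}.
#'
#' @param n_pixels Number of rows (independent series).
#' @param n_frames Series length T; must be >= 10.
#' @param phi AR(1) coefficient, `|phi| < 1`; scalar or one value per row.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return `n_pixels` x `n_frames` numeric matrix.
#' @examples
#' x <- ar1_panel(4, 100, phi = 0.6, seed = 1)
#' @export
ar1_panel <- function(n_pixels, n_frames, phi, seed) {
  if (n_frames < 10L) stop("`n_frames` must be at least 10", call. = FALSE)
  if (n_pixels < 1L) stop("`n_pixels` must be positive", call. = FALSE)
  if (any(abs(phi) >= 1))
    stop("|phi| must be < 1 for a stationary AR(1) process", call. = FALSE)
  if (!length(phi) %in% c(1L, n_pixels))
    stop("`phi` must be a scalar or one value per pixel", call. = FALSE)
  phi <- rep_len(phi, n_pixels)
  with_seed(seed, {
    x <- matrix(rnorm(n_pixels * n_frames), n_pixels, n_frames)
    s <- sqrt(1 - phi^2)
    for (t in 2:n_frames) x[, t] <- phi * x[, t - 1L] + s * x[, t]
    x
  })
}

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the study conditions the package validates against: a
#' 32 x 32 grid with an elliptical dorsal-window mask covering ~60% of the
#' grid, 5-min runs at 1 Hz (T = 300), AR(1) coefficient 0.75 (analytic
#' autocorrelation time 1/(1-0.75^2) = 2.29 s, inside the 2-3.5 s range
#' typical of bandpassed cortical hemodynamics), two planted networks with
#' within-network correlation 0.7 and between-network correlation -0.3, and
#' 5 x 5 Gaussian spatial smoothing with sigma = 1 pixel.
#'
#' The implied network correlation matrix (diagonal
#' `within_network_corr`, off-diagonal `between_network_corr`) must be
#' positive semi-definite; this is checked at construction.
#'
#' @param grid_shape Grid `c(rows, cols)`.
#' @param mask_fraction Fraction of the grid inside the elliptical mask.
#' @param n_frames Frames T at 1 Hz; >= 10.
#' @param ar_coeff AR(1) coefficient `phi` (scalar, `|phi| < 1`).
#' @param n_networks Number of planted correlated blocks.
#' @param within_network_corr Target correlation of pixel pairs in the same
#'   network, in `[0, 1)`.
#' @param between_network_corr Target correlation of pixel pairs in
#'   different networks, may be negative; `|between| < 1`.
#' @param spatial_sigma Gaussian smoothing SD in pixels (0 disables).
#' @param kernel_size Odd smoothing-kernel support in pixels.
#' @param noise Idiosyncratic pixel-noise model: `"ar1"` (default; noise
#'   shares the network AR(1) coefficient, so every pixel series is exactly
#'   AR(1) and `truth_tau = 1/(1-phi^2)`) or `"white"` (uncorrelated
#'   frame-to-frame noise, emulating low-SNR pixels whose autocorrelation
#'   time is diluted towards 1; then
#'   `truth_tau = 1 + w^2 phi^2/(1-phi^2)` with `w` the within-network
#'   correlation).
#' @param seed Root RNG seed recorded in the dataset.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(grid_shape = c(32L, 32L),
                         mask_fraction = 0.6,
                         n_frames = 300L,
                         ar_coeff = 0.75,
                         n_networks = 2L,
                         within_network_corr = 0.7,
                         between_network_corr = -0.3,
                         spatial_sigma = 1,
                         kernel_size = 5L,
                         noise = c("ar1", "white"),
                         seed = 1L) {
  noise <- match.arg(noise)
  if (n_frames < 10L) stop("`n_frames` must be at least 10", call. = FALSE)
  if (abs(ar_coeff) >= 1) stop("|ar_coeff| must be < 1", call. = FALSE)
  if (within_network_corr < 0 || within_network_corr >= 1)
    stop("`within_network_corr` must be in [0, 1)", call. = FALSE)
  if (abs(between_network_corr) >= 1)
    stop("|between_network_corr| must be < 1", call. = FALSE)
  if (n_networks < 1L) stop("`n_networks` must be >= 1", call. = FALSE)
  w <- within_network_corr; v <- between_network_corr
  if (w == 0 && v != 0)
    stop("`between_network_corr` must be 0 when `within_network_corr` is 0",
         call. = FALSE)
  if (n_networks > 1L && abs(v) > w)
    stop(sprintf(paste0("implied network correlation matrix is not positive ",
                        "semi-definite: |between| = %.3f exceeds within = %.3f"),
                 abs(v), w), call. = FALSE)
  if (w > 0 && n_networks > 1L) {
    B <- matrix(v / w, n_networks, n_networks); diag(B) <- 1
    ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10)
      stop(sprintf(paste0("implied network correlation matrix is not positive ",
                          "semi-definite: between/within ratio %.3f requires ",
                          ">= -1/(K-1) = %.3f for K = %d networks"),
                   v / w, -1 / (n_networks - 1), n_networks), call. = FALSE)
  }
  structure(
    list(grid_shape = as.integer(grid_shape), mask_fraction = mask_fraction,
         n_frames = as.integer(n_frames), ar_coeff = ar_coeff,
         n_networks = as.integer(n_networks),
         within_network_corr = w, between_network_corr = v,
         spatial_sigma = spatial_sigma, kernel_size = as.integer(kernel_size),
         noise = noise, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("<synth_config> %dx%d grid (mask %.0f%%), T=%d, ",
                     "phi=%.2f, %d networks (r_within=%.2f, r_between=%.2f), ",
                     "sigma=%.1f px, seed=%d\n"),
              x$grid_shape[1], x$grid_shape[2], 100 * x$mask_fraction,
              x$n_frames, x$ar_coeff, x$n_networks, x$within_network_corr,
              x$between_network_corr, x$spatial_sigma, x$seed))
  invisible(x)
}

# Analytic autocorrelation time (sum over lags 0,1,2,... of squared
# autocorrelations) implied by the generator configuration. With AR(1)
# idiosyncratic noise every pixel is AR(1): tau = 1/(1-phi^2). With white
# noise the lag-k (k >= 1) pixel autocorrelation is w * phi^k.
analytic_tau <- function(config) {
  phi2 <- config$ar_coeff^2
  if (identical(config$noise, "white")) {
    w <- config$within_network_corr
    1 + w^2 * phi2 / (1 - phi2)
  } else 1 / (1 - phi2)
}

# Assign masked pixels to n contiguous vertical bands (balanced sizes).
assign_blocks <- function(mask, n_networks) {
  idx <- mask$pixel_index
  ord <- order(idx[, "col"], idx[, "row"])       # left-to-right bands
  labels <- integer(mask$n_pixels)
  sizes <- diff(round(seq(0, mask$n_pixels, length.out = n_networks + 1L)))
  labels[ord] <- rep(seq_len(n_networks), times = sizes)
  labels
}

#' Generate a synthetic dataset with planted correlation networks
#'
#' Masked pixels are split into `n_networks` spatially contiguous blocks.
#' Each block is driven by a latent AR(1) network signal; the latent signals
#' are mixed through the Cholesky factor of the network correlation matrix
#' (unit diagonal, off-diagonal `between/within`), and each pixel adds
#' independent AR(1) noise:
#' \deqn{x_p = \sqrt{w}\, S_{b(p)} + \sqrt{1-w}\, e_p,}
#' which realizes pixel-pair correlations of exactly `within_network_corr`
#' (same block) and `between_network_corr` (different blocks) before
#' smoothing. Optional Gaussian spatial smoothing (mask-renormalized) is
#' applied afterwards; because all components share the same AR(1)
#' coefficient, smoothing preserves the per-pixel autocorrelation structure,
#' so `truth_tau = 1/(1-phi^2)` holds either way.
#'
#' @param config A [synth_config()].
#' @param mask Optional [brain_mask()] overriding the default ellipse.
#' @return An object of class `"synth_dataset"`: `series` (pixel x time),
#'   `mask`, `parcellation` (planted blocks as a [parcellation()]),
#'   `truth_corr` (network-level correlation matrix, unit diagonal),
#'   `truth_within`/`truth_between` (pixel-pair targets), `truth_tau`
#'   (analytic per-pixel autocorrelation time), `block` (per-pixel network
#'   label), `config`, `seed`.
#' @examples
#' d <- generate_dataset(synth_config(grid_shape = c(12, 12), seed = 7))
#' dim(d$series)
#' @export
generate_dataset <- function(config, mask = NULL) {
  stopifnot(inherits(config, "synth_config"))
  mask <- mask %||% ellipse_mask(config$grid_shape, config$mask_fraction)
  P <- mask$n_pixels
  K <- config$n_networks
  Tn <- config$n_frames
  w <- config$within_network_corr
  v <- config$between_network_corr
  seeds <- child_seeds(config$seed, 2L)

  block <- assign_blocks(mask, K)
  S <- ar1_panel(K, Tn, config$ar_coeff, seed = seeds[1])
  if (K > 1L && w > 0) {
    B <- matrix(v / w, K, K); diag(B) <- 1
    L <- t(chol(B + diag(1e-12, K)))
    S <- L %*% S
  }
  E <- if (identical(config$noise, "white"))
    with_seed(seeds[2], matrix(rnorm(P * Tn), P, Tn))
  else ar1_panel(P, Tn, config$ar_coeff, seed = seeds[2])
  X <- if (w > 0) sqrt(w) * S[block, , drop = FALSE] + sqrt(1 - w) * E else E

  if (config$spatial_sigma > 0) {
    W <- smoothing_matrix(mask, config$kernel_size, config$spatial_sigma)
    X <- W %*% X
  }

  truth_corr <- if (K > 1L && w > 0) {
    B <- matrix(v / w, K, K); diag(B) <- 1; B
  } else diag(1, K)
  labels <- matrix(0L, mask$shape[1], mask$shape[2])
  labels[mask$pixel_index] <- block

  structure(
    list(series = X, mask = mask,
         parcellation = parcellation(labels, mask),
         truth_corr = truth_corr,
         truth_within = w, truth_between = if (K > 1L) v else NA_real_,
         truth_tau = rep(analytic_tau(config), P),
         block = block, config = config, seed = config$seed),
    class = "synth_dataset"
  )
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("<synth_dataset> %d pixels x %d frames, %d networks, seed=%d\n",
              nrow(x$series), ncol(x$series), x$config$n_networks, x$seed))
  invisible(x)
}

#' Independent dataset pair for null-hypothesis calibration
#'
#' Emulates the null-data construction of correlating every pixel of one
#' recording against a second, independent recording: two datasets drawn
#' from the same configuration but disjoint RNG streams, so all
#' cross-dataset true correlations are exactly zero.
#'
#' @param config A [synth_config()]; its `seed` field is ignored.
#' @param seed_a,seed_b Distinct integer seeds for the two datasets.
#' @return List with elements `a` and `b`, each a `synth_dataset`.
#' @export
generate_null_pair <- function(config, seed_a, seed_b) {
  stopifnot(inherits(config, "synth_config"))
  if (identical(as.integer(seed_a), as.integer(seed_b)))
    stop("`seed_a` and `seed_b` must differ (independence of the null pair)",
         call. = FALSE)
  ca <- config; ca$seed <- as.integer(seed_a)
  cb <- config; cb$seed <- as.integer(seed_b)
  list(a = generate_dataset(ca), b = generate_dataset(cb))
}

#' Turn a synthetic dataset into a raw-series object
#'
#' Convenience bridge into the preprocessing/statistics chain; sampling rate
#' is 1 Hz by construction.
#' @param dataset A `synth_dataset`.
#' @param run_id Label recorded in the series.
#' @return An [raw_series()] object.
#' @export
as_raw_series <- function(dataset, run_id = "synthetic") {
  stopifnot(inherits(dataset, "synth_dataset"))
  raw_series(dataset$series, fs = 1, mask = dataset$mask, run_id = run_id)
}
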