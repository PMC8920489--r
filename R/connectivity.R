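# Correlation matrices, Fisher transforms and seed maps.

#' Fisher z transform of correlation coefficients
#'
#' `arctanh` with `|r|` clipped to `1 - 1e-7` first, so exactly (anti)equal
#' series give a large finite value instead of `Inf`.
#'
#' @param r Correlations in `[-1, 1]` (vector or matrix).
#' @return Same shape as `r`.
#' @examples
#' fisher_z(0.5)   # 0.5493061
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

new_corr_result <- function(R, n_frames, mode, mask, mask_b = NULL) {
  structure(list(R = R, F = fisher_z(R), n_frames = n_frames, mode = mode,
                 mask = mask, mask_b = mask_b),
            class = "corr_result")
}

#' Within-run Pearson correlation matrix
#'
#' Full P x P matrix of Pearson correlations between all pairs of pixel time
#' courses, with its Fisher transform. The result is the Gram matrix of the
#' standardized rows, hence symmetric, unit-diagonal and positive
#' semi-definite.
#'
#' @param series An `ois_norm` series (T >= 5).
#' @return Object of class `"corr_result"` with elements `R`, `F` (Fisher
#'   transform, clipped at `|r| = 1 - 1e-7`), `n_frames`, `mode =
#'   "within_run"` and the mask.
#' @export
correlation_matrix <- function(series) {
  stopifnot(inherits(series, "ois_norm"))
  if (series$n_frames < 5L) stop("need at least 5 frames", call. = FALSE)
  R <- stats::cor(t(series$data))
  dup <- abs(R[lower.tri(R)]) >= 1 - 1e-7
  if (any(dup))
    warning(sprintf("%d pixel pair(s) are exact duplicates (|r| ~ 1)",
                    sum(dup)), call. = FALSE)
  new_corr_result(R, series$n_frames, "within_run", series$mask)
}

#' Cross-run (null) correlation matrix
#'
#' Correlates every pixel of one recording against every pixel of an
#' independent recording, the construction under which all true
#' correlations are zero. The result is Pa x Pb and not symmetric; no pair
#' within either recording is included.
#'
#' @param series_a,series_b `ois_norm` series with equal frame counts.
#' @return `corr_result` with `mode = "cross_null"`.
#' @export
cross_null_matrix <- function(series_a, series_b) {
  stopifnot(inherits(series_a, "ois_norm"), inherits(series_b, "ois_norm"))
  if (series_a$n_frames != series_b$n_frames)
    stop("both series must have the same number of frames", call. = FALSE)
  if (identical(series_a$data, series_b$data))
    warning("series are identical; this is a within-run matrix, not a null",
            call. = FALSE)
  R <- stats::cor(t(series_a$data), t(series_b$data))
  new_corr_result(R, series_a$n_frames, "cross_null", series_a$mask,
                  mask_b = series_b$mask)
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("<corr_result> %s: %d x %d, T=%d, R in [%.3f, %.3f]\n",
              x$mode, nrow(x$R), ncol(x$R), x$n_frames,
              min(x$R), max(x$R)))
  invisible(x)
}

#' Seed-based correlation map
#'
#' Paints one row of the correlation matrix back onto the image grid:
#' the correlation of every pixel with the chosen seed. Pixels outside the
#' mask are `NA`.
#'
#' @param corr A [correlation_matrix()] result.
#' @param seed Row index of the seed pixel (in canonical mask order).
#' @return Numeric matrix of the grid shape.
#' @export
seed_map <- function(corr, seed) {
  stopifnot(inherits(corr, "corr_result"))
  if (seed < 1L || seed > nrow(corr$R))
    stop("`seed` index out of range", call. = FALSE)
  target_mask <- corr$mask_b %||% corr$mask
  mask_to_image(target_mask, corr$R[seed, ])
}
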