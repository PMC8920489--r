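# Preprocessing chain: spatial smoothing -> bandpass/downsample -> global
# signal regression -> normalization, plus parcel averaging and run
# concatenation. Each step records itself in the series provenance and
# refuses to run twice on the same data.

#' Raw pixel-by-time series
#'
#' Container for masked hemodynamic image time series (e.g. total-hemoglobin
#' changes), one row per masked pixel in the canonical row-major order of
#' the mask.
#'
#' @param data Numeric pixel x time matrix (finite values).
#' @param fs Sampling rate in Hz.
#' @param mask A [brain_mask()]; `nrow(data)` must equal `mask$n_pixels`.
#' @param run_id Label for the run.
#' @return Object of class `"ois_raw"` with a `provenance` record.
#' @export
raw_series <- function(data, fs, mask, run_id = "run1") {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(data))) stop("`data` must be finite", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  stopifnot(inherits(mask, "brain_mask"))
  if (nrow(data) != mask$n_pixels)
    stop(sprintf("`data` has %d rows but the mask has %d pixels",
                 nrow(data), mask$n_pixels), call. = FALSE)
  structure(list(data = data, fs = fs, mask = mask, run_id = run_id,
                 provenance = character()),
            class = "ois_raw")
}

#' @export
print.ois_raw <- function(x, ...) {
  cat(sprintf("<ois_raw> %s: %d pixels x %d frames @ %g Hz [%s]\n",
              x$run_id, nrow(x$data), ncol(x$data), x$fs,
              if (length(x$provenance)) paste(x$provenance, collapse = " -> ")
              else "unprocessed"))
  invisible(x)
}

mark_step <- function(x, step) {
  if (step %in% x$provenance)
    stop(sprintf("step '%s' already applied to this series (provenance: %s)",
                 step, paste(x$provenance, collapse = " -> ")), call. = FALSE)
  x$provenance <- c(x$provenance, step)
  x
}

# Row-stochastic smoothing operator over masked pixels: entry (i, j) is the
# renormalized Gaussian weight of masked pixel j in the kernel around masked
# pixel i. Masked-out pixels contribute nothing; weights re-sum to 1 at mask
# edges.
smoothing_matrix <- function(mask, kernel_size, sigma) {
  k <- gaussian_kernel(kernel_size, sigma)
  half <- (kernel_size - 1L) / 2L
  idx <- mask$pixel_index
  # map grid coordinates -> row of the series matrix
  pos <- matrix(0L, mask$shape[1], mask$shape[2])
  pos[idx] <- seq_len(mask$n_pixels)
  P <- mask$n_pixels
  W <- matrix(0, P, P)
  off <- seq(-half, half)
  for (i in seq_len(P)) {
    r <- idx[i, 1L]; cc <- idx[i, 2L]
    rs <- r + off; cs <- cc + off
    rok <- rs >= 1L & rs <= mask$shape[1]
    cok <- cs >= 1L & cs <= mask$shape[2]
    sub <- as.matrix(expand.grid(r = rs[rok], c = cs[cok]))
    kk <- as.vector(k[rok, cok, drop = FALSE])
    j <- pos[sub]
    keep <- j > 0L
    wgt <- kk[keep] / sum(kk[keep])
    W[i, j[keep]] <- wgt
  }
  W
}

#' Gaussian spatial smoothing within the brain mask
#'
#' Convolves every frame with a truncated Gaussian kernel (default 5 x 5,
#' sigma = 1 pixel). The kernel is renormalized over the in-mask support, so
#' pixels outside the mask contribute nothing and weights always sum to 1.
#'
#' @param raw An [raw_series()].
#' @param kernel_size Odd kernel support in pixels.
#' @param sigma Kernel SD in pixels.
#' @return Smoothed `ois_raw`.
#' @export
spatial_smooth <- function(raw, kernel_size = 5L, sigma = 1) {
  stopifnot(inherits(raw, "ois_raw"))
  raw <- mark_step(raw, "spatial_smooth")
  W <- smoothing_matrix(raw$mask, kernel_size, sigma)
  raw$data <- W %*% raw$data
  raw
}

#' Zero-phase bandpass and decimation
#'
#' Applies a 4th-order Butterworth bandpass (two poles per band edge)
#' forward and backward (`signal::filtfilt`, zero phase), then decimates to
#' `target_fs` by keeping every `fs/target_fs`-th sample. The low-pass edge
#' of the band (default 0.1 Hz) is what prevents aliasing at a 1 Hz target
#' rate.
#'
#' @param raw An [raw_series()].
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param target_fs Output rate in Hz; `fs/target_fs` must be an integer.
#' @return Filtered, decimated `ois_raw` with `fs = target_fs`.
#' @export
bandpass_downsample <- function(raw, low = 0.01, high = 0.1, target_fs = 1) {
  stopifnot(inherits(raw, "ois_raw"))
  if (!(low > 0 && low < high && high < raw$fs / 2))
    stop("band must satisfy 0 < low < high < fs/2", call. = FALSE)
  if (target_fs > raw$fs) stop("`target_fs` cannot exceed fs", call. = FALSE)
  factor <- raw$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9)
    stop("fs must be an integer multiple of `target_fs`", call. = FALSE)
  factor <- as.integer(round(factor))
  raw <- mark_step(raw, "bandpass_downsample")
  bf <- signal::butter(2, c(low, high) / (raw$fs / 2), type = "pass")
  filt <- t(apply(raw$data, 1L, function(x) signal::filtfilt(bf, x)))
  raw$data <- filt[, seq(1L, ncol(filt), by = factor), drop = FALSE]
  raw$fs <- target_fs
  raw
}

#' Global signal regression
#'
#' The global signal is the mean time course over all masked pixels; it is
#' removed from every pixel by ordinary least squares (with intercept), so
#' each residual series is orthogonal to the global signal.
#'
#' @param raw An [raw_series()].
#' @return `ois_raw` of residuals (each row zero-mean).
#' @export
global_signal_regress <- function(raw) {
  stopifnot(inherits(raw, "ois_raw"))
  raw <- mark_step(raw, "global_signal_regress")
  g <- colMeans(raw$data)
  gc <- g - mean(g)
  ssg <- sum(gc^2)
  if (ssg < 1e-12 * length(gc))
    stop("global signal has (near-)zero variance; cannot regress",
         call. = FALSE)
  Xc <- raw$data - rowMeans(raw$data)
  beta <- as.vector(Xc %*% gc) / ssg
  raw$data <- Xc - tcrossprod(beta, gc)
  raw
}

#' Normalize each pixel series to zero mean and unit SD
#'
#' @param raw An [raw_series()].
#' @return Object of class `"ois_norm"`: `data` (rows standardized), `fs`,
#'   `mask`, `n_frames`, `run_id`, `provenance`.
#' @export
normalize_series <- function(raw) {
  stopifnot(inherits(raw, "ois_raw"))
  raw <- mark_step(raw, "normalize")
  sds <- apply(raw$data, 1L, stats::sd)
  bad <- which(sds < 1e-12)
  if (length(bad))
    stop(sprintf("zero-variance pixel series at row(s) %s; drop them from the mask",
                 paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  data <- (raw$data - rowMeans(raw$data)) / sds
  structure(list(data = data, fs = raw$fs, mask = raw$mask,
                 n_frames = ncol(data), run_id = raw$run_id,
                 provenance = raw$provenance,
                 run_boundaries = ncol(data)),
            class = "ois_norm")
}

#' @export
print.ois_norm <- function(x, ...) {
  cat(sprintf("<ois_norm> %s: %d pixels x %d frames @ %g Hz\n",
              x$run_id, nrow(x$data), x$n_frames, x$fs))
  invisible(x)
}

#' Parcellation label image
#'
#' @param labels Integer label image (0 = unassigned); labels may only sit
#'   on masked pixels.
#' @param mask The associated [brain_mask()].
#' @return Object of class `"ois_parcellation"` with `labels`, `parcel_ids`
#'   (sorted), `areas` (pixels per parcel), and the per-masked-pixel label
#'   vector `pixel_labels`.
#' @export
parcellation <- function(labels, mask) {
  stopifnot(is.matrix(labels), inherits(mask, "brain_mask"))
  if (!identical(dim(labels), mask$shape))
    stop("label image dimensions do not match the mask", call. = FALSE)
  if (any(labels[!mask$image] != 0L))
    stop("parcel labels found outside the brain mask", call. = FALSE)
  pix <- as.integer(labels[mask$pixel_index])
  ids <- sort(unique(pix[pix > 0L]))
  if (!length(ids)) stop("parcellation has no labelled pixels", call. = FALSE)
  areas <- vapply(ids, function(i) sum(pix == i), integer(1))
  structure(list(labels = labels, parcel_ids = ids, areas = areas,
                 pixel_labels = pix, mask = mask),
            class = "ois_parcellation")
}

#' @export
print.ois_parcellation <- function(x, ...) {
  cat(sprintf("<ois_parcellation> %d parcels, areas %d-%d px\n",
              length(x$parcel_ids), min(x$areas), max(x$areas)))
  invisible(x)
}

#' Average normalized series within parcels
#'
#' One output row per parcel: the unweighted mean of member-pixel series,
#' re-standardized to zero mean and unit SD. Parcels are ordered by sorted
#' parcel id.
#'
#' @param series An [normalize_series()] result.
#' @param parc An [parcellation()] aligned with the series mask.
#' @return `ois_norm` with one row per parcel; carries `parcellation` and
#'   the pre-normalization parcel-mean SDs as `parcel_sd`.
#' @export
parcel_average <- function(series, parc) {
  stopifnot(inherits(series, "ois_norm"), inherits(parc, "ois_parcellation"))
  if (!same_mask(series$mask, parc$mask))
    stop("parcellation mask does not match the series mask", call. = FALSE)
  means <- t(vapply(parc$parcel_ids, function(id) {
    rows <- parc$pixel_labels == id
    if (!any(rows)) stop(sprintf("parcel %d is empty", id), call. = FALSE)
    colMeans(series$data[rows, , drop = FALSE])
  }, numeric(series$n_frames)))
  sds <- apply(means, 1L, stats::sd)
  if (any(sds < 1e-12)) stop("zero-variance parcel mean", call. = FALSE)
  out <- series
  out$data <- (means - rowMeans(means)) / sds
  out$parcel_sd <- sds
  out$parcellation <- parc
  out$provenance <- c(series$provenance, "parcel_average")
  out
}

#' Concatenate runs time-wise
#'
#' Each run keeps its own normalization (every segment is already zero-mean,
#' unit-SD); total frame count is the sum over runs and run boundaries are
#' recorded in the result.
#'
#' @param runs List of `ois_norm` objects sharing mask, pixel order and fs.
#' @return `ois_norm` spanning all runs.
#' @export
concatenate_runs <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  lapply(runs, function(r) stopifnot(inherits(r, "ois_norm")))
  if (length(runs) == 1L) return(runs[[1L]])
  ref <- runs[[1L]]
  for (r in runs[-1L]) {
    if (!same_mask(ref$mask, r$mask))
      stop("all runs must share the same mask and pixel order", call. = FALSE)
    if (!isTRUE(all.equal(ref$fs, r$fs)))
      stop("all runs must share the same sampling rate", call. = FALSE)
  }
  out <- ref
  out$data <- do.call(cbind, lapply(runs, `[[`, "data"))
  out$n_frames <- ncol(out$data)
  out$run_boundaries <- vapply(runs, `[[`, integer(1), "n_frames")
  out$run_id <- paste(vapply(runs, `[[`, character(1), "run_id"),
                      collapse = "+")
  out$provenance <- c(ref$provenance, "concatenate_runs")
  out
}

#' Run the standard preprocessing chain
#'
#' Smooth -> bandpass/downsample -> global signal regression -> normalize,
#' with each stage optional. The enforced order matches the acquisition
#' pipeline: smoothing and filtering act on the raw hemodynamics, the global
#' signal is computed from the filtered data, and standardization comes
#' last.
#'
#' @param raw An [raw_series()].
#' @param smooth,filter,gsr Logical switches for the three stages.
#' @param kernel_size,sigma Smoothing parameters.
#' @param low,high,target_fs Bandpass/decimation parameters.
#' @return An `ois_norm` series.
#' @export
preprocess_run <- function(raw, smooth = TRUE, filter = TRUE, gsr = TRUE,
                           kernel_size = 5L, sigma = 1,
                           low = 0.01, high = 0.1, target_fs = 1) {
  stopifnot(inherits(raw, "ois_raw"))
  if (smooth) raw <- spatial_smooth(raw, kernel_size, sigma)
  if (filter) raw <- bandpass_downsample(raw, low, high, target_fs)
  if (gsr)    raw <- global_signal_regress(raw)
  normalize_series(raw)
}
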