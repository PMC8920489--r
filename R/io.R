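# File formats: multi-frame TIFF image stacks (32-bit float, affine scaling
# recorded in a YAML sidecar), TIFF label images for masks/parcellations,
# and exact CSV round trips for matrices.

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write a brain mask as a single-frame TIFF
#' @param mask A [brain_mask()].
#' @param path Output file (.tif).
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "brain_mask"))
  tiff::writeTIFF(mask$image * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a brain mask from a TIFF or CSV grid
#' @param path File with 0/1 pixels (.tif or .csv).
#' @return A [brain_mask()].
#' @export
read_mask <- function(path) {
  img <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    as.matrix(utils::read.csv(path, header = FALSE))
  } else {
    tiff::readTIFF(path)
  }
  brain_mask(round(img) > 0)
}

#' Write a parcellation label image as TIFF
#'
#' Labels are stored as 16-bit grey levels (label / 65535), supporting up
#' to 65535 parcels.
#' @param parc An [parcellation()] or an integer label matrix.
#' @param path Output file (.tif).
#' @export
write_labels_tiff <- function(parc, path) {
  labels <- if (inherits(parc, "ois_parcellation")) parc$labels else parc
  if (max(labels) > 65535L) stop("too many parcels for 16-bit labels",
                                 call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a parcellation label image
#' @param path TIFF written by [write_labels_tiff()].
#' @param mask The associated [brain_mask()].
#' @return An [parcellation()].
#' @export
read_labels_tiff <- function(path, mask) {
  labels <- matrix(as.integer(round(tiff::readTIFF(path) * 65535)),
                   nrow = mask$shape[1])
  parcellation(labels, mask)
}

#' Write a pixel-by-time series as a multi-frame TIFF stack
#'
#' Frames are the time axis; each frame is the masked image (off-mask
#' pixels zero). Values are affinely mapped into [0, 1] for 32-bit float
#' TIFF storage; the offset/scale, sampling rate, run id and provenance go
#' into a `<path>.yaml` sidecar that [load_run()] uses to undo the mapping.
#'
#' @param series An `ois_raw` or `ois_norm` object.
#' @param path Output file (.tif).
#' @export
write_run_tiff <- function(series, path) {
  stopifnot(inherits(series, c("ois_raw", "ois_norm")))
  data <- series$data; mask <- series$mask
  lo <- min(data); hi <- max(data)
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(ncol(data)), function(t) {
    img <- matrix(0, mask$shape[1], mask$shape[2])
    img[mask$pixel_index] <- (data[, t] - lo) / scale
    img
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  yaml::write_yaml(list(fs = series$fs, offset = lo, scale = scale,
                        run_id = series$run_id %||% "run",
                        provenance = as.list(series$provenance)),
                   sidecar_path(path))
  invisible(path)
}

#' Write a pixel-by-time series as CSV (exact round trip)
#' @param series An `ois_raw` or `ois_norm` object (or plain matrix).
#' @param path Output file (.csv).
#' @export
write_run_csv <- function(series, path) {
  data <- if (is.matrix(series)) series else series$data
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Load a run into a raw series
#'
#' Accepts a multi-frame TIFF stack written by [write_run_tiff()] (the
#' YAML sidecar supplies sampling rate and scaling) or a pixel-by-time CSV
#' written by [write_run_csv()]. Frames are flattened over the mask in the
#' canonical row-major pixel order.
#'
#' @param path Series file (.tif stack or .csv matrix).
#' @param mask_path Mask file (.tif or .csv), or a [brain_mask()].
#' @param fs Sampling rate in Hz; required for CSV input without a
#'   sidecar, otherwise read from the sidecar.
#' @param run_id Optional label override.
#' @return An [raw_series()].
#' @export
load_run <- function(path, mask_path, fs = NULL, run_id = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path),
                               call. = FALSE)
  mask <- if (inherits(mask_path, "brain_mask")) mask_path
          else read_mask(mask_path)
  meta <- if (file.exists(sidecar_path(path)))
    yaml::read_yaml(sidecar_path(path)) else list()
  fs <- fs %||% meta$fs
  if (is.null(fs)) stop("sampling rate `fs` not given and no sidecar found",
                        call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    data <- as.matrix(utils::read.csv(path))
    dimnames(data) <- NULL
    if (nrow(data) != mask$n_pixels)
      stop(sprintf("series has %d rows but the mask has %d pixels",
                   nrow(data), mask$n_pixels), call. = FALSE)
  } else {
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    if (!identical(dim(frames[[1]]), as.integer(mask$shape)))
      stop("frame dimensions do not match the mask", call. = FALSE)
    data <- vapply(frames, function(f) f[mask$pixel_index],
                   numeric(mask$n_pixels))
    if (is.null(dim(data))) data <- matrix(data, nrow = mask$n_pixels)
    off <- meta$offset %||% 0; sc <- meta$scale %||% 1
    data <- data * sc + off
  }
  raw_series(data, fs = fs, mask = mask,
             run_id = run_id %||% meta$run_id %||%
               sub("\\.[^.]+$", "", basename(path)))
}

#' Write a synthetic dataset to a directory
#'
#' Series as TIFF stack (+ CSV for exact values), mask and parcellation as
#' TIFF label images, ground-truth tables as CSV.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  raw <- as_raw_series(dataset)
  write_run_tiff(raw, file.path(dir, "series.tif"))
  write_run_csv(raw, file.path(dir, "series.csv"))
  write_mask_tiff(dataset$mask, file.path(dir, "mask.tif"))
  write_labels_tiff(dataset$parcellation, file.path(dir, "parcellation.tif"))
  utils::write.csv(dataset$truth_corr,
                   file.path(dir, "truth_network_corr.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(pixel = seq_along(dataset$truth_tau),
                              block = dataset$block,
                              tau = dataset$truth_tau),
                   file.path(dir, "truth_tau.csv"), row.names = FALSE)
  invisible(dir)
}
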