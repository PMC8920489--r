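# End-to-end pipeline: (simulate | load) -> preprocess -> correlation ->
# variance/z/p per estimator -> BY FDR, writing every stage's artifacts
# with the resolved configuration beside them.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Either `input` (a series
#' file readable by [load_run()]) or `synth` (a [synth_config()], the
#' default) provides the data. Preprocessing defaults assume input already
#' in the 1 Hz bandpassed regime (the synthetic generator's output):
#' smoothing and filtering off, global signal regression on.
#'
#' @param input Optional series path; `NULL` simulates from `synth`.
#' @param mask Optional mask path (required with `input`).
#' @param synth A [synth_config()] used when `input` is NULL.
#' @param estimators Character subset of `c("naive", "bartlett", "xdf")`.
#' @param gamma Allowed FDR level for thresholding.
#' @param gamma_grid Optional grid for the sensitivity map; NULL uses the
#'   [sensitivity_map()] default (13 log-spaced points 1e-5..1e-2); NA
#'   skips the sensitivity stage.
#' @param max_lag Maximum lag policy; NULL = `round(2*sqrt(T))`.
#' @param two_sided Bartlett effective-DOF convention.
#' @param smooth,filter,gsr Preprocessing switches.
#' @param kernel_size,sigma,low,high,target_fs Preprocessing parameters.
#' @param fs Input sampling rate override for [load_run()].
#' @param seed Root seed (simulation).
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, mask = NULL,
                            synth = synth_config(),
                            estimators = "bartlett",
                            gamma = 1e-3, gamma_grid = NULL,
                            max_lag = NULL, two_sided = TRUE,
                            smooth = FALSE, filter = FALSE, gsr = TRUE,
                            kernel_size = 5L, sigma = 1,
                            low = 0.01, high = 0.1, target_fs = 1,
                            fs = NULL, seed = 1L) {
  estimators <- match.arg(estimators, c("naive", "bartlett", "xdf"),
                          several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  src <- if (is.null(x$input)) "synthetic" else x$input
  cat(sprintf("<pipeline_config> source=%s, estimators=%s, gamma=%g, seed=%d\n",
              src, paste(x$estimators, collapse = "/"), x$gamma, x$seed))
  invisible(x)
}

#' Serialize / restore a pipeline configuration (YAML)
#'
#' Round-trips losslessly; every pipeline run writes its resolved
#' configuration (plus an md5 hash) beside the outputs.
#' @param config A [pipeline_config()].
#' @param path YAML file.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- unclass(config)
  lst$synth <- unclass(lst$synth)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  if (!is.null(lst$synth)) {
    lst$synth$grid_shape <- as.integer(unlist(lst$synth$grid_shape))
    lst$synth <- do.call(synth_config, lst$synth)
  }
  lst$estimators <- unlist(lst$estimators)
  do.call(pipeline_config, lst)
}

plog <- function(verbose, fmt, ...) {
  if (verbose) message(format(Sys.time(), "[%H:%M:%S] "), sprintf(fmt, ...))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> preprocess -> correlation ->
#' autocorrelation-corrected z scores (every requested estimator) -> BY
#' FDR (+ sensitivity map), writing each stage's artifacts under
#' `out_dir`: the resolved config (`config.yaml` + hash), tau map
#' (CSV + TIFF), per-estimator z/p/rejection matrices (CSV for small
#' pixel counts), and a `summary.json`. Deterministic given the config
#' seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Artifact directory (created).
#' @param verbose Stage banners via [message()].
#' @return Invisibly, a list with the preprocessed `series`, the per-
#'   estimator `fits`, `sensitivity` maps and the artifact paths.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  hash <- unname(tools::md5sum(cfg_path))
  writeLines(hash, file.path(out_dir, "config.md5"))
  plog(verbose, "pipeline start (config %s)", substr(hash, 1, 8))

  # --- stage: data -------------------------------------------------------
  if (is.null(config$input)) {
    sc <- config$synth; sc$seed <- config$seed
    dataset <- generate_dataset(sc)
    raw <- as_raw_series(dataset)
    plog(verbose, "simulate: %d pixels x %d frames, %d networks",
         nrow(raw$data), ncol(raw$data), sc$n_networks)
  } else {
    dataset <- NULL
    raw <- load_run(config$input, config$mask, fs = config$fs)
    plog(verbose, "load: %s (%d pixels x %d frames @ %g Hz)",
         config$input, nrow(raw$data), ncol(raw$data), raw$fs)
  }

  # --- stage: preprocess -------------------------------------------------
  series <- tryCatch(
    preprocess_run(raw, smooth = config$smooth, filter = config$filter,
                   gsr = config$gsr, kernel_size = config$kernel_size,
                   sigma = config$sigma, low = config$low,
                   high = config$high, target_fs = config$target_fs),
    error = function(e) stop("stage 'preprocess': ", conditionMessage(e),
                             call. = FALSE))
  plog(verbose, "preprocess: %s", paste(series$provenance, collapse = " -> "))

  # --- stage: statistics per estimator -----------------------------------
  fits <- list(); sens <- list()
  small <- nrow(series$data) <= 400L
  for (est in config$estimators) {
    fit <- tryCatch(
      fc_fit(series, estimator = est, gamma = config$gamma,
             max_lag = config$max_lag, two_sided = config$two_sided),
      error = function(e) stop(sprintf("stage 'stats[%s]': %s", est,
                                       conditionMessage(e)), call. = FALSE))
    fits[[est]] <- fit
    plog(verbose, "stats[%s]: <tau>=%.2f, %d/%d pairs significant (%.1f%%)",
         est, fit$acmap$mean_tau, fit$fdr$k_star, fit$fdr$n_tested,
         fit$fdr$percent_significant)
    if (small) {
      for (nm in c("R", "Z", "P"))
        utils::write.csv(fit[[nm]],
                         file.path(out_dir, sprintf("%s_%s.csv", nm, est)),
                         row.names = FALSE)
      utils::write.csv(fit$fdr$reject_mask * 1,
                       file.path(out_dir, sprintf("reject_%s.csv", est)),
                       row.names = FALSE)
    }
    if (!isTRUE(is.na(config$gamma_grid))) {
      sm <- sensitivity_map(fit$P, config$gamma_grid, mode = fit$mode)
      sens[[est]] <- sm
      plog(verbose, "fdr[%s]: rejections %d..%d across gamma %g..%g",
           est, min(sm$n_reject), max(sm$n_reject),
           min(sm$gamma_grid), max(sm$gamma_grid))
    }
  }

  # --- stage: artifacts --------------------------------------------------
  ac <- fits[[1L]]$acmap
  utils::write.csv(data.frame(pixel = seq_along(ac$tau), tau = ac$tau),
                   file.path(out_dir, "tau.csv"), row.names = FALSE)
  tau_img <- mask_to_image(series$mask, ac$tau)
  tau_img[is.na(tau_img)] <- 0
  tiff::writeTIFF(tau_img / max(tau_img), file.path(out_dir, "tau.tif"),
                  bits.per.sample = 32L)
  summary_list <- lapply(fits, function(f) {
    s <- summary(f)
    list(estimator = s$estimator, n_pixels = s$n_pixels,
         n_frames = s$n_frames, n_pairs = s$n_pairs,
         mean_tau = s$mean_tau, t_hat = s$t_hat, gamma = s$gamma,
         k_star = s$k_star, percent_significant = s$percent_significant,
         percent_above_z2 = s$percent_above_z2)
  })
  jsonlite::write_json(list(config_md5 = hash, fits = summary_list),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  plog(verbose, "pipeline done: artifacts in %s", out_dir)
  invisible(list(series = series, dataset = dataset, fits = fits,
                 sensitivity = sens, out_dir = out_dir,
                 config_md5 = hash))
}
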