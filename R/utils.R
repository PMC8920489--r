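# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' perturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds from a root seed (kept < 2^31).
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Truncated, normalized 2-D Gaussian kernel on an odd k x k support.
gaussian_kernel <- function(size, sigma) {
  if (size %% 2L == 0L) stop("`kernel_size` must be odd", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  half <- (size - 1L) / 2L
  d <- seq(-half, half)
  k <- exp(-outer(d^2, d^2, `+`) / (2 * sigma^2))
  k / sum(k)
}

# Tukey taper weights w_i = (1 + cos(pi * i / M)) / 2 for i = 0..M.
tukey_weights <- function(max_lag) {
  0.5 * (1 + cos(pi * (0:max_lag) / max_lag))
}

# Default maximum lag for tapered correlation sums: round(2 * sqrt(T)).
default_max_lag <- function(n_frames) {
  max(1L, min(n_frames - 1L, as.integer(round(2 * sqrt(n_frames)))))
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
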