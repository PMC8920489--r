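# Benjamini-Yekutieli FDR control over correlation-matrix p-values,
# FDR-sensitivity maps and false-positive summaries.

#' Benjamini-Yekutieli procedure
#'
#' Rank the p-values ascending as \eqn{p_1 \le \dots \le p_N}, and let
#' \eqn{k^*} be the largest k with
#' \deqn{p_k < \frac{k}{N} \cdot \frac{\gamma}{\sum_{j=1}^N 1/j};}
#' reject the hypotheses with the \eqn{k^*} smallest p-values. The harmonic
#' penalty makes the guarantee \eqn{FDR \le \gamma} valid under arbitrary
#' dependence, which a correlation matrix with both positive and negative
#' dependence requires. The inequality is strict, and the sort is stable on
#' (p, index) so ties at the boundary resolve deterministically: all values
#' with sort rank `<= k*` are rejected.
#'
#' @param p Vector of p-values in (0, 1].
#' @param gamma Allowed FDR level in (0, 1).
#' @return Object of class `"fdr_result"`: `gamma`, `k_star`, `p_threshold`
#'   (p-value at rank `k_star`, 0 if none), `reject` (logical in input
#'   order), `n_tested`, `percent_significant`.
#' @examples
#' by_procedure(c(0.001, 0.02, 0.04), gamma = 0.05)$k_star  # 1
#' @export
by_procedure <- function(p, gamma) {
  if (!length(p)) stop("empty p-value input", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  if (gamma <= 0 || gamma >= 1) stop("`gamma` must be in (0, 1)",
                                     call. = FALSE)
  n <- length(p)
  ord <- order(p, seq_along(p))             # stable on (p, index)
  ps <- p[ord]
  thr <- (seq_len(n) / n) * gamma / sum(1 / seq_len(n))
  ok <- which(ps < thr)
  k_star <- if (length(ok)) max(ok) else 0L
  reject <- logical(n)
  if (k_star > 0L) reject[ord[seq_len(k_star)]] <- TRUE
  structure(list(gamma = gamma, k_star = k_star,
                 p_threshold = if (k_star > 0L) ps[k_star] else 0,
                 reject = reject, n_tested = n,
                 percent_significant = 100 * k_star / n),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("<fdr_result> gamma=%g: %d / %d rejected (%.2f%%), p* = %g\n",
              x$gamma, x$k_star, x$n_tested, x$percent_significant,
              x$p_threshold))
  invisible(x)
}

# Extract the tested p-values from a p-value matrix: strict lower triangle
# for symmetric within-run matrices, every entry for cross-null matrices.
tested_entries <- function(P, mode = NULL) {
  sym <- if (!is.null(mode)) mode == "within_run" else
    nrow(P) == ncol(P) && isTRUE(all.equal(P, t(P), tolerance = 1e-12))
  if (sym) which(lower.tri(P)) else seq_along(P)
}

#' FDR thresholding of a p-value matrix
#'
#' Runs [by_procedure()] once over the whole matrix: for a symmetric
#' within-run matrix only the strict lower triangle is tested (N =
#' P(P-1)/2) and rejections are mirrored to a symmetric mask with a FALSE
#' diagonal; for a rectangular cross-null matrix every entry is a distinct
#' test.
#'
#' @param P Matrix of p-values, or a list with elements `P` and `mode` (as
#'   produced by [fc_fit()]).
#' @param gamma Allowed FDR level.
#' @param mode `"within_run"`, `"cross_null"`, or NULL to infer from
#'   symmetry.
#' @return `fdr_result` with an additional `reject_mask` matrix.
#' @export
threshold_matrix <- function(P, gamma, mode = NULL) {
  if (is.list(P) && !is.null(P$P)) { mode <- mode %||% P$mode; P <- P$P }
  stopifnot(is.matrix(P))
  idx <- tested_entries(P, mode)
  res <- by_procedure(P[idx], gamma)
  mask <- matrix(FALSE, nrow(P), ncol(P))
  mask[idx] <- res$reject
  if (length(idx) == sum(lower.tri(P)) && nrow(P) == ncol(P))
    mask <- mask | t(mask)                   # mirror the decided triangle
  res$reject_mask <- mask
  res
}

#' Minimal-FDR sensitivity map
#'
#' For each tested pair, the smallest level of a gamma grid at which the
#' pair is rejected (`Inf` if never rejected, even at the largest grid
#' level). Because the BY rejection set is nested in gamma, the map is
#' well defined.
#'
#' @param P p-value matrix (or `fc_fit` p-list as in [threshold_matrix()]).
#' @param gamma_grid Ascending levels in (0, 1); default 13 log-spaced
#'   points from 1e-5 to 1e-2.
#' @param mode See [threshold_matrix()].
#' @return List with `gamma_grid`, `min_gamma` (matrix, `Inf` where never
#'   significant; `NA` on untested entries) and the per-level rejection
#'   counts `n_reject`.
#' @export
sensitivity_map <- function(P, gamma_grid = NULL, mode = NULL) {
  if (is.list(P) && !is.null(P$P)) { mode <- mode %||% P$mode; P <- P$P }
  gamma_grid <- gamma_grid %||% 10^seq(-5, -2, length.out = 13)
  if (is.unsorted(gamma_grid, strictly = TRUE) ||
      any(gamma_grid <= 0) || any(gamma_grid >= 1))
    stop("`gamma_grid` must be strictly ascending within (0, 1)",
         call. = FALSE)
  idx <- tested_entries(P, mode)
  min_gamma <- matrix(NA_real_, nrow(P), ncol(P))
  min_gamma[idx] <- Inf
  n_reject <- integer(length(gamma_grid))
  for (i in rev(seq_along(gamma_grid))) {
    res <- threshold_matrix(P, gamma_grid[i], mode = mode)
    hit <- res$reject_mask & !is.na(min_gamma)
    min_gamma[hit] <- gamma_grid[i]
    n_reject[i] <- res$k_star
  }
  sym <- length(idx) == sum(lower.tri(P)) && nrow(P) == ncol(P)
  if (sym) {
    lower <- min_gamma; lower[upper.tri(lower)] <- t(lower)[upper.tri(lower)]
    min_gamma <- lower; diag(min_gamma) <- NA_real_
  }
  list(gamma_grid = gamma_grid, min_gamma = min_gamma, n_reject = n_reject)
}

#' Median false-positive percentage across null comparisons
#'
#' Summarizes FDR results computed on cross-null matrices (where every
#' rejection is a false positive): the per-comparison percent significant
#' and their median.
#'
#' @param results A single `fdr_result` or a list of them.
#' @return List with `percent` (per comparison) and `median_percent`.
#' @export
false_positive_summary <- function(results) {
  if (inherits(results, "fdr_result")) results <- list(results)
  stopifnot(length(results) >= 1L)
  pct <- vapply(results, function(r) {
    stopifnot(inherits(r, "fdr_result"))
    r$percent_significant
  }, numeric(1))
  list(percent = pct, median_percent = stats::median(pct))
}

#' Uncorrected fixed-threshold positive rate
#'
#' Percentage of tested pairs with `|z|` above a fixed cutoff (default 2,
#' i.e. per-test two-sided alpha ~ 0.05 with no multiplicity control) --
#' the baseline that FDR control improves on.
#'
#' @param Z z-score matrix.
#' @param z_threshold Positive cutoff.
#' @param mode See [threshold_matrix()].
#' @return Percent in `[0, 100]`.
#' @export
fwe_naive_rate <- function(Z, z_threshold = 2, mode = NULL) {
  stopifnot(is.matrix(Z))
  if (z_threshold <= 0) stop("`z_threshold` must be positive", call. = FALSE)
  idx <- tested_entries(Z, mode)
  100 * mean(abs(Z[idx]) > z_threshold)
}
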