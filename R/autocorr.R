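# Temporal-autocorrelation statistics: tapered correlation sequences,
# autocorrelation times, effective degrees of freedom, and the three
# variance estimators (naive, Bartlett, xDF) with z-scores and p-values.
#
# All sample auto- and cross-correlations use the biased normalization
# (sums divided by the full-sample sum of squares), the standard choice
# that keeps the estimated sequence positive semi-definite, and are
# truncated at a maximum lag M (default round(2*sqrt(T))) with Tukey
# tapering w_i = (1 + cos(pi i / M)) / 2 to suppress spurious long-lag
# estimates.

center <- function(x) x - mean(x)

#' Tukey-tapered sample autocorrelation sequence
#'
#' Sample autocorrelations \eqn{\hat\rho_i} for lags `0..max_lag`, each
#' multiplied by the Tukey weight \eqn{w_i = (1+\cos(\pi i/M))/2}; the
#' weight is 1 at lag 0 and 0 at lag M.
#'
#' @param x Numeric time series.
#' @param max_lag Maximum lag M (`< length(x)`); default `round(2*sqrt(T))`.
#' @return Numeric vector of length `max_lag + 1` (lags 0..M).
#' @export
tapered_autocorr <- function(x, max_lag = NULL) {
  Tn <- length(x)
  max_lag <- max_lag %||% default_max_lag(Tn)
  if (max_lag >= Tn) stop("`max_lag` must be smaller than the series length",
                          call. = FALSE)
  xc <- center(x)
  ss <- sum(xc^2)
  if (ss <= 0) stop("series has zero variance", call. = FALSE)
  rho <- c(1, vapply(seq_len(max_lag), function(k)
    sum(xc[1:(Tn - k)] * xc[(k + 1):Tn]) / ss, numeric(1)))
  rho * tukey_weights(max_lag)
}

#' Autocorrelation time of a single series
#'
#' \eqn{\tau = \sum_{i=0}^{M} (w_i \hat\rho_i)^2}: the sum of squared
#' tapered autocorrelations, truncated at `max_lag`. For white noise
#' \eqn{\tau \to 1}; for AR(1) with coefficient \eqn{\phi} the untapered
#' infinite sum is \eqn{1/(1-\phi^2)}. \eqn{\tau \ge 1} always (the lag-0
#' term contributes 1).
#'
#' @inheritParams tapered_autocorr
#' @return Scalar autocorrelation time in samples (= seconds at 1 Hz).
#' @export
autocorr_time <- function(x, max_lag = NULL) {
  sum(tapered_autocorr(x, max_lag)^2)
}

#' Per-pixel autocorrelation-time map
#'
#' Applies [autocorr_time()] to every masked pixel (vectorized over rows)
#' and records the mask average, which feeds the Bartlett effective degrees
#' of freedom.
#'
#' @param series An `ois_norm` series (or plain pixel x time matrix).
#' @param max_lag Maximum lag M; default `round(2*sqrt(T))`.
#' @return Object of class `"autocorr_map"`: `tau` (per masked pixel),
#'   `mean_tau`, `median_tau`, `max_lag`, `n_frames`, `mask` (may be NULL
#'   for plain matrices).
#' @export
autocorr_map <- function(series, max_lag = NULL) {
  if (inherits(series, "ois_norm")) {
    H <- series$data; mask <- series$mask
  } else if (is.matrix(series)) {
    H <- series; mask <- NULL
  } else stop("`series` must be an ois_norm object or a matrix",
              call. = FALSE)
  Tn <- ncol(H)
  max_lag <- max_lag %||% default_max_lag(Tn)
  if (max_lag >= Tn) stop("`max_lag` must be smaller than T", call. = FALSE)
  Hc <- H - rowMeans(H)
  ss <- rowSums(Hc^2)
  if (any(ss <= 0)) stop("zero-variance pixel series", call. = FALSE)
  w <- tukey_weights(max_lag)
  tau <- rep(1, nrow(H))                       # lag-0 term: (w_0 * 1)^2
  for (k in seq_len(max_lag)) {
    rho <- rowSums(Hc[, 1:(Tn - k), drop = FALSE] *
                   Hc[, (k + 1):Tn, drop = FALSE]) / ss
    tau <- tau + (w[k + 1L] * rho)^2
  }
  structure(list(tau = tau, mean_tau = mean(tau),
                 median_tau = stats::median(tau), max_lag = max_lag,
                 n_frames = Tn, mask = mask),
            class = "autocorr_map")
}

#' @export
print.autocorr_map <- function(x, ...) {
  cat(sprintf(paste0("<autocorr_map> %d pixels, T=%d, M=%d: tau mean %.2f, ",
                     "median %.2f, range [%.2f, %.2f]\n"),
              length(x$tau), x$n_frames, x$max_lag, x$mean_tau,
              x$median_tau, min(x$tau), max(x$tau)))
  invisible(x)
}

#' Bartlett effective degrees of freedom
#'
#' Converts the mask-average autocorrelation time into the effective sample
#' size used by Bartlett's variance correction. With `two_sided = TRUE`
#' (default) the classical Bartlett count is used,
#' \deqn{\hat T = T / (2\langle\tau\rangle - 1),}
#' i.e. the average of the double-sided sum of squared autocorrelations
#' (lags \eqn{-M..M}), which calibrates the correlation variance under the
#' null (see the methods vignette). `two_sided = FALSE` gives the
#' single-sided convention \eqn{\hat T = T / \langle\tau\rangle}.
#'
#' @param acmap An [autocorr_map()].
#' @param two_sided Use the double-sided (classical) conversion. Default
#'   `TRUE`.
#' @param tau_summary `"mean"` (default) or `"median"` summary of the
#'   per-pixel autocorrelation times.
#' @return Object of class `"effective_dof"`: `T_hat`, `T`, `mean_tau`
#'   (the summary actually used), `two_sided`, `tau_summary`.
#' @export
bartlett_edof <- function(acmap, two_sided = TRUE,
                          tau_summary = c("mean", "median")) {
  stopifnot(inherits(acmap, "autocorr_map"))
  tau_summary <- match.arg(tau_summary)
  mt <- if (tau_summary == "mean") acmap$mean_tau else acmap$median_tau
  if (mt < 1) stop("mean autocorrelation time must be >= 1", call. = FALSE)
  denom <- if (two_sided) 2 * mt - 1 else mt
  structure(list(T_hat = acmap$n_frames / denom, T = acmap$n_frames,
                 mean_tau = mt, two_sided = two_sided,
                 tau_summary = tau_summary),
            class = "effective_dof")
}

#' @export
print.effective_dof <- function(x, ...) {
  cat(sprintf("<effective_dof> T=%d, <tau>=%.3f (%s, %s) => T_hat=%.1f\n",
              x$T, x$mean_tau, x$tau_summary,
              if (x$two_sided) "two-sided" else "single-sided", x$T_hat))
  invisible(x)
}

#' Naive variance of a Pearson correlation
#'
#' Independent-samples approximation \eqn{V(R) = (1-R^2)^2/(T-3)}.
#' @param r Correlation value(s).
#' @param n_frames Sample count T (> 3).
#' @return Variance, same shape as `r`.
#' @export
variance_naive <- function(r, n_frames) {
  if (n_frames <= 3) stop("need T > 3", call. = FALSE)
  (1 - r^2)^2 / (n_frames - 3)
}

#' Bartlett variance of a Pearson correlation
#'
#' \eqn{V(R) = (1-R^2)^2 / \hat T}: the naive form with the raw sample
#' count replaced by the effective degrees of freedom.
#' @param r Correlation value(s).
#' @param edof A [bartlett_edof()] result.
#' @return Variance, same shape as `r`.
#' @export
variance_bartlett <- function(r, edof) {
  stopifnot(inherits(edof, "effective_dof"))
  (1 - r^2)^2 / edof$T_hat
}

# Tapered cross-correlation sequences for one pair; returns list with
# vectors a (rho_k(p,p)), b (rho_k(q,q)), cpos (rho_k(p,q)),
# cneg (rho_{-k}(p,q)) for k = 1..M, plus r0.
pair_corr_sequences <- function(x, y, max_lag) {
  Tn <- length(x)
  xc <- center(x); yc <- center(y)
  ssx <- sum(xc^2); ssy <- sum(yc^2)
  if (ssx <= 0 || ssy <= 0) stop("zero-variance series", call. = FALSE)
  sxy <- sqrt(ssx * ssy)
  w <- tukey_weights(max_lag)[-1L]
  ks <- seq_len(max_lag)
  a <- b <- cp <- cn <- numeric(max_lag)
  for (k in ks) {
    i1 <- 1:(Tn - k); i2 <- (k + 1):Tn
    a[k] <- sum(xc[i1] * xc[i2]) / ssx
    b[k] <- sum(yc[i1] * yc[i2]) / ssy
    cp[k] <- sum(xc[i1] * yc[i2]) / sxy   # rho_k(p, q)
    cn[k] <- sum(xc[i2] * yc[i1]) / sxy   # rho_{-k}(p, q)
  }
  list(a = w * a, b = w * b, cpos = w * cp, cneg = w * cn,
       r0 = sum(xc * yc) / sxy)
}

xdf_combine <- function(r0, a, b, cp, cn, Tn, max_lag, cross_term) {
  g <- Tn - 2 - seq_len(max_lag)
  ct <- if (cross_term == "printed") cp^2 * cn^2 else cp * cn
  raw <- ((Tn - 2) * (1 - r0^2)^2 +
            r0^2 * sum(g * (a^2 + b^2 + ct)) -
            2 * r0 * sum(g * (a + b) * (cp + cn)) +
            2 * sum(g * (a * b + cp * cn))) / Tn^2
  raw
}

#' xDF variance of a Pearson correlation for one pixel pair
#'
#' Pairwise variance estimator built from the full tapered auto- and
#' cross-correlation sequences of the two series, assuming only
#' stationarity:
#' \deqn{V = \frac{1}{T^2}\Big[(T-2)(1-R_0^2)^2
#'   + R_0^2 \sum_k (T-2-k)\big(R_k(p,p)^2 + R_k(q,q)^2 + C_k\big)
#'   - 2 R_0 \sum_k (T-2-k)\big(R_k(p,p)+R_k(q,q)\big)\big(R_k(p,q)+R_{-k}(p,q)\big)}
#' \deqn{\qquad + 2 \sum_k (T-2-k)\big(R_k(p,p)R_k(q,q) + R_k(p,q)R_{-k}(p,q)\big)\Big],}
#' with sums truncated at `max_lag` and Tukey-tapered estimates. The
#' cross term is \eqn{C_k = R_k(p,q)^2 R_{-k}(p,q)^2} by default
#' (`cross_term = "printed"`) or \eqn{R_k(p,q) R_{-k}(p,q)}
#' (`cross_term = "product"`); the two differ negligibly in the regimes
#' this package targets since the term is premultiplied by \eqn{R_0^2} and
#' is high-order in small cross-correlations.
#'
#' The result is floored at the naive variance
#' \eqn{(1-R_0^2)^2/(T-3)}; for white-noise pairs the raw formula value
#' is approximately \eqn{(T-2)/T^2}, which lies below the floor, so the
#' flag is set.
#'
#' @param x,y The two time series (equal length, nonzero variance).
#' @param max_lag Maximum lag M; default `round(2*sqrt(T))`.
#' @param cross_term `"printed"` or `"product"` (see above).
#' @return List with `V` (floored variance), `V_raw`, `floor_applied`
#'   (logical) and `r0` (the sample correlation).
#' @export
variance_xdf <- function(x, y, max_lag = NULL,
                         cross_term = c("printed", "product")) {
  cross_term <- match.arg(cross_term)
  if (length(x) != length(y))
    stop("`x` and `y` must have the same length", call. = FALSE)
  Tn <- length(x)
  max_lag <- max_lag %||% default_max_lag(Tn)
  if (max_lag >= Tn) stop("`max_lag` must be smaller than T", call. = FALSE)
  s <- pair_corr_sequences(x, y, max_lag)
  raw <- xdf_combine(s$r0, s$a, s$b, s$cpos, s$cneg, Tn, max_lag, cross_term)
  fl <- variance_naive(s$r0, Tn)
  list(V = max(raw, fl), V_raw = raw, floor_applied = raw < fl, r0 = s$r0)
}

#' xDF variance for every pair of a within-run series
#'
#' Evaluates [variance_xdf()] over all pixel pairs using per-lag matrix
#' products, so the cost is `max_lag` dense multiplications instead of a
#' per-pair loop. Diagonal entries (degenerate pairs, `|R0| ~ 1`) carry the
#' floor value and are excluded from inference downstream.
#'
#' @param series An `ois_norm` series.
#' @param max_lag Maximum lag M; default `round(2*sqrt(T))`.
#' @param cross_term See [variance_xdf()].
#' @return List with matrices `V` (floored), `V_raw`, `floor_applied`.
#' @export
variance_xdf_matrix <- function(series, max_lag = NULL,
                                cross_term = c("printed", "product")) {
  cross_term <- match.arg(cross_term)
  stopifnot(inherits(series, "ois_norm"))
  H <- series$data
  Tn <- ncol(H); P <- nrow(H)
  max_lag <- max_lag %||% default_max_lag(Tn)
  if (max_lag >= Tn) stop("`max_lag` must be smaller than T", call. = FALSE)
  Hc <- H - rowMeans(H)
  ss <- rowSums(Hc^2)
  norm <- sqrt(outer(ss, ss))
  R0 <- (Hc %*% t(Hc)) / norm
  w <- tukey_weights(max_lag)[-1L]
  u_auto_sq <- numeric(P)      # sum_k g_k a_k(p)^2
  M_ct <- matrix(0, P, P)      # sum_k g_k C_k
  M_t3 <- matrix(0, P, P)      # sum_k g_k (a_p + a_q)(c_k + d_k)
  M_aa <- matrix(0, P, P)      # sum_k g_k a_p a_q
  M_cd <- matrix(0, P, P)      # sum_k g_k c_k d_k
  for (k in seq_len(max_lag)) {
    g <- Tn - 2 - k
    Ck <- w[k] * (Hc[, 1:(Tn - k), drop = FALSE] %*%
                    t(Hc[, (k + 1):Tn, drop = FALSE])) / norm
    Dk <- t(Ck)                               # rho_{-k}(p, q)
    ak <- diag(Ck)
    u_auto_sq <- u_auto_sq + g * ak^2
    M_ct <- M_ct + g * (if (cross_term == "printed") Ck^2 * Dk^2 else Ck * Dk)
    M_t3 <- M_t3 + g * (outer(ak, ak, `+`) * (Ck + Dk))
    M_aa <- M_aa + g * outer(ak, ak)
    M_cd <- M_cd + g * Ck * Dk
  }
  U <- outer(u_auto_sq, u_auto_sq, `+`)
  raw <- ((Tn - 2) * (1 - R0^2)^2 + R0^2 * (U + M_ct) -
            2 * R0 * M_t3 + 2 * (M_aa + M_cd)) / Tn^2
  fl <- variance_naive(R0, Tn)
  list(V = pmax(raw, fl), V_raw = raw, floor_applied = raw < fl)
}

# Vectorized xDF over n independent pairs: row i of X against row i of Y.
# Internal engine for the Monte-Carlo calibration checks.
xdf_pairs <- function(X, Y, max_lag = NULL,
                      cross_term = c("printed", "product")) {
  cross_term <- match.arg(cross_term)
  stopifnot(is.matrix(X), is.matrix(Y), all(dim(X) == dim(Y)))
  Tn <- ncol(X)
  max_lag <- max_lag %||% default_max_lag(Tn)
  Xc <- X - rowMeans(X); Yc <- Y - rowMeans(Y)
  ssx <- rowSums(Xc^2); ssy <- rowSums(Yc^2)
  sxy <- sqrt(ssx * ssy)
  r0 <- rowSums(Xc * Yc) / sxy
  w <- tukey_weights(max_lag)[-1L]
  sA <- sT3 <- sT4 <- numeric(nrow(X))
  for (k in seq_len(max_lag)) {
    g <- Tn - 2 - k
    i1 <- 1:(Tn - k); i2 <- (k + 1):Tn
    a <- w[k] * rowSums(Xc[, i1, drop = FALSE] * Xc[, i2, drop = FALSE]) / ssx
    b <- w[k] * rowSums(Yc[, i1, drop = FALSE] * Yc[, i2, drop = FALSE]) / ssy
    cp <- w[k] * rowSums(Xc[, i1, drop = FALSE] * Yc[, i2, drop = FALSE]) / sxy
    cn <- w[k] * rowSums(Xc[, i2, drop = FALSE] * Yc[, i1, drop = FALSE]) / sxy
    ct <- if (cross_term == "printed") cp^2 * cn^2 else cp * cn
    sA <- sA + g * (a^2 + b^2 + ct)
    sT3 <- sT3 + g * (a + b) * (cp + cn)
    sT4 <- sT4 + g * (a * b + cp * cn)
  }
  raw <- ((Tn - 2) * (1 - r0^2)^2 + r0^2 * sA - 2 * r0 * sT3 + 2 * sT4) / Tn^2
  fl <- variance_naive(r0, Tn)
  list(V = pmax(raw, fl), V_raw = raw, floor_applied = raw < fl, r0 = r0)
}

#' z score of a Fisher-transformed correlation
#'
#' \eqn{Z = F \,(1-R^2)/\sqrt{V(R)}}, i.e. the Fisher value divided by its
#' standard error (the delta method maps the variance of R to that of F by
#' the factor \eqn{(1-R^2)^{-2}}). With the naive variance this reduces
#' exactly to \eqn{Z = \sqrt{T-3}\, F}.
#'
#' @param f Fisher-transformed correlation(s).
#' @param r Correlation(s), `|r| < 1` after clipping.
#' @param v Variance(s) of R, positive.
#' @return z score(s), same shape as the inputs.
#' @export
zscore <- function(f, r, v) {
  if (any(v <= 0)) stop("variance must be positive", call. = FALSE)
  f * (1 - r^2) / sqrt(v)
}

#' Two-tailed normal p-value
#'
#' \eqn{p = 2(1-\Phi(|z|))}, clamped below at the smallest positive
#' representable double so downstream log/ranking operations stay finite.
#'
#' @param z z score(s), finite.
#' @return p-value(s) in (0, 1].
#' @export
pvalue <- function(z) {
  if (any(!is.finite(z))) stop("z scores must be finite", call. = FALSE)
  pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
}

#' Kolmogorov-Smirnov distance from the standard normal
#'
#' One-sample KS statistic of a z-score collection against N(0, 1); used to
#' compare how well each variance estimator normalizes null-data z scores
#' (smaller is better).
#'
#' @param z Numeric vector, at least 50 values.
#' @return The KS statistic (a scalar in `[0, 1]`).
#' @export
ks_normality <- function(z) {
  z <- z[is.finite(z)]
  if (length(z) < 50L) stop("need at least 50 z values", call. = FALSE)
  unname(suppressWarnings(stats::ks.test(z, "pnorm")$statistic))
}

#' Regression of parcel autocorrelation time on parcel size
#'
#' OLS of parcel-level autocorrelation time on the characteristic length
#' (square root of the parcel area in pixels). A negative slope indicates
#' that larger parcels average down to shorter autocorrelation times.
#'
#' @param tau Per-parcel autocorrelation times: an [autocorr_map()] computed
#'   on a parcel-averaged series, or a plain numeric vector (one value per
#'   parcel, ordered by sorted parcel id).
#' @param parc The [parcellation()] (>= 3 parcels).
#' @return List with `slope`, `intercept` and Pearson `r` of tau vs
#'   sqrt(area).
#' @export
parcel_length_regression <- function(tau, parc) {
  stopifnot(inherits(parc, "ois_parcellation"))
  if (inherits(tau, "autocorr_map")) tau <- tau$tau
  if (length(tau) != length(parc$parcel_ids))
    stop("need one tau value per parcel", call. = FALSE)
  if (length(tau) < 3L) stop("need at least 3 parcels", call. = FALSE)
  len <- sqrt(parc$areas)
  fit <- stats::lm(tau ~ len)
  r <- if (stats::sd(tau) < 1e-14) 0 else stats::cor(tau, len)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]), r = r)
}
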