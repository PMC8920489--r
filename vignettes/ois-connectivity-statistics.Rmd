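---
title: "Autocorrelation-corrected significance for OIS functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autocorrelation-corrected significance for OIS functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oisconn)
```

## The statistical model

Widefield optical intrinsic signal (OIS) imaging measures hemoglobin
absorption changes over the dorsal mouse cortex, typically 128×128 pixels
at 30 Hz. After conversion to total-hemoglobin changes, smoothing,
0.01–0.1 Hz bandpass and downsampling to 1 Hz, a 5-min resting-state run
yields a normalized series $H(p,t)$, $t = 1..T$ (T = 300), at each masked
pixel $p$. Functional connectivity is the Pearson correlation
$R(p,q) = \rho(H(p,\cdot), H(q,\cdot))$.

To test $R(p,q) \ne 0$ the correlation is Fisher-transformed,
$F = \operatorname{arctanh} R$, and converted to a z score

$$Z = \frac{F\,(1 - R^2)}{\sqrt{V(R)}}, \qquad p = 2\,(1 - \Phi(|Z|)),$$

where $V(R)$ is the variance of the correlation estimate and the factor
$(1-R^2)^{-2}$ maps it to the Fisher scale by the delta method. Everything
hinges on $V(R)$.

### Why the naive variance fails

With $T$ independent samples, $V(R) \approx (1-R^2)^2/(T-3)$ and
$Z = \sqrt{T-3}\,F$. Bandpassed hemodynamics, however, are strongly
autocorrelated: each frame carries a fraction of new information. The true
variance of $R$ between two independent stationary series is approximately
$\tfrac1T \sum_k \rho_k(p)\rho_k(q)$ summed over all lags — for matched
AR(1) series with coefficient $\phi$ this is
$\tfrac1T\,(1+\phi^2)/(1-\phi^2)$, e.g. 4.6× the naive value at
$\phi = 0.8$. Naive z scores are inflated by the square root of that
factor, and their null distribution is far from N(0,1).

### Autocorrelation time and Bartlett's method

The package quantifies temporal autocorrelation per pixel as

$$\tau(p) = \sum_{i=0}^{M} \left(w_i\,\hat\rho_i(p)\right)^2,$$

the sum of squared sample autocorrelations, Tukey-tapered
($w_i = \tfrac12(1+\cos \pi i/M)$) and truncated at a maximum lag
$M$ to suppress spurious long-lag estimates. Sample autocorrelations use
the biased normalization (divide by the full-sample sum of squares), the
standard choice that keeps the estimated sequence positive semi-definite.
For white noise $\tau \to 1$; for AR(1), the untapered infinite sum is
$1/(1-\phi^2)$.

Two conventions exist for turning $\tau$ into effective degrees of
freedom, because the classical variance involves the *double-sided* lag
sum $\sum_{k=-\infty}^{\infty}\rho_k^2 = 2\tau - 1$:

* `two_sided = TRUE` (default): $\hat T = T/(2\langle\tau\rangle - 1)$.
* `two_sided = FALSE`: $\hat T = T/\langle\tau\rangle$, using the
  single-sided sum directly.

The package defaults to the two-sided (classical Bartlett) conversion
because it is the one that calibrates: in the test-suite Monte-Carlo
(5,000 independent AR(1) pairs, T = 300), the mean Bartlett variance is
within 15% of the empirical variance of $R$ at every
$\phi \in \{0, 0.5, 0.8\}$ under the two-sided convention, while the
single-sided conversion under-covers by the factor
$\langle\tau\rangle/(2\langle\tau\rangle-1)$ (about 0.6 at $\phi = 0.8$).
A calibrated null variance is also what makes null z scores close to
N(0,1), which is the property the whole inference chain rests on. The
single-sided variant is retained as an option for comparison with
implementations that use it; on real data whose $\tau$ map has a heavy
upper tail, the *mean* single-sided $\tau$ can approximate the two-sided
value of a typical pixel, which masks the difference.

Bartlett's method then sets $V(R) = (1-R^2)^2/\hat T$ with one global
$\hat T$ per run ($\langle\cdot\rangle$ is the arithmetic mean over masked
pixels; a median option is provided). It is exact only near the null and
under spatially homogeneous autocorrelation — both reasonable for mouse
OIS, where $\tau$ is far more uniform across the cortex than in human
fMRI — and it rescales every z score by the same constant
$\sqrt{\hat T/(T-3)}$.

### xDF: a pairwise variance

The xDF estimator drops the homogeneity and null assumptions, using the
full tapered auto- and cross-correlation sequences of the pair:

$$
V = \frac{1}{T^2}\Big[(T-2)(1-R_0^2)^2
  + R_0^2 \textstyle\sum_k (T-2-k)\big(R_k(p,p)^2 + R_k(q,q)^2 + C_k\big)
  - 2 R_0 \sum_k (T-2-k)\big(R_k(p,p)+R_k(q,q)\big)\big(R_k(p,q)+R_{-k}(p,q)\big)
  + 2 \sum_k (T-2-k)\big(R_k(p,p)R_k(q,q) + R_k(p,q)R_{-k}(p,q)\big)\Big]
$$

with sums truncated at $M$. The cross term defaults to
$C_k = R_k(p,q)^2 R_{-k}(p,q)^2$ (`cross_term = "printed"`), with
$C_k = R_k(p,q)R_{-k}(p,q)$ (`"product"`) available; the two differ
negligibly in practice because the term is premultiplied by $R_0^2$ and is
high-order in small cross-correlations — the Monte-Carlo calibration does
not separate them. The estimate is floored at the naive variance: for
near-white pairs the raw formula value is about $(T-2)/T^2$, which lies
just below $1/(T-3)$, and sampling noise in the lag sums would otherwise
produce anti-conservative variances. The floor flag is set exactly when
the floor binds.

At the null, Bartlett z scores are closest to normal (smallest KS
statistic), xDF close behind, naive far off — the ordering the test suite
reproduces on synthetic cross-run nulls. For strongly correlated pairs
Bartlett is conservative (it inflates $V$ regardless of $R$), whereas xDF
keeps high z scores for highly correlated data.

### Maximum lag

The tapered sums need a truncation point. The package uses
$M = \operatorname{round}(2\sqrt{T})$ (35 at T = 300), the convention of
the xDF literature: large enough that AR(1)-like tails (a few seconds at
1 Hz) are captured, small enough that the $O(M/T)$ noise accumulated by
summing squared estimates stays negligible (the white-noise bias of
$\tau$ is about $\tfrac{3M}{8T}$, i.e. < 0.01 at T = 300). `max_lag` is
exposed on every relevant function.

### FDR control over the correlation matrix

A P-pixel run yields $N = P(P-1)/2$ dependent tests (the strict lower
triangle; the diagonal is excluded). The Benjamini–Yekutieli step-up rule
rejects the $k^*$ smallest p-values where $k^*$ is the largest $k$ with

$$p_k < \frac{k}{N}\,\frac{\gamma}{\sum_{j=1}^N 1/j},$$

controlling FDR $\le \gamma$ under *arbitrary* dependence — the right
guarantee for a spatially autocorrelated matrix containing both positive
and negative correlations, where positive-dependence assumptions behind
plain Benjamini–Hochberg are not defensible. The procedure runs once over
the whole matrix, never per seed map. The harmonic sum is computed
directly. The strict inequality is implemented as stated; with a stable
sort on (p, index), ties at the boundary resolve deterministically (all
sort ranks $\le k^*$ rejected). For cross-run null matrices every entry of
the rectangular matrix is a distinct test.

`sensitivity_map()` sweeps $\gamma$ over a log-spaced grid
($10^{-5}..10^{-2}$, 13 points by default) and records the smallest level
at which each pair is rejected; BY rejection sets are nested in $\gamma$,
so the map is well defined, and pairs surviving at $10^{-5}$ vs pairs
needing more than $10^{-2}$ bracket the stable core of a network.

## The synthetic-data generator

No public OIS recordings accompany the methodology, so validation runs on
synthetic data whose ground truth is known exactly. `synth_config()`
defaults encode the target regime:

| parameter | default | meaning |
|---|---|---|
| `grid_shape`, `mask_fraction` | 32×32, 0.6 | elliptical dorsal-window mask (~616 px), desk-scale stand-in for 128×128/~10⁴ px |
| `n_frames` | 300 | one 5-min run at 1 Hz |
| `ar_coeff` | 0.75 | AR(1) coefficient; analytic $\tau = 1/(1-\phi^2) = 2.29$ s, inside the 2–3.5 s range of bandpassed cortical hemodynamics |
| `n_networks` | 2 | planted blocks, spatially contiguous bands |
| `within_network_corr` | 0.7 | pixel-pair correlation inside a block |
| `between_network_corr` | −0.3 | anticorrelation across blocks |
| `spatial_sigma`, `kernel_size` | 1 px, 5 | Gaussian spatial smoothing scale |
| `noise` | `"ar1"` | idiosyncratic noise model (see below) |

Pixels in block $b$ follow $x_p = \sqrt{w}\,S_b + \sqrt{1-w}\,e_p$, where
the latent network signals $S_b$ are AR(1) series mixed through the
Cholesky factor of the network correlation matrix (unit diagonal,
off-diagonal `between/within`; positive semi-definiteness is checked at
construction and violations name the offending ratio). This realizes the
pixel-pair targets exactly before smoothing. Because every component
shares one AR(1) coefficient, any linear operation — Cholesky mixing,
spatial smoothing, global signal regression — preserves the AR(1)
autocorrelation, so `truth_tau` stays analytic. With `noise = "white"`
the idiosyncratic term is frame-wise independent instead, emulating
low-SNR pixels whose autocorrelation time is diluted toward 1
($\tau = 1 + w^2\phi^2/(1-\phi^2)$); this is the regime in which parcel
averaging demonstrably tightens the $\tau$ map, as it does on real data.
An AR(1) process was chosen as the minimal stationary model of the
bandpassed regime; whether narrowband-filtered noise imitates real OIS
spectra better is left configurable by passing pre-made series into the
chain rather than baked into the generator.

Null data follow the cross-recording construction: `generate_null_pair()`
draws two datasets from disjoint RNG streams, so every cross-dataset
correlation is exactly zero, and `fc_null_fit()` correlates every pixel of
one against every pixel of the other. One root seed drives per-purpose
child streams; identical config + seed reproduces a dataset bit for bit.

What the generator does *not* emulate: hemoglobin spectroscopy and
path-length effects, camera noise, motion, spatially varying $\tau$,
non-stationarity within a run, and the $1/f$-ish spectral shape of real
hemodynamics. Passing tests therefore demonstrate correctness of the
statistics under the stated stationary model, not robustness to every
artifact of a real rig.

## Preprocessing conventions

The enforced order is smooth → bandpass/downsample → global signal
regression → normalize; each step records itself in the series provenance
and refuses to run twice. Choices the methodology leaves open were fixed
as follows:

* Bandpass: 4th-order Butterworth (two poles per edge) applied
  forward–backward (`signal::filtfilt`) for zero phase. Higher orders are
  numerically unstable at 0.01–0.1 Hz normalized to a 30 Hz rate. The
  0.1 Hz edge is what prevents aliasing when decimating to 1 Hz by
  keeping every $f_s$-th sample.
* Global signal regression uses OLS with intercept on the mask-mean time
  course, computed *before* per-pixel normalization; residuals are exactly
  orthogonal to the global signal.
* Zero-variance pixels raise an error listing the offending rows rather
  than being dropped silently — mask edits should be explicit.
* Pixel order is row-major over the grid, fixed at mask construction and
  shared by every matrix in the package.
* Parcel averaging takes the unweighted member mean and re-standardizes;
  concatenated runs keep per-run normalization and record boundaries.
* Correlations are clipped to $|R| \le 1 - 10^{-7}$ before
  $\operatorname{arctanh}$, so duplicate pixels warn instead of producing
  infinities; degenerate pairs are excluded from inference by the
  diagonal convention. p-values are clamped at the smallest positive
  double to keep ranking well defined.

## Validation problem sizes

The test suite and `scripts/acceptance.R` size their simulations as: BY
vs brute force on 1,000 random p-vectors (N ≤ 12, exact agreement); FDR
mixture (950 uniform nulls + 50 Beta(1,50) alternatives) × 500
replicates; variance calibration on 5,000 independent AR(1) pairs at
T = 300 per $\phi \in \{0, 0.5, 0.8\}$; null-normality KS on a 154 × 154
cross-run grid (~24k pairs); $\tau$ recovery on 200 × T = 1,000 and
100 × T = 10,000 panels; and 50 full-pipeline replicates at the default
synthetic conditions for planted-network recovery. These sizes put the
Monte-Carlo error comfortably below every asserted tolerance.

## Known limitations

* The tapered, truncated xDF runs ~10–15% below the empirical variance at
  strong autocorrelation ($\phi = 0.8$): the Tukey weights enter products
  of two tapered sequences as $w_k^2$ and shrink real tail mass. This is
  inherent to the taper-and-truncate convention, shared by reference
  implementations, and conservative in the direction of slightly inflated
  xDF z scores relative to Bartlett near the null.
* Bartlett's single global $\hat T$ ignores spatial variation in $\tau$;
  on data with a strongly heterogeneous $\tau$ map, per-pair xDF is the
  appropriate estimator despite its $O(P^2 M)$ cost (implemented as one
  dense matrix product per lag).
* FDR control is within-run; group-level inference across animals, random
  field theory, prewhitening, partial or lagged connectivity are out of
  scope.
* With planted networks, cross-dataset null correlations share a handful
  of latent signals, so a *single* null run's p-value histogram is lumpy
  even though the estimator is calibrated; calibration checks use the
  independent-pixel null for this reason.
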