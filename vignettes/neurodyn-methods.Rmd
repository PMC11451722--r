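---
title: "Methods: multiscale nonlinear dynamics and supervised tensor biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale nonlinear dynamics and supervised tensor biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodyn)
```

## Overview

`neurodyn` treats a multichannel neurophysiological recording as a set of
observables of one underlying dynamical system. Each channel is split into
dyadic frequency bands; each band series is characterized by a vector of
dynamical invariants — band power, the nine recurrence-quantification (RQA)
measures, sample entropy, correlation dimension, the DFA and Hurst scaling
exponents and the largest Lyapunov exponent (15 measures by default, with
approximate and permutation entropy and a recurrence-network block
available). Stacking subjects gives a fourth-order tensor, subjects x
sensors x bands x measures. Canonical polyadic (CP) decomposition extracts
a small number of latent factors; an optional supervision term aligns one
factor with a behavioral target such as age; cross-validated regression
maps factor scores to the target and reports the pooled Pearson r and mean
absolute error.

The package is fully testable without clinical data: canonical dynamical
systems (Lorenz, logistic map, sinusoids, white/pink noise, Brownian
motion, fractional Gaussian noise) provide analytic ground truth, and an
age-modulated synthetic cohort exercises the end-to-end biomarker chain.

## Phase-space reconstruction and recurrence analysis

A scalar series is embedded by the method of delays,
\(\mathbf{p}_i = (x_i, x_{i+\tau}, \dots, x_{i+(m-1)\tau})\). The delay
\(\tau\) defaults to the first zero of the autocorrelation function (a
sample estimate within \(1.96/\sqrt{n}\) of zero counts as zero, so
analytic zero crossings are not missed by finite-sample jitter);
`1/e`-decay and mutual-information minima are alternatives. The embedding
dimension can be chosen by the Kennel false-nearest-neighbor criterion
(tolerances 10 and 2, threshold 5 %); feature extraction uses a fixed
default \(m = 3\) for every band series so that measure values are
comparable across bands and subjects.

The recurrence matrix marks pairs of embedded points within distance
\(\varepsilon\). Following standard practice the threshold is set
indirectly through a fixed recurrence rate, default 0.05: \(\varepsilon\)
is the empirical 0.05-quantile (inverse CDF) of the off-diagonal pairwise
distances, with pairs inside the Theiler window \(|i-j| \le \tau\)
excluded from the bookkeeping.

One numerical subtlety matters. Distances numerically equal to the
quantile (relative tolerance 1e-9) are included *as a whole tie class*.
For generic signals the distance distribution is continuous, the tie class
is a single pair, and the achieved density equals the target within the
quantile granularity (±0.005 for 100+ points). But degenerate inputs exist
whose distance distribution has large atoms — a sinusoid sampled at an
exact integer number of samples per period visits only that many distinct
embedded points. A naive quantile then slices an atom at floating-point
noise level and scatters an arbitrary subset of mathematically identical
pairs into the plot as isolated points, biasing the line-based measures
(determinism drops by ~5 % for such a sinusoid). With whole-class
inclusion the threshold never splits a tie: the achieved rate for such
inputs is the nearest attainable tie-class boundary at or above the
target, and a pure sinusoid scores DET = 1 exactly. For atomic
distributions no threshold can satisfy the ±0.005 density band in
general; the density invariant is therefore stated for tie-free
(continuous-distance) inputs.

Line histograms are computed on the matrix with the line of identity and
the Theiler band zeroed, so diagonal and vertical structures are counted
on the same matrix that density bookkeeping uses. Diagonal lines are
scanned on one triangle and doubled (the matrix is symmetric). The nine
measures follow the standard definitions: RR; DET and LAM as the fraction
of recurrence points on diagonal/vertical lines of length at least
`lmin = 2`; mean and maximal diagonal length; Shannon entropies (natural
log) of the diagonal and vertical length distributions at `lmin`; trapping
time as the mean vertical length; and the entropy of the white-vertical
(recurrence-time) distribution, which uses all lengths >= 1 since a
minimum length has no standard meaning for recurrence times. Empty
histograms yield flagged zeros rather than NaN so tensors stay dense.

Two geometric facts discovered in testing are worth recording. First,
with delay 1 and \(m > 1\), neighboring diagonal recurrences share
\(m - 1\) coordinates, which inflates DET for i.i.d. noise to ~0.57; with
\(m = 1\) or any delay >= 2 the expected low value (< 0.3) appears. This
is embedding geometry, not an artifact of the implementation. Second, the
recurrence-network interpretation simply zeroes the diagonal (and Theiler
band) and reads the matrix as an adjacency; its measures (density,
transitivity, mean local clustering, average path length on the largest
component, global efficiency, mean betweenness) go through igraph, with
exact computation up to 2,000 nodes and a seeded node subsample beyond.

## Direct invariants

*Sample entropy* uses Chebyshev distance, template length \(m = 2\) and
tolerance \(r = 0.2\,\mathrm{SD}\) of the band series (resolved against
the band, not the broadband signal, because band amplitudes differ by
orders of magnitude). Both the \(m\)- and \((m+1)\)-counts range over the
\(n - m\) templates that have a continuation, self-matches excluded.
Approximate entropy follows the Pincus construction with self-matches
included; permutation entropy uses ordinal patterns of order 3 with ties
broken by order of occurrence (stable sort).

*Correlation dimension* is the Grassberger–Procaccia slope of
\(\log C(\varepsilon)\) against \(\log \varepsilon\). The radii grid is
log-spaced between the \(5\times10^{-4}\) and 0.05 distance quantiles —
the scaling regime lives at small scales; radii near the median visibly
flatten the slope (a Lorenz attractor drops from ~2.05 to ~1.7). Within
the grid the contiguous window (at least half the radii) with the best
\(R^2\) is used; if no window reaches \(R^2 = 0.9\) the value is a flagged
zero.

*DFA* integrates the series, detrends non-overlapping windows (taken from
both ends so the whole profile is used) with a linear fit by default, and
regresses log RMS fluctuation on log scale over ~12 log-spaced scales
between 8 and \(n/4\).

*The Hurst exponent* uses classic rescaled-range analysis over dyadic
windows (64 and larger — R/S statistics on shorter windows are dominated
by small-sample bias, which depresses estimates for persistent series)
with the Anis–Lloyd–Peters correction: H is 0.5 plus
the slope of \(\log(R/S) - \log E[R/S \mid \text{iid}]\) against log
window size. The uncorrected slope is biased upward by about +0.05 even at
\(n = 10^4\) and would misreport white noise; the corrected estimator
recovers 0.5 for uncorrelated input and tracks the fGn generator within
±0.1 at H = 0.8.

*The largest Lyapunov exponent* follows Rosenstein's method: nearest
neighbors outside a temporal exclusion window (the mean period estimated
from mean crossings), mean log divergence over k steps, slope of the
initial linear region. The default fit range ends where the divergence
curve first comes within 0.5 nats of its saturation level, which suits
maps (the fully chaotic logistic map yields ln 2 within a few percent).
Flows sampled densely need an explicit post-transient range — for Lorenz
x at dt = 0.01 the early steps are dominated by neighbor geometry and the
benchmark value 0.9/s appears in the range of roughly steps 50–250.
Neighbor separations at floating-point noise level (exactly recurring
trajectories) are reported as a flagged zero: such distances carry no
dynamical information.

*Fractional Gaussian noise* is synthesized exactly by circulant embedding
(Davies–Harte): with coefficients \(\sqrt{\lambda_k/M}\) on the FFT of the
autocovariance's circulant row, the real part has covariance exactly
\(\gamma(h)\). Small negative eigenvalues from rounding are clipped at 0.

## Band decomposition

Bands are wavelet details of an orthonormal periodic DWT; detail level j
spans \((f_s/2^{j+1}, f_s/2^j]\) Hz and each band is reconstructed to full
time resolution so every downstream measure operates on a common sampling
grid. The band series plus the residual approximation sum to the input
exactly, and coefficient energy is conserved.

The Haar filter has a special status: its approximation coefficients equal
coarse-grained (multiscale) means times \(2^{k/2}\), which the package
verifies exactly, and `dwt_decompose()` therefore defaults to Haar. For
*band splitting*, however, Haar's two-tap details leak roughly half of a
mid-band sinusoid's energy into neighboring bands, which makes nominal
band labels misleading; `to_band_signals()` therefore defaults to the
16-tap `db8` filter (94 % in-band concentration for a 10 Hz tone at 250
Hz), with haar/db2/db4 selectable. Six bands are named by overlap with the
clinical delta/theta/alpha/beta/gamma ranges, duplicates suffixed
(`gamma2`, `gamma1`); whether a sixth band should instead be the final
approximation is exposed via `include_approx`.

## The feature tensor and its factorization

`extract_features()` produces one measure vector per (channel, band);
failures (constant or too-short band series, empty histograms, missing
scaling regions) are flagged placeholder zeros, and the flags travel into
the tensor's mask. Measures are z-scored per measure slice over unmasked
cells before factorization (they span incompatible scales); constant
slices are flagged and zeroed, and the stored center/scale allow exact
inversion and — importantly for cross-validation — application of
training-fold statistics to held-out subjects.

CP-ALS minimizes the masked reconstruction error with EM imputation
(masked cells are refilled with the current reconstruction each sweep, so
they never influence the fit; perturbing them provably changes nothing).
Initialization is the best of 5 seeded random starts; convergence is a
relative objective change below 1e-8 or 500 sweeps. Non-subject factor
columns are renormalized to unit length every update with the scale
absorbed into the subject mode, and the final model is reported with unit
columns, weights in descending order, and signs fixed so each non-subject
column's dominant loading is positive — all deterministic given the seed.

### Supervision

The supervised variant designates one component as target-aligned: its
subject scores \(u\) are shrunk toward the span of the standardized target
and covariates by adding \(\gamma\,\|u - W\beta\|^2\) (ridge on
\(\beta\)) to the objective, alternating the \(\beta\) regression with the
factor updates. At \(\gamma = 0\) this is exactly the unsupervised
factorization (one code path); at large \(\gamma\) the designated
component's loadings converge to the target-covariant feature pattern
while the remaining components model the dominant residual structure.

This design was not the first attempt, and the reason is instructive. A
coupled-regression objective of the form
\(\|T - [[\lambda; A,B,C,D]]\|^2 + \gamma\|y - A\beta\|^2\) looks natural
but is vacuous for out-of-sample use: \(A\) has \(N \times R\) free
parameters against \(N\) target constraints, so ALS interpolates \(y\)
at negligible reconstruction cost at *any* coupling weight — the
in-sample score fit is perfect while the sensor/band/measure loadings
(the only thing a held-out subject can be projected onto) remain exactly
as unsupervised. Shrinking *all* score columns toward the target span
instead collapses the score Gram matrix and the ALS normal equations
become singular. Pinning a single component is the simplest member of the
SupCP family that avoids both failure modes and still reduces exactly to
CP at \(\gamma = 0\). The default \(\gamma = 1\) charges off-target score
variance of that component one-for-one against the reconstruction it
buys.

### Out-of-sample scores and the cross-validation protocol

Held-out subjects are scored by least squares against the weighted
Khatri–Rao basis of the non-subject factors, per subject and restricted
to unmasked cells; no target information is involved. Within
`cv_factor_regress()` each training fold gets its own normalization
statistics, its own factorization (supervised on training targets only)
and its own regressor; the regressor is trained on *projected* training
scores so that training and test scores follow the identical computation
path (ALS scores additionally carry the supervision pull and are
distributed differently from anything computable for a new subject).
Corrupting held-out targets provably leaves that fold's predictions
unchanged. Predictions are pooled over folds for the reported r, p and
MAE; per-fold correlations are also returned. Regressors: random forest
(randomForest, 500 trees), gradient boosting (xgboost, 200 rounds, depth
3, learning rate 0.1, single thread for determinism) and a linear model,
all seeded.

## The synthetic cohort: what it emulates, what it does not

Each subject's channel is a sum over bands of
\(w_b(a)\,[(1-c_b(a))\,\text{osc}_b + c_b(a)\,\text{noise}_b]\) plus
broadband measurement noise, where \(a\) is age scaled to the cohort
range, \(\text{osc}_b\) is a band-center sinusoid with random phase and
\(\text{noise}_b\) is unit-SD band-limited noise. The age effect model
follows the canonical developmental EEG picture over the emulated span
(6–84 months, uniform grid; matching the age span of typical infancy
to-childhood cohorts): posterior-dominant fast rhythms strengthen
(alpha weight 0.5 + 1.0a, beta 0.4 + 0.8a), slow activity recedes (theta
1.2 − 0.7a, delta 1.4 − 0.9a), and signal complexity rises (noise mixing
fraction 0.25 + 0.5a). Fixed spatial gains (alpha posterior-dominant,
beta frontal) give the sensor mode real structure. Development across
this span dominates real infant EEG, so the designed effect is strong;
nuisance variance is deliberately *structured*: a per-subject global
amplitude factor (lognormal, sd 0.25 at the default noise level — skull
and tissue conductivity differences scale all channels jointly) and a
shared per-subject complexity offset (sd 0.125) are rank-1 in the subject
mode, which is precisely the kind of age-independent variance that
unsupervised factorization latches onto; small per-band weight jitter and
broadband noise (sd 0.05 and 0.075 at default) represent unstructured
measurement variability. A single knob `noise_sd` scales all four
sources, so `noise_sd = 0` gives strictly monotone designed band
statistics. All randomness flows from one seed through independent
per-subject streams, so subsets reproduce exactly.

What the generator does *not* emulate: volume conduction and realistic
forward models, eyeblink/EMG artifacts, line noise, non-stationarity
within a recording, heteroscedastic age effects, or any preprocessing
pipeline. A passing end-to-end test therefore demonstrates that the
machinery recovers a planted, monotone, low-rank age effect under
realistic nuisance structure — not that it would survive raw clinical
recordings unpreprocessed.

Desk-scale problem sizes were chosen once: the recovery experiment uses
40 subjects, 4 channels (F3, F4, O1, O2), 4 s at 64 Hz, rank 3, 5-fold
cross-validation, 10 generator seeds; the feature-count check uses one
19-channel, 8 s recording at 250 Hz. On these sizes the supervised
pipeline reaches pooled held-out r near 0.9 with unsupervised factors
substantially lower, mirroring the supervised/unsupervised contrast the
framework is designed to expose.

## Defaults worth knowing

| Parameter | Default | Meaning |
|---|---|---|
| `target_rr` | 0.05 | fixed recurrence rate for thresholding |
| `lmin` | 2 | minimal diagonal/vertical line length |
| Theiler window | \(\tau\) | temporal exclusion around the diagonal |
| `embed_m` | 3 | embedding dimension for band features |
| `entropy_m`, `entropy_r` | 2, 0.2 SD | sample/approximate entropy template and tolerance |
| `n_bands`, wavelet | 6, db8 | dyadic band split for features |
| `max_points` | 1500 | cap on embedded points in quadratic-cost measures |
| rank, \(\gamma\) | 3, 1 | CP rank and supervision trade-off |
| k, regressor | 5, random forest | cross-validation |

## Known limitations

- The fixed-RR density guarantee is stated for continuous distance
  distributions; atomic distributions (exactly periodic inputs) achieve
  the nearest tie-class boundary instead.
- Lyapunov estimates for densely sampled flows need a user-chosen fit
  range; the automatic rule is designed for maps and band-limited
  signals.
- The FNN dimension selector is exposed but not run per band series in
  `extract_features()` (a fixed \(m\) keeps measures comparable and
  runtime linear in the number of series).
- CP-ALS finds local optima; multiple seeded starts mitigate but do not
  eliminate this, and factor congruence tests are run on exact-rank
  constructions where the global optimum is known.
- Betweenness on recurrence networks beyond 2,000 nodes uses a seeded
  node subsample.
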