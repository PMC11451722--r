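# neurodyn

Multiscale nonlinear dynamics and supervised tensor biomarkers for
multichannel neurophysiological (EEG-like) recordings.

Scalp recordings are time-series measurements of an underlying neural
dynamical system. By the embedding theorems, the geometry of that system's
phase portrait can be reconstructed from each channel by the method of
delays, and quantified by *dynamical invariants*. `neurodyn` computes, per
channel and per frequency band:

- **band power** — mean squared amplitude of the wavelet-detail band
  series;
- **recurrence quantification** from fixed-recurrence-rate recurrence
  plots (recurrence rate RR, determinism DET, laminarity LAM, mean/max
  diagonal line length, line-length entropy, trapping time, vertical and
  recurrence-time entropies), plus recurrence-*network* measures
  (clustering, efficiency, betweenness) from the same matrix read as a
  graph adjacency;
- **complexity and scaling exponents** — sample/approximate/permutation
  entropy, Grassberger–Procaccia correlation dimension D2, DFA exponent,
  rescaled-range Hurst exponent, and the largest Lyapunov exponent
  (Rosenstein method).

The default 15-measure set over `Ns` sensors and `Nf` bands yields a
subject feature vector that is naturally a third-order array; a cohort is
the fourth-order tensor `N x Ns x Nf x Nm`. Canonical polyadic (CP)
decomposition compresses it to a few latent factors,

`T  ≈  Σ_r  w_r ·  a_r ∘ b_r ∘ c_r ∘ d_r ,`

whose subject scores are candidate digital biomarkers. A supervised
variant shrinks one component's subject scores toward the span of a
behavioral target (e.g. age) and covariates, so that component's loadings
converge to the target-covariant feature pattern; `gamma = 0` is exactly
the unsupervised factorization. Factor scores are mapped to the target by
seeded k-fold cross-validated regression (random forest, gradient
boosting, or linear), with per-fold factorization and projection so no
target information leaks into held-out scores.

A synthetic-signal module (Lorenz, logistic map, sinusoids, white/pink
noise, Brownian motion, fractional Gaussian noise) and an age-modulated
synthetic EEG cohort generator make every stage testable with known
ground truth — no clinical data required.

## Worked example

Simulate a 40-subject developmental cohort, extract features, build the
tensor and compare supervised with unsupervised latent factors:

```r
library(neurodyn)

co  <- generate_cohort(n_subjects = 40, seed = 1)
age <- co$cohort$age_months

ft <- lapply(co$recordings, extract_features)
x  <- assemble_tensor(ft, co$cohort)
x
#> <neurodyn_tensor> 40 subjects x 4 sensors x 6 bands x 15 measures (0.2% masked)

sup   <- cv_factor_regress(x, age, rank = 3, supervised = TRUE,  seed = 1)
unsup <- cv_factor_regress(x, age, rank = 3, supervised = FALSE, seed = 1)
sup
#> <neurodyn_prediction> random_forest, 5 folds: r = 0.878 (p = 9.87e-14), MAE = 9.43
unsup
#> <neurodyn_prediction> random_forest, 5 folds: r = 0.505 (p = 0.0009), MAE = 16.60
```

The pooled held-out correlation with age is high when the factorization is
supervised by the training folds' ages and substantially lower when the
factors are extracted unsupervised — the generator plants a strong
monotone age effect, but also large age-independent amplitude and
complexity differences between subjects, and the unsupervised factors
spend their rank on that nuisance variance. MAE is in months.

Single-series invariants work standalone:

```r
lg <- generate_system("logistic", 3000, params = list(r = 4))
lyapunov_max(lg$data[1, ], m = 1, tau = 1)   # ~ log(2) = 0.693 for r = 4
#> [1] 0.6827573

x  <- generate_system("sine", 2000, params = list(frequency = 10), fs = 250)
e  <- delay_embed(x$data[1, ], m = 3, tau = 6)
rp <- recurrence_matrix(e, target_rr = 0.05, theiler = 6)
rqa_measures(rp)["DET"]                       # a pure tone is fully deterministic
#> DET
#>   1
```

The same pipeline runs from the shell over a directory of recordings
(CSV or EDF):

```sh
exec/neurodyn all --out run1 --subjects 40 --seed 1
exec/neurodyn predict --out run1 --unsupervised --force
```

Each stage (`simulate`, `features`, `tensor`, `factorize`, `predict`)
persists its artifacts and is resumable.

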