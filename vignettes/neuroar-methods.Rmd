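---
title: "Models and methods behind neuroar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neuroar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The modeling problem

`neuroar` benchmarks subject-specific auto-regressive models of
parcellated BOLD signals. A run is a `T x P` matrix `X` (time points by
parcels, sampled every TR seconds). The task is one-step-ahead prediction:
a model `f` maps the `k` most recent time points of all parcels to the next
time point, trained by minimizing mean squared error. Forecasts at lag
`l > 1` are produced by *iterated single-step prediction*: the model's own
outputs replace the unavailable true values as the window slides forward,
so a lag-3 forecast of time `t` uses true data up to `t - 3` and the
model's lag-1 and lag-2 predictions for `t - 2` and `t - 1`. Accuracy is
the per-parcel coefficient of determination R², averaged over an evaluation
parcel mask; R² is negative when a model does worse than predicting the
run's mean.

The model zoo spans the families whose contrast is scientifically
informative:

* **linear_uni** — each parcel predicted from its own `k` past values
  (independent weights per parcel; `P (k + 1)` parameters with bias);
* **linear_multi** — the classical VAR, every parcel predicted from the
  full window (`P (k P + 1)` parameters);
* **mlp_uni / mlp_multi** — the same two wirings with hidden ReLU layers;
* **chebnet** — a graph convolutional network: the `k` window steps enter
  as `k` channels per node and each layer computes
  `sum_{j<K} T_j(L~) X theta_j + b`, where `T_j` are Chebyshev polynomials
  of the scaled graph Laplacian evaluated by the three-term recurrence
  (never by eigendecomposition), with optional ReLU between layers. Setting
  `nonlinear = FALSE` yields the *linear Chebnet*, which is exactly a
  node-shared polynomial graph filter.

## Graph priors

The Chebnet's graph is a binary symmetric parcel connectome at fixed edge
density (default 10%): *functional* (top pairs by signed Pearson
correlation on the training runs — an absolute-value mode exists behind the
`binarize_top_density` weights argument by passing `abs(C)`), *spatial*
(closest pairs of parcel centroids), or *random* (uniform without
replacement, seeded). Ties at the density threshold are broken by (row,
column) order so graphs are bit-reproducible. The spectral operator is the
symmetric normalized Laplacian `L = I - D^{-1/2} A D^{-1/2}` with isolated
nodes assigned `D^{-1/2} = 0` (their row of `L` is an identity row),
rescaled as `L~ = (2 / lambda_max) L - I` with `lambda_max` from a dense
symmetric eigensolve (exact and cheap at desk scale, `P <= 1000`); an
edgeless graph uses the `lambda_max = 2` convention, making `L~ = 0` so
every filter is purely local. The spectrum of `L~` then lies in `[-1, 1]`,
the domain of Chebyshev polynomials.

## The synthetic cohort generator

No public data matches the density the benchmark assumes, so the package
generates cohorts whose statistical structure mirrors what the analyses
assume, with full ground truth. Each subject's intrinsic dynamics follow a
stable VAR(p) on a sparse symmetric support graph; the observed signal is

```
X_t = V_t + shared_t,   V_t = sum_j A_j V_{t-j} + eps_t
```

with i.i.d. Gaussian innovations. Design choices that matter:

* **Exact stability.** Scaling `A_j -> c^j A_j` scales every eigenvalue of
  the VAR companion matrix by `c`, so coefficients are rescaled to hit the
  target spectral radius (default 0.9) exactly; all cohorts are provably
  stationary.
* **Positive off-diagonal couplings.** Off-support entries are zero;
  on-support couplings are drawn half-normal (positive), and diagonal
  self-couplings are always present and positive. A Chebyshev graph filter
  aggregates neighbors with shared non-negative weights; with zero-mean
  coupling signs that aggregate is orthogonal in expectation to the true
  dynamics, and graph identity could not matter at all — a degenerate
  emulation. Positive couplings mirror what top-decile
  functional-connectivity edges capture in real BOLD: predominantly
  positive co-fluctuation.
* **Shared response additive on the output.** The stimulus-evoked
  component (low-pass filtered Gaussian noise, standardized, default
  amplitude 0.5 SD units, cutoff 0.05 Hz) is identical across subjects
  within a (condition, run) and is added *outside* the recursion. Injected
  inside, the VAR would propagate a filtered copy of the shared history,
  making it impossible to remove by subtraction or regression — the
  leave-one-subject-out analyses assume the evoked response is a common
  signal superimposed on intrinsic dynamics, and the generator realizes
  exactly that. Rest-like conditions have amplitude 0.
* **Subject divergence.** Subject couplings are `(1 - d) base + d fresh`
  (rescaled), with the fresh draw on the *same* support, so a cohort has
  one true support graph; `d = 0` gives identical subjects (the null for
  specificity tests), `d = 1` fully individual dynamics. Default 0.5.
* **Burn-in 200 samples** erases the zero initial state (more than five
  autocorrelation time constants at radius 0.95 or below).
* **Defaults** mirror the benchmark's shape at desk scale: 6 subjects, 30
  parcels, 68 movie-like runs (44/12/12 after the split) plus 5 rest runs
  of 480 points at TR 1.49 s; a 197-parcel layout is a config change.

What the generator does **not** emulate: hemodynamic convolution,
physiological noise and motion artifacts, non-stationarity, heavy-tailed
innovations, and spatially structured measurement noise. Passing tests
therefore validate the *pipeline and its claims under the stated generative
assumptions*, not performance on real BOLD.

## Preprocessing conventions

Runs are high-pass filtered at 0.01 Hz by removing the least-squares
projection onto DCT-II regressors with frequency below the cutoff (plus the
constant), then z-scored per run using the *population* standard deviation
— one convention fixed for bit-reproducibility. Windows are built after
normalization and never span run boundaries. The run split takes the first
`ceil(f n)` runs for training and alternates the remainder validation/test
from 0-based even positions, the deterministic analog of an even/odd
episode split; the basis of the alternation is a documented choice, not a
claim. The cross-subject shared response is estimated leave-one-subject-out
as the per-(condition, run) mean of the other subjects' normalized series
and regressed out per run and per parcel with an intercept (per-run
granularity matches the per-run normalization pipeline; a sensitivity check
over concatenated-run regression is future work).

## Training and model selection

All families train with Adam (conventional moments, `beta1 = 0.9`,
`beta2 = 0.999`, `eps = 1e-8`, no weight decay) on MSE, with analytic
gradients implemented per family; the Chebyshev layer's backward pass uses
a Clenshaw-style adjoint of the three-term recurrence, so no Laplacian
polynomial is ever materialized. Weights initialize uniform with fan-in
scaling from the config seed; minibatch shuffles derive from the training
seed; every run of `fit_model` is bit-reproducible. When a validation set
is supplied, the returned parameters are the best-validation-epoch
checkpoint — a conservative choice in place of explicit early stopping.
Hyper-parameter search (`grid_search`) scores each configuration by mean
validation R² over subjects, parcels, and the requested lags, shares the
training randomness across configurations so comparisons are paired (and
exact duplicates tie, resolved first-in-grid), and skips configurations
that diverge. A direct multi-lag mode (`fit_direct_multilag`) trains one
independent model per lag as the alternative to iterated prediction.

## Evaluation and statistics

R² uses the evaluated targets' own mean as the baseline (the
predict-the-run-mean reading of a naive model); negative values are
retained in averages, with masking left to the caller. Aggregation order is
fixed: mean over parcels within a run, then across runs. Subject
specificity compares, for every ordered subject pair and matched test run,
the model's R² on its own subject versus the other subject; per-pair
two-sided Wilcoxon signed-rank tests over runs are Benjamini-Hochberg
corrected across pairs. The Wilcoxon p-value is exact for `n <= 25` — the
null distribution of the signed-rank statistic is built by dynamic
programming over doubled (average) ranks, which handles ties and equals
full `2^n` enumeration — and uses the normal approximation with tie and
continuity correction above. Note that with fully divergent subjects the
per-subject noise ceiling varies, so individual ordered pairs can be
negative even under genuine specificity; the cohort-level mean difference
is the stable quantity, mirroring how subject-level exceptions appear in
real data.

## Prediction dynamics

Power spectra are plain per-column periodograms (`|DFT|^2`, no detrending
or tapering) on the one-sided grid; the high-frequency fraction sums
folded two-sided power above a cutoff (0.025 Hz in the lag analyses)
relative to total power, pooling parcels by power (not magnitude)
averaging. Iterated predictions are aligned to target time indices by
construction, so spectra at different lags describe the same time span.
Seed-based connectivity correlates a (possibly predicted) seed parcel
signal with all original parcel signals; maps are compared after
thresholding to the top fraction of parcels (ties broken by index). At desk
scale a top-10% mask of 30 parcels is only 3 parcels, so the
mask-preservation analysis uses the top 20% (6 parcels) — a granularity at
which overlap is meaningfully assertable.

## Problem sizes and numerical guards

The test and acceptance workloads run cohorts of 20-30 parcels with runs of
240 points and 6-26 runs, 10 cohort seeds for the graph-sensitivity and
specificity properties and 5 for the spectral ones — the package's chosen
desk-scale study conditions; parameter-recovery checks use single runs of
10,000 points. Degenerate inputs fail loudly with typed conditions:
constant parcels (z-scoring, correlation), explosive couplings (simulation
names the first bad time index), shapes that do not match a model's
contract, diverging optimizations (epoch and learning rate reported), and
undefined R² or power fractions. Coupling draws whose rescaling degenerates
are retried on an incremented sub-seed (at most 100 times). All randomness
flows from one base seed through named substreams (`substream_seed`), so
any stage can be reproduced in isolation.

## Known limitations

Training is plain R matrix arithmetic: adequate for desk-scale benchmarks
(seconds per model), not for 197 parcels x 9 h of data on a deadline. The
generator's linearity means non-linear families can at best match the
linear ones on synthetic cohorts — informative as a null (and consistent
with linear Chebnets matching non-linear ones), but not evidence about
non-linear structure in real BOLD. Recurrent and attention-based families
are out of scope; the `forward`/`fit` contract accepts external model
plug-ins should they be needed.
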