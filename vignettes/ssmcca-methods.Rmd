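---
title: "Structured sparse multiset CCA: model, tuning and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured sparse multiset CCA: model, tuning and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmcca)
```

## The problem

Concurrent EEG–fNIRS recordings measure the same neural events through two
very different lenses: EEG sees fast oscillatory dynamics (here the
sensorimotor mu rhythm, 8–13 Hz, whose power *drops* during action
execution and observation), fNIRS sees the slow hemodynamic consequence (an
HbO *increase* over engaged cortex). Canonical correlation analysis (CCA)
is the natural tool for asking which weighted combinations of channels in
one modality covary with which combinations of regions in the other — but
neuroimaging feature counts routinely exceed the number of usable samples,
and plain CCA then overfits catastrophically. This package implements a
multiset CCA that counters overfitting with two structured penalties: an
L1 term that switches irrelevant features off entirely, and a graph
Laplacian quadratic that encourages features known to be related (adjacent
regions, correlated channels) to receive similar weights.

## The model

Given $M$ datasets $X_1,\dots,X_M$ (rows are shared samples, columns are
standardized features), the solver maximizes the penalized SUMCOR
(sum-of-correlations) objective

$$
\max_{w_1,\dots,w_M}\;
\sum_{k<l} w_k^\top X_k^\top X_l\, w_l
\;-\;\sum_k \lambda_k \lVert w_k\rVert_1
\;-\;\tfrac12 \sum_k w_k^\top\!\left(I + \alpha_k L_k\right) w_k ,
\qquad \lVert w_k\rVert_2 \le 1 ,
$$

where $L_k = D_k - A_k$ is the graph Laplacian of the $k$-th feature
graph. Its quadratic form is the weighted edge-difference energy
$u^\top L u = \sum_{i<j} a_{ij}(u_i-u_j)^2$, so increasing $\alpha_k$
forces strongly connected features toward similar weights. With $L = I$
the penalty reduces to the elastic net; with $\alpha = 0$ the model is
sparse multiset CCA (smCCA); with $\lambda = \alpha = 0$ it is plain
multiset CCA (mCCA). Feature graphs default to absolute Pearson
correlation between feature columns (absolute, because the Laplacian needs
nonnegative edge weights to stay positive semi-definite).

Within-set covariance is approximated by the identity, the usual
convention of the sparse-CCA family: with $n \ll p$ the sample covariance
is singular anyway, and the identity approximation is what makes the
coordinate-wise updates closed-form. The consequence is that unpenalized
solutions coincide with classical CCA only on (near-)whitened data, which
is exactly how the oracle-equivalence tests are constructed.

### The block update

The objective is concave in each $w_k$ with the others fixed. One sweep
updates every set in turn; for set $k$, with gradient
$g = \sum_{l\neq k} X_k^\top X_l w_l$:

* $\lambda_k = \alpha_k = 0$: $w_k = g / \max(1, \lVert g\rVert_2)$ — the
  classical normalized SUMCOR step.
* $\alpha_k = 0$: $w_k = S(g, \lambda_k)/\lVert S(g,\lambda_k)\rVert_2$
  with $S$ the soft-threshold operator — the exact maximizer of the
  L1-penalized linear objective over the unit ball.
* $\alpha_k > 0$: projected proximal-gradient ascent with step size
  $1/(\alpha_k\,\lambda_{max}(L_k))$; each step (gradient, soft-threshold,
  radial projection) cannot decrease the objective.

Two numerical choices deserve explanation. First, the identity part of
the quadratic, $\tfrac12\lVert w\rVert^2$, is absorbed into the unit-ball
constraint: on the constraint boundary, where the maximizer lives, it is a
constant. Tracking it literally makes $w = 0$ the global optimum whenever
the leading correlation is below one, which is almost always. Second,
penalized solves are warm-started from the unpenalized solution of the
same random start: the soft-threshold update has an absorbing all-zero
state, and a dense random initialization falls into it whenever
$\lambda$ exceeds its (small, spread-out) initial gradient entries, while
the unpenalized solution already concentrates mass where the
cross-covariance lives. Random initialization still seeds the procedure;
five restarts are kept by default and the best objective wins, with ties
going to the lowest restart index for reproducibility.

The objective value after every sweep is recorded in each component's
convergence record, and the test suite asserts it never decreases.
Convergence is declared when the relative objective change falls below
`tol` (default `1e-6`, at most 500 sweeps); both are configurable.

### Components beyond the first

Higher-order components must be orthogonal, per set, to the earlier
weight vectors. Exact orthogonality of sparse vectors conflicts with
sparsity, so the package uses projection deflation: component $n$ is
fitted on $X_k(I - P_k)$ with $P_k$ the projector onto the span of the
earlier weights. The weight that reproduces the fitted scores on the
*original* data is then $(I-P_k)v$, which is exactly orthogonal to all
earlier components and is stored as `weights`; the solver's sparse
iterate $v$ is kept as `weights_sparse` and is what feature selection and
reports use (for the first component the two coincide). Degenerate
(all-zero) components are flagged, their correlations reported as
undefined, and later components still attempted on the deflated data.
Four components are extracted by default.

`selected_features()` reports the nonzero entries of `weights_sparse`
whose magnitude is within an order of magnitude (`rel_tol = 0.1`) of the
largest — the usual interpretive convention for sparse loadings, under
which residual near-zero coefficients carry no meaning. In the recovery
simulations below, true and false coefficients are separated by more than
a factor of ten, so the reported sets are insensitive to this threshold
over a wide range.

## Penalty selection

`two_step_cv()` follows the two-step scheme: first the smoothness weights
$\alpha$ are searched with $\lambda = 0$, then $\lambda$ with the chosen
$\alpha$ fixed. Every candidate is scored by the mean absolute difference
between the first component's training correlation and its held-out
correlation over repeated $k$-fold partitions (threefold with three
repeats by default; threefold is preferred over leave-one-out because
averaging over three partitions gives a far less variable estimate, and
repeated partitioning averages away the split itself). The criterion
embodies the requirement that a well-regularized model generalizes: train
and test correlations should agree.

Three refinements keep that criterion on its meaningful domain:

* cells whose training correlation is degenerate in any fold are excluded;
* cells whose mean training correlation falls below half the step's best
  are excluded — an over-penalized model whose correlation has collapsed
  attains a near-zero gap trivially, by "generalizing" its own failure
  (the 0.5 fraction is deliberately loose; in the regimes exercised here
  the collapsed cells sit at a tenth of the best training correlation,
  so any fraction between roughly 0.15 and 0.9 selects identically);
* among cells whose mean gap lies within one standard error of the
  minimum — statistically indistinguishable under the criterion — the one
  with the highest mean test correlation is preferred, the same logic as
  the one-standard-error rule of penalized regression.

Grids are data-calibrated. The $\lambda$ grid is eight log-spaced values
up to 0.8 times the largest absolute cross-product entry (beyond which
every coordinate is thresholded away). The $\alpha$ grid is
$\{0, 0.1, 1, 10\}$ divided by the largest Laplacian spectral radius
across sets: $\alpha$ multiplies a quadratic whose scale grows with the
graph's spectral radius (about 4 for a chain, near $p$ for a dense
correlation graph), so a fixed grid cannot span weak-to-strong smoothing
across graphs. When no graphs are supplied, correlation graphs are
recomputed inside every training fold, so the held-out rows never
influence the structure.

Significance of a fitted component is assessed by permutation:
`permutation_pvalue()` independently permutes the sample rows of all but
the first dataset, refits, and applies the add-one rule
$p = (1 + \#\{\rho_{null} \ge \rho_{obs}\})/(1 + n_{perm})$, so $p$ can
never fall below $1/(n_{perm}+1)$. The package makes no claim that this
matches any particular published procedure; it is the natural exchangeable
null for "no cross-set association".

## The fusion feature pipeline

`assemble_fusion_matrices()` turns raw multichannel recordings into the
commensurate matrices the solvers consume:

* **EEG** — band-pass to the mu band (8–13 Hz, zero-phase Butterworth
  with reflection padding), instantaneous power as the squared analytic
  envelope, inversion (reciprocal with an $\varepsilon = 10^{-8}$ guard by
  default, or baseline-minus-power), convolution with a unit-area gamma
  HRF (shape 6, scale 1 s, peak at 5 s — the canonical single-gamma),
  epoching to $[-1.5, 1.5)$ s around action-start markers, trial
  averaging, and Fourier resampling to the common 300-row grid. A 3 s
  window at 1000 Hz yields exactly 3000 samples under the half-open
  convention — the only convention that makes the arithmetic exact.
* **fNIRS** — epoching to $[-5, 25)$ s (300 samples at 10 Hz), trial
  averaging with pre-stimulus baseline correction, and aggregation of
  channels into unweighted ROI means.

The time-resolved envelope is used for "mean power" because a scalar per
epoch could not be convolved with an HRF; inversion precedes convolution
so that mu desynchronization and the HbO increase share a sign
convention. The power is computed at the recording's native rate and the
epoch resampled afterwards. Edge effects of filtering and envelope
extraction are handled by reflection padding; the first and last half
second are excluded from power-accuracy assertions in the tests, never
from data.

## What the synthetic generators emulate

`gen_multiset()` draws $X_k = \sum_n z^{[n]} (w_k^{[n]})^\top + E_k$:
shared orthogonal latent time courses, per-set loadings with contiguous
supports smoothed along a feature graph by one step of graph diffusion
($u \leftarrow (I+L)^{-1}u$ restricted to the support, then renormalized),
and Gaussian noise scaled so the entrywise signal-to-noise variance ratio
equals `snr`. Supports, loadings, graphs and noise levels are returned,
so recovery can be scored exactly. Two validation regimes are used
throughout the tests, chosen once:

* **recovery**: $M = 3$, $p = 40$, one latent through 4-sparse loadings,
  $\mathrm{snr} = 1$, $n = 150$, 30 replicates — comfortable sample size,
  honest noise; CV-tuned fits must identify the true supports (mean
  F1 $\ge 0.9$) and directions (aligned cosine $\ge 0.9$).
* **method comparison**: $n_{train} = 35 \ll p = 40$, an extended
  contiguous 10-sparse support, $\mathrm{snr} = 0.25$, structure graphs
  supplied to the structured solver, held-out correlation on 200 test
  rows — the high-dimensional low-signal regime the penalties target,
  where the expected ordering ssmCCA $\ge$ smCCA $\ge$ mCCA emerges in
  the 30-seed mean.

`gen_modalities()` simulates paired recordings: EEG channels carry a
10 Hz oscillation whose amplitude drops by `mu_erd_depth` during action
windows — beginning 1.5 s before the marker, reflecting the
well-documented pre-movement onset of mu suppression during motor
preparation — plus broadband noise; fNIRS channels carry the event train
convolved with the HRF plus a post-preprocessing noise mix of moderate
drift, a cardiac oscillation with channel-specific phase, and white
measurement noise. Setting `event_effect = FALSE` produces the matched
null: identical noise structure and markers, no event-locked modulation.
The discriminating property — the fused $(E, N)$ first canonical
correlation exceeds the event-free control's — holds in 10 of 10 seeded
replicates at the defaults.

What these generators deliberately do **not** model: volume conduction
and channel mixing, artifacts (ocular, motion, optode decoupling),
non-stationary background rhythms, subject-level variability, or any
head-geometry forward model. Passing tests therefore demonstrate that the
estimator recovers the structure it assumes, under honest noise — not
that real recordings satisfy those assumptions.

## Worked example

```{r example, eval = FALSE}
sim <- gen_multiset(n_samples = 150, feature_counts = c(40, 40, 40),
                    n_latents = 1, sparsity = 4, snr = 1, seed = 1)
cv <- two_step_cv(sim$datasets, graphs = sim$truth$graphs, seed = 2)
fit <- ssmcca_fit(sim$datasets, graphs = sim$truth$graphs,
                  penalties = cv$penalties, n_components = 1, init_seed = 3)
component_report(fit)
selected_features(fit$components[[1]])
```

The same flow is available from the shell through
`inst/cli/ssmcca.R` (subcommands `simulate`, `fuse-features`, `tune`,
`fit`, `fit-baselines`, `permtest`, `run`), and end-to-end through
`run_pipeline()` driven by a YAML configuration; rerunning a
configuration with the same seed reproduces every numeric output.

## Numerical choices and degenerate inputs

* Standardization: columns centered, scaled to unit Euclidean norm;
  constant columns are zeroed with a warning rather than producing NaN.
* Convergence: relative objective change below `1e-6` or 500 sweeps;
  inner proximal loops stop at a `1e-10` step change or 200 iterations.
* Ties across restarts: equal objectives (within `1e-12`) resolve to the
  lowest restart index.
* Deflation tolerance: orthogonality of reported weights is exact by
  construction; the testable contract is $|w^{[n]}\!\cdot w^{[j]}| \le
  10^{-6}$.
* Zero-variance projections in held-out scoring are flagged as undefined
  (`NA` plus an attribute), never silently propagated.
* Long convolutions run via zero-padded FFT at 2-3-5-smooth lengths;
  naive full-length FFTs can land on near-prime sizes with quadratic
  cost.
* Fourier resampling assumes band-limited content; the tests verify a
  10 Hz tone survives a 1000 Hz to 100 Hz resample with correlation
  above 0.999.

## Known limitations

* The identity within-set covariance approximation trades statistical
  efficiency for stability; on well-conditioned low-dimensional data,
  classical CCA (available as `cca_closed_form()`) is the better
  estimator.
* The two-step search is a coarse approximation to the joint penalty
  optimum; the tests verify it lands within 0.05 held-out correlation of
  an exhaustive joint grid search on the same grids, not that it finds
  the optimum.
* The train/test gap criterion selects for generalization *agreement*,
  not peak held-out correlation; with weak signal it prefers heavier
  regularization than an oracle would.
* Permutation p-values for components beyond the first are conditional
  on the earlier components through deflation; they should be read as
  per-component screening, not family-wise inference.
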