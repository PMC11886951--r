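---
title: "Stacked prediction of subject traits from models of brain network dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked prediction of subject traits from models of brain network dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statestack)
```

## The problem

Resting-state fMRI gives, per subject, a multivariate timeseries of a few
hundred to a few thousand time points over a few dozen parcels.  Static
functional connectivity (FC) summarises it as one covariance matrix per
subject; models of *dynamics* instead describe the scan as switching
between a small number of recurring states, each with its own amplitude
pattern and connectivity.  Features derived from such models can predict
cognitive traits, but the derived predictions are sensitive to modelling
choices: the number of states, the strength of the temporal prior, the
initialisation of the fit, and which subjects enter a stochastic update.
`statestack` treats this variability as a resource rather than a
nuisance: it fits an *ensemble* of state-space descriptions, turns each
into a trait prediction, and combines the predictions by stacked
generalisation, so that model selection is replaced by model
combination.

## The generative model

Each subject's timeseries $X_t \in \mathbb{R}^M$ is modelled by a
$K$-state Gaussian hidden Markov model with parameters
$\theta = [\pi, A, \mu, \Sigma]$: initial state probabilities $\pi$, a
row-stochastic transition matrix $A$, state means $\mu_k$ (amplitude)
and state covariances $\Sigma_k$ (FC).  Conditional on the active state
$q_t = k$,

$$X_t \mid q_t = k \sim \mathcal{N}(\mu_k, \Sigma_k), \qquad
  q_t \mid q_{t-1} = k \sim \mathrm{Cat}(A_{k\cdot}).$$

Group-level parameters are fitted on the pooled cohort by
expectation-maximisation (Baum–Welch) with a maximum-a-posteriori M-step
for $A$: a Dirichlet prior concentrated on the diagonal adds $\delta$
pseudo-counts to every self-transition cell, so larger $\delta$ yields
more persistent states and a slower effective time scale.  We use MAP-EM
rather than stochastic variational inference because it is deterministic
per seed and converges monotonically in full batch — properties the test
suite relies on — while still exposing the same two sources of run-to-run
variability that matter for the ensemble: the initialisation seed, and
(optionally, via `batch_size`) the random subject subset used per
iteration.  Initialisation uses a seeded k-means assignment on a data
subsample when state means are modelled, and randomised contiguous-block
assignment for the covariance-only parameterisation (`model_mean =
FALSE`), where k-means has no mean signal to work with.  A state whose
posterior occupancy falls below $M+1$ time points has its covariance
reset to the pooled covariance and a warning is raised; this guard
sacrifices the monotonicity guarantee in the (rare, logged) collapse
case.

Subject-specific parameters come from *dual estimation*: state
posteriors are computed under the fixed group model, and subject means,
covariances, transition rows and initial probabilities are re-estimated
as posterior-weighted statistics blended with the group values using
`prior_strength` pseudo-observations.  The exact dual-estimation recipe
is not pinned down in the literature we follow, so the blending rule is
this package's explicit choice: it is the conjugate-prior update for
each parameter family, it returns the group parameters exactly as
`prior_strength` grows to infinity, and states a subject never visits
inherit the group values.  The default `prior_strength = M` (one
pseudo-observation per channel) regularises noticeably only where a
state is barely visited.

## From state covariances to features

Covariance and precision matrices live on the manifold of symmetric
positive-definite (SPD) matrices, where Euclidean operations are not
valid.  The feature pipeline per state is:

1. **Regularised precision** (`regularized_precision`):
   $\bar\Omega_k = (\Sigma_k + aI)^{-1}$, computed through the Cholesky
   factor.  The Tikhonov term $a$ stabilises inversion of covariances
   estimated from few effective time points.  The default is $a = 0.1$
   for $K \le 6$ and $0.5$ above, reflecting that higher state counts
   mean fewer points per state; the value is exposed everywhere.
2. **Riemannian reference** (`riemannian_mean`): the affine-invariant
   Karcher mean of the state's matrices across subjects, found by
   fixed-point iteration on the manifold exponential/log maps, with an
   arithmetic-mean warm start, convergence declared when the Frobenius
   norm of the mean tangent vector drops below `tol`.
3. **Tangent projection** (`tangent_project`):
   $\log\mathrm{m}(C_G^{-1/2}\, C\, C_G^{-1/2})$ via eigendecomposition
   of the whitened matrix.
4. **Isometric vectorisation** (`vectorize_symmetric`): the row-major
   upper triangle with off-diagonal entries scaled by $\sqrt 2$, so
   Euclidean distances between feature vectors equal Frobenius distances
   between tangent matrices.  The plain "vectorise" wording of the
   source methodology leaves the scaling open; the isometric convention
   makes the subsequent linear kernel geometry-consistent.

The per-state tangent blocks are concatenated with the flattened state
means and the row-major transition matrix (each optional).  Partial
correlations (`partial_correlation`) are available as the standard
normalisation of the precision matrix, with the diagonal set to $1$ by
the self-correlation convention (the raw formula gives $-1$ there, which
carries no information either way).  The static-FC branch
(`static_fc_features`) applies steps 1–4 to the whole-scan covariance,
so static and dynamic features are geometrically comparable.

Two deliberate leakage-accepting choices mirror the methodology we
follow and are defensible for comparative studies on a fixed cohort: the
group HMM is trained on all subjects, and the tangent reference means
are computed across all subjects.  Both are applied identically to every
compared method; the prediction stage itself (deconfounding,
standardisation, ridge fitting, penalty selection, stacking weights)
uses training folds only, which the test suite enforces with bitwise
sentinels.

## Prediction and stacking

Features enter a linear-kernel ridge regression
($K_L(m,n) = U_m^\top U_n$, $\alpha = (K_L + \lambda I)^{-1} y$).
Before the kernel is formed, confounds are regressed out of both the
feature columns and the trait with parameters estimated on the training
fold only, and feature columns are z-scored with training statistics —
without this, transition-probability features are dwarfed by the tangent
blocks.  The ridge penalty is chosen per base model on a 17-point
logarithmic grid ($10^{-4}$ to $10^4$) by 10-fold cross-validated MSE,
with ties broken towards heavier regularisation.

The nested scheme follows the two-inner-loop design: each outer fold
(10-fold, family-respecting) holds out a test set; the outer-training
subjects are split into 10 inner folds shared by two loops — the first
selects $\lambda$ per base model, the second produces inner
out-of-sample base predictions at those $\lambda$ on which the stacking
weights are fitted.  Weights solve the simplex-constrained least-squares
problem

$$\min_\beta \lVert \hat Y \beta - y \rVert^2 \quad \text{s.t.}\quad
  \beta_i \ge 0,\ \textstyle\sum_i \beta_i = 1,$$

by an active-set iteration on the KKT system, converged to a $10^{-10}$
KKT residual; with collinear base predictions the optimum is not unique
and the minimum-norm solution on the final support is returned (a
documented tie-break via a pseudo-inverse solve).  Base models are then
refitted on the full outer-training set with their selected penalties,
predict the outer test fold, and the fold's weights combine these into
the stacked out-of-sample prediction; uniform-weight averaging and the
individual base predictions are recorded from the same test predictions.
Where the two-inner-loop description leaves open whether outer-test base
predictions come from refitted models or assembled inner models, we
adopt the refit reading, which matches the "using the optimised
hyperparameter from inner loop 1" step of the scheme.

Inside the orchestration the ridge solutions are computed through an SVD
of the training feature matrix rather than by factorising the
$N \times N$ kernel per fold.  The two forms are algebraically
identical for a linear kernel (the primal–dual equivalence is asserted
to $10^{-8}$ on random instances in the tests); the SVD path costs
$O(ND^2)$ per fold instead of $O(N^3)$, which is what makes
1,000-subject nested runs routine.  The kernel-facing API
(`linear_kernel`, `krr_fit`, `krr_predict`, `select_lambda`) implements
the kernel form directly.  The orchestration additionally centres the
trait by its training-fold mean (re-added to predictions) — a no-op
after deconfounding, which leaves training residuals with exactly zero
mean, but necessary for the undeconfounded comparison runs.

## Evaluation

Accuracy is the coefficient of determination $R^2$ of pooled
out-of-sample predictions; robustness is the variance of $R^2$ across
repetitions of the whole cross-validation with re-randomised folds.
Method comparisons use the corrected repeated $k$-fold t-test on
per-(fold, repetition) accuracy differences,

$$t = \frac{\tfrac{1}{kr}\sum_{ij} x_{ij}}
          {\sqrt{\left(\tfrac{1}{kr} + \tfrac{n_2}{n_1}\right)\hat\sigma^2}},$$

with $\hat\sigma^2$ the sample variance of the differences (the
deviation term is squared; written without the square the sum is
identically zero, so the squared Nadeau–Bengio form is the only coherent
reading) and $kr - 1$ degrees of freedom.  The $n_2/n_1$ inflation
accounts for the positive correlation between cells induced by
overlapping training sets: the statistic is *calibrated* under the
equicorrelated null it is built for (cell correlation
$\rho = (n_2/n_1)/(1 + n_2/n_1)$) and deliberately *conservative* for
independent cells — both properties are verified by simulation in the
test suite.  Fold-level $R^2$ values are the accuracies entering the
test, since the $k \cdot r$ indexing requires per-fold quantities.
Multiple comparisons are handled by Benjamini–Hochberg FDR across the
batch of tests being reported together, and variance comparisons use
Levene's test on mean-centred absolute deviations, since the score
distributions cannot be assumed normal.

## What the synthetic cohorts emulate — and what they do not

`cohort_spec`/`generate_cohort` produce state-switching Gaussian
timeseries in which each subject perturbs the group parameters: additive
Gaussian deviations of the state means, a congruence transform
$(I+E)\,\Sigma_k\,(I+E)^\top$ with small symmetric $E$ for the
covariances (closed on the SPD manifold by construction, with bounded
retries), and Dirichlet resampling of the transition rows around the
group rows.  Deviations are partially shared within families
(`family_share`), families are never split across folds, and confounds
optionally shift the subject state means (`confound_strength`) as well
as the trait (`confound_effect` in `trait_spec`) — without the first
pathway, confounds could never leak through the features and
deconfounding would be untestable.  Traits are linear functionals of the
*true* subject features computed through the same SPD pathway, plus
confound contribution and noise; the attainable signal fraction (oracle
$R^2$) is stored with every trait so pipeline accuracy can be judged
against what the signal supports rather than against absolute values.

Two presets encode the canonical acquisition regimes at desk scale:
`"hcp_like"` (few subjects, long scans, families) and `"ukb_like"`
(many unrelated subjects, short scans).  The regime-contrast regression
test uses scan lengths of 400 versus 40 points at $M = 4$, matching the
roughly 100-vs-10 points-per-parcel ratios of the two source regimes.

The generator is deliberately idealised: Gaussian emissions with exact
Markov switching, no haemodynamic convolution, no realistic fMRI noise
spectrum, no motion artefacts, no parcellation error.  Passing tests
therefore demonstrate that the pipeline recovers what its own model
class can express, is leakage-free, and behaves as the theory predicts
across regimes — not that any particular real-data accuracy will be
attained.  Real-data $R^2$ values for cognitive traits are small (a few
percent of variance), an order below what the synthetic couplings
produce by design, so that property checks are not drowned in noise.

## Problem sizes and numerical choices

The test and acceptance runs use cohorts of 100–1,000 subjects, 4–6
channels, scans of 40–5,000 points, and ensembles of up to 10 base
models (9 HMM configurations crossing $K \in \{2,\dots,6\}$ with
$\delta \in \{10, 100\}$, plus static FC), sizes chosen so the whole
suite exercises every claim at full nesting depth on a single CPU.
Mini-batch EM (`batch_size = 150`) is used for the large-ensemble runs,
matching the stochastic-update regime the ensemble is meant to exploit.
Fixed defaults of $K = 6$, $\delta = 10$ are the conventional settings
for the fixed-hyperparameter ensemble.  All randomness flows through
explicit integer seeds; child seeds are derived arithmetically (never
from consumed RNG state), so every result object is bitwise reproducible
from its seed and config, which the tests assert.

Remaining numerical conventions: symmetric eigendecompositions back all
matrix log/exp/power maps, with positive-definiteness checked by
Cholesky success and reported with the offending state or matrix named;
near-singular M-step covariances receive a $10^{-8}$-scaled diagonal
jitter; rank-deficient confound matrices fall back to a
ridge-stabilised solve with a warning; duplicate penalty-grid entries
are deduplicated; and the forward–backward recursions are scaled per
time step with an explicit error (never silent `NaN`) on underflow.

## Known limitations

Autoregressive observation models, nonlinear kernels and nonlinear
meta-learners (e.g. random-forest stacking), log-Euclidean or
Bures–Wasserstein geometries, shrinkage estimators beyond Tikhonov,
permutation inference, and M/EEG-rate data are out of scope.  The
stacking-weight estimate degrades with few subjects — with cohorts of a
few hundred subjects, uniform averaging is often as accurate and more
robust, which the evaluation tools make easy to check on any given
dataset.
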