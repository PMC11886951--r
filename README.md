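# statestack

Predicting individual traits (cognitive scores, clinical measures) from
multivariate brain timeseries — and doing it robustly — runs into an
awkward fact: models of brain-network *dynamics* are sensitive to their
own estimation choices.  A Gaussian hidden Markov model (HMM) fitted to
parcellated resting-state fMRI yields different state decompositions
depending on the number of states *K*, the self-transition prior δ, the
initialisation seed, and the subject batches used by stochastic updates.
`statestack` treats that variability as signal: it fits an ensemble of
HMM configurations, derives one trait prediction per configuration, and
combines the predictions by **stacked generalisation**, replacing model
selection with model combination.

The pipeline, end to end:

1. **Group HMM** — MAP-EM (Baum–Welch) on the pooled cohort, with a
   Dirichlet prior adding δ pseudo-counts to the self-transition
   diagonal; optional mini-batch updates.  Each state *k* is a Gaussian
   N(μₖ, Σₖ) over the *M* parcels, with Markov switching qₜ ~ Cat(A[qₜ₋₁,]).
2. **Dual estimation** — subject-specific copies of the parameters,
   re-estimated under the subject's data and blended with the group
   values by a pseudo-observation prior.
3. **SPD tangent features** — each state covariance becomes a
   Tikhonov-regularised precision (Σₖ + aI)⁻¹, projected to the tangent
   space of the SPD manifold at the cohort's Riemannian (Karcher) mean,
   logm(C_G^{-1/2} C C_G^{-1/2}), and vectorised isometrically;
   concatenated with state means and transition rows.  A static-FC
   branch applies the same geometry to the whole-scan covariance.
4. **Deconfounded kernel ridge regression** — linear kernel
   K_L(m,n) = Uₘᵀ·Uₙ, α = (K_L + λI)⁻¹y, confounds regressed out of
   features and trait with training-fold parameters, λ selected by
   10-fold inner CV.
5. **Simplex-constrained stacking** — out-of-sample base predictions Ŷ
   from a second inner loop feed min_β ‖Ŷβ − y‖² with βᵢ ≥ 0, Σβᵢ = 1,
   inside a family-aware nested 10-fold outer CV; uniform averaging and
   all per-model predictions are recorded alongside.
6. **Evaluation** — R², repeated CV for robustness, the corrected
   repeated k-fold t-test t = mean(x)/√((1/kr + n₂/n₁)σ̂²), BH-FDR, and
   Levene's test.

A synthetic-cohort generator (subject-varying HMM parameters, family
structure, confound effects, traits coupled to the true subject
dynamics with recorded attainable R²) makes every stage testable without
restricted data.  See `vignettes/stacking-brain-dynamics.Rmd` for the
full methods account.

## Worked example

```r
library(statestack)

spec   <- cohort_spec(N = 120, M = 4, T_len = 150, K_true = 2,
                      subject_sd = 0.2, n_confounds = 2,
                      confound_strength = 0.2, seed = 5)
group  <- generate_group_params(spec)
cohort <- generate_cohort(group, spec)
gen    <- generate_traits(cohort, trait_spec(
  coupling = c(tangent = 1, means = 0.5, transitions = 0.3, static = 0.5),
  noise_sd = 1, confound_effect = 0.3), seed = 9)
gen$oracle_r2
#> [1] 0.6144405

fit  <- fit_group_hmm(cohort$timeseries, hmm_control(K = 2, max_iter = 20),
                      seed = 1)
subj <- lapply(cohort$timeseries, function(X) dual_estimate(fit$params, X))
fs   <- list(hmm    = assemble_features(subj),
             static = static_fc_features(cohort$timeseries))

scheme <- make_folds(cohort$ids, cohort$families, n_folds = 10, seed = 2)
res <- run_nested_stacking(fs, gen$traits[, 1], cohort$confounds, scheme,
                           seed = 3)
res
#> stacked_result: 120 subjects, 2 base models, 10 folds
#>   out-of-sample R^2: stacked 0.1221 | averaged 0.1471 | base mean 0.1220 (best 0.1260)
```

Reading the numbers: the trait was built so that 61% of its variance is
carried by the true subject features (`oracle_r2`); at N = 120 subjects
and 150 time points the fitted pipeline recovers about 0.12–0.15 of the
variance out of sample after deconfounding — far from the oracle, as
expected for short scans and a small cohort, and exactly the regime in
which uniform averaging rivals stacking (with larger cohorts the stacked
combination pulls ahead; the test suite demonstrates this at N = 1,000).
`res$weights` holds the per-fold simplex weights, `res$lambda` the
selected ridge penalties, and `summary(res)` the R² per method.

For repeated-CV robustness and significance:

```r
rep_scores <- repeated_cv_evaluate(fs, gen$traits[, 1], cohort$confounds,
                                   cohort$families, R = 10, seed = 4)
compare_methods(rep_scores, "stacked", "averaged")  # corrected t-test
```

A config-driven front end (`run_experiment`, and the thin CLI at
`inst/cli/statestack.R` with subcommands
`simulate|fit-hmm|features|stack|evaluate|run-all`) orchestrates the
whole pipeline from a single YAML/JSON file and writes a reproducible
results directory.

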