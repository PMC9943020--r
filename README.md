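# spinglassfc

Personalized pairwise maximum-entropy (Ising spin-glass) models of
parcellated brain dynamics.

## The problem

Resting-state fMRI studies of altered brain states (pharmacological,
pathological, developmental) need a compact, mechanistic summary of how
"ordered" a subject's large-scale dynamics are. One line of work binarizes
parcel-averaged BOLD time series and models the joint on/off patterns
with an Ising model

```
H(σ) = − Σ_{i<j} J_ij σ_i σ_j − Σ_i h_i σ_i ,    P(σ) ∝ exp(−β H(σ))
```

where `σ_i = ±1` is the state of parcel `i`, the couplings `J` form a
signed "Ising connectome", and the inverse temperature `β = 1/T` measures
how strongly that architecture constrains the dynamics. Because one
scanning session cannot constrain `N(N+1)/2` parameters, a group
**archetype** `(h, J)` is fitted to the pooled cohort by maximum
pseudo-likelihood, and each subject and condition is then **personalized**
by a single temperature: hotter T means more disordered dynamics, located
relative to the archetype's critical temperature `T_c` (peak of the
magnetic susceptibility χ).

The package implements the full analysis chain for this kind of study:

* median binarization and session assembly (`binarize_median`,
  `assemble_condition_data`);
* archetype fitting by pseudo-likelihood gradient ascent and
  single-parameter temperature personalization (`fit_archetype`,
  `fit_temperature`), with an exact-enumeration oracle for small systems
  (`exact_distribution`, `exact_observables`);
* Metropolis sampling, phase diagrams, susceptibility / heat-capacity /
  local and link susceptibilities, critical-point location, and
  link-perturbation experiments (`metropolis_run`, `temperature_sweep`,
  `find_critical_temperature`, `perturb_links`);
* Lempel–Ziv–Welch and Block Decomposition Method complexity of binarized
  data, with archetype-dictionary seeding (`lzw_compress`, `bdm`,
  `build_archetype_dictionary`);
* connectivity metrics — global, intra/interhemispheric, homotopic — and
  archetype comparisons (`connectivity_metrics`, `compare_archetypes`,
  `correlate_with_covariate`);
* condition-contrast statistics: paired Wilcoxon/t tests, a parcel-label
  permutation test for the temperature effect, metric correlations, and a
  one-call pipeline (`paired_condition_test`,
  `permutation_test_temperature`, `run_pipeline`);
* a synthetic cohort generator with programmed ground truth
  (`make_archetype`, `simulate_cohort`) so the whole chain is testable
  without any external dataset.

## Worked example

Simulate a cohort whose condition B runs 7% hotter than condition A, fit
the archetype and per-subject temperatures, and test the contrast:

```r
library(spinglassfc)

arch <- make_archetype(archetype_spec(), seed = 11)
arch
#> Ising model: 16 parcels, 120 nonzero couplings

coh <- simulate_cohort(arch, cohort_config(n_subjects = 8, seed = 42))
coh
#> Cohort: 8 subjects x 2 conditions x 2 sessions, 16 parcels

fit <- fit_archetype(assemble_condition_data(coh, "global"))
fit
#> Archetype fit: 16 parcels, 109 iterations, mismatch 9.67e-05

d <- assemble_condition_data(coh, "subject_condition",
                             condition = "B", subject = "S01")
fit_temperature(d, fit$model)
#> Temperature fit: beta = 0.9741 (T = 1.0266), 11 iterations

report <- run_pipeline(coh, analysis_config(seed = 1, n_perm = 200))
report
#> Analysis report: 8 subjects, 16 parcels
#>   temperature shift B vs A: 5.02% (Wilcoxon one-tailed p = 0.0195)
#>   permutation test p = 0.428 (200 permutations)
```

Reading the output: the archetype fit converged to a maximum moment
mismatch below 1e-4; subject S01's condition-B data personalizes to
T ≈ 1.03; across the 8 subjects the recovered B-vs-A temperature shift is
+5.0% (the programmed +7% minus cohort-level noise), significant by the
paired one-tailed Wilcoxon test. The permutation test — which scrambles
parcel labels of `(h, J)` and refits all temperatures per permutation —
is deliberately conservative at this small cohort and parcel count (see
the methods vignette); at the default 15 subjects it sharpens
considerably. Connectivity summaries of the fitted archetype come from
`connectivity_metrics(fit$model)` (here mean homotopic strength 0.578,
mean intra-hemispheric global connectivity 0.648, recovering the
generator's programmed structure).

The methods vignette (`vignettes/spinglassfc-methods.Rmd`) documents the
model, every tunable parameter with its default and rationale, the
sampling conventions, and known limitations.

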