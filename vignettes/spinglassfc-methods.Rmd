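---
title: "Personalized Ising models of parcellated brain dynamics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized Ising models of parcellated brain dynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the model and the numerical
choices behind it. It is written for someone who wants to understand, audit,
or extend the pipeline, not just run it.

## The model

The package models the joint activity of $N$ brain parcels as a pairwise
maximum-entropy distribution over binary patterns
$\sigma \in \{-1,+1\}^N$ — an Ising spin glass with arbitrary-sign couplings
and fields:

$$H(\sigma) = -\sum_{i<j} J_{ij}\sigma_i\sigma_j - \sum_i h_i \sigma_i,
\qquad P(\sigma) \propto e^{-\beta H(\sigma)}.$$

$J_{ij}$ is the "Ising connectivity" between parcels $i$ and $j$ (positive:
co-activation; negative: anti-correlation), $h_i$ modulates the mean
activity of parcel $i$, and the inverse temperature $\beta = 1/T$ scales
the whole energy landscape. Maximum entropy means this is the least
structured distribution whose 1- and 2-point moments match the data; all
higher-order structure in the model is emergent, not fitted.

The analysis strategy is two-stage:

1. **Archetype**: one $(h, J)$ pair is fitted at $\beta = 1$ to the
   concatenated binarized data of all subjects (and, separately, of each
   condition). Pooling is deliberate — a single scanning session is far too
   short to constrain $N(N+1)/2$ parameters.
2. **Personalization**: with $(h, J)$ frozen, one scalar $\beta$ is fitted
   per subject and condition. The temperature $T = 1/\beta$ is the
   personalized summary statistic: hotter means more disordered dynamics,
   and its position relative to the archetype's critical temperature says
   on which side of the phase transition a subject's dynamics sit.

## Binarization

Continuous parcel time series are binarized at the **per-parcel median**:
$+1$ strictly above the median, $-1$ otherwise (`binarize_median()`). The
median threshold maximizes the entropy of each binarized series, which is
the right operating point for both the Ising fit and compression-based
complexity. Two deliberate details:

* Ties at the median map to $-1$ (the threshold rule is "strictly
  greater"). For continuous data ties have measure zero; the rule only
  matters for discrete or degenerate inputs, and fixing it makes the
  operation deterministic.
* Binarization is applied per session before sessions are concatenated,
  so each session's median is its own — session-level offsets are removed
  rather than mixed.

A constant row binarizes to all $-1$ and triggers a warning; downstream
fits treat it as an always-off parcel.

## Archetype estimation by maximum pseudo-likelihood

Full maximum likelihood needs the partition function ($2^N$ terms), so the
likelihood is replaced by the pseudo-likelihood, the product over spins and
time points of the conditional probability of each spin given the others.
The conditional mean of spin $i$ is $\tanh\!\big(\beta(h_i + \sum_j J_{ij}
\sigma_j)\big)$, and gradient ascent takes the fixed-point form of moment
matching:

$$h_i \leftarrow h_i + \eta\,(\langle\sigma_i\rangle_{\mathrm{emp}}
  - \langle\sigma_i\rangle_{\tilde P}), \qquad
  J_{ij} \leftarrow J_{ij} + \eta\,(\langle\sigma_i\sigma_j\rangle_{\mathrm{emp}}
  - \langle\sigma_i\sigma_j\rangle_{\tilde P}).$$

Choices that matter:

* **Symmetrization.** The pair pseudo-moment is asymmetric in $(i,j)$ (one
  may condition on $i$ or on $j$); the package averages both conditionals,
  which keeps $J$ exactly symmetric at every step.
* **Defaults**: $\eta = 0.2$, tolerance $10^{-4}$ on the maximum absolute
  moment mismatch, at most 5000 iterations, zero initialization. The
  mismatch criterion — not the likelihood — defines convergence, because
  moment matching *is* the fixed point. A divergence guard aborts with
  advice to reduce $\eta$ if the mismatch grows for 100 consecutive steps.
* Pseudo-likelihood is consistent as $t_{\max} \to \infty$; at short
  $t_{\max}$ the fit inherits sampling noise in the empirical moments.
  `fit_archetype()` warns when $t_{\max} < 10N$.

The inner loop is compiled (RcppArmadillo); on desk scale this keeps a
full cohort fit (N = 16, ~13 000 time points) under a second.

## Personalization: one temperature per subject

With the archetype frozen, the single parameter $\beta$ is driven by
energy matching:

$$\beta \leftarrow \beta - \eta\,(\langle H\rangle_{\mathrm{emp}}
  - \langle H\rangle_{\tilde P}(\beta)),$$

whose fixed point equates the empirical mean energy of the subject's data
with the pseudo-model mean energy (pairs counted once on both sides, so
the fixed point is well defined). Two numerical choices:

* **Adaptive damping.** A fixed $\eta$ diverges whenever
  $\eta > 2/|\partial\langle H\rangle_{\tilde P}/\partial\beta|$, and the
  energy-variance scale that sets that derivative grows with $N$. The
  package keeps the update rule but halves the step when the energy
  mismatch grows and relaxes it (×1.25) while it shrinks. This converges
  in ~10–100 iterations for any curvature without changing the fixed
  point.
* **Sign freedom.** For the user-facing fit, $\beta \le 0$ is an error —
  a personalized temperature must be positive. Inside the parcel-label
  permutation test, however, a scrambled architecture can be genuinely
  *anti-matched* to the data, putting the energy-matching fixed point at
  $\beta \le 0$; the permutation fits therefore run unconstrained
  (`allow_negative`), and the same unconstrained algorithm is applied to
  the observed archetype so observed and permuted statistics remain
  exchangeable.

## Metropolis sampling and observables

`metropolis_run()` is random-site single-flip Metropolis with acceptance
$\min(1, e^{-\Delta H/T})$, adjacency-list couplings (sparse lattices pay
only for their edges), incremental energy bookkeeping re-verified against
a from-scratch Hamiltonian at chain end, and R's RNG for reproducibility.
Defaults for sweeps: burn-in of 1000 sweeps, thinning of one sweep
(N attempts), with chain $i$ of a temperature grid seeded as
`seed + i`.

Observables use the un-normalized magnetization $M = \sum_i \sigma_i$:
$\chi = \mathrm{Var}(M)/T$, $C_v = \mathrm{Var}(H)/T^2$,
$\chi_n = \beta(\langle M\sigma_n\rangle - \langle M\rangle\langle\sigma_n\rangle)$,
$l_{ij} = \beta(\langle M\sigma_i\sigma_j\rangle - \langle M\rangle
\langle\sigma_i\sigma_j\rangle)$, and $L_{ij} = l_{ij}J_{ij}$. Note that
$\sum_n \chi_n = \chi$ exactly, a useful internal consistency check that
the test suite asserts on enumeration.

* **Branch-flip convention.** Finite systems below the critical point are
  bistable; chain averages of $M$ would mix the two branches. The
  `branch_flipped` convention reflects every retained sample by the sign
  of its magnetization ($\sigma \to \sigma\,\mathrm{sign}(M)$, with
  $\mathrm{sign}(0) := +1$, a tie-break the convention itself leaves open)
  before averaging. The raw convention is kept alongside because the
  exact-enumeration oracle validates both.
* **Standard errors** come from a moving-block bootstrap (50 contiguous
  blocks, 200 replicates) over per-block sufficient statistics, which
  absorbs the chain autocorrelation without modeling it.
* **Critical temperature**: grid argmax of $\chi$ refined by quadratic
  interpolation through the three bracketing points; a boundary maximum
  is an error rather than an extrapolation. Sweep-to-sweep noise of the
  refined peak is about ±0.02–0.03 at the default chain lengths, so
  model contrasts in $T_c$ are best made with shared chain seeds
  (paired sweeps), as both the tests and the acceptance script do.

For small systems ($N \le 20$), `exact_distribution()` /
`exact_observables()` enumerate all $2^N$ states and serve as the oracle
throughout the test suite: sampled state frequencies are held to total
variation < 0.02 of the Boltzmann distribution, estimators to their
Monte-Carlo standard errors, and $\chi$, $C_v$ to centered numerical
derivatives of $\langle M\rangle$ and $\langle H\rangle$
(fluctuation–dissipation).

## Complexity: LZW and BDM

`lzw_compress()` is the standard Lempel–Ziv–Welch parse over the binary
alphabet: longest dictionary match, emit its code, insert the match
extended by one symbol. The description length is
$\ell = c(n)\log_2 c(n)$ with $c(n)$ the number of emitted codes, and
$\rho_0 = \ell/n$ bits per character; the exact sum of emitted code
widths is available via `code_length = "emitted_widths"`. Matrices are
flattened parcel-fastest within each time frame ("space then time"); the
transposed order is exposed for sensitivity checks.

$\rho_0$ is an upper bound that converges to the source entropy rate
slowly (like $1/\log n$): at $n = 10^5$ the measured excess over $H(p)$
for i.i.d. bits is about 0.17–0.26 bits/char under the
$c\log_2 c$ formula (the emitted-widths formula is tighter). Absolute
$\rho_0$ values at these lengths must therefore be read as relative
measures — which is how the pipeline uses them (condition contrasts,
monotone temperature response) — not as entropy estimates.

The **archetype dictionary** replays the cohort-pooling idea for
compression: all sessions are flattened and concatenated (first listed
condition first, a choice that has to be made; reversing it moves
per-subject seeded $\rho_0$ by well under a percent at cohort scale,
which the suite asserts), compressed once, and the final dictionary
seeds each per-subject compression, scoring subjects against the
cohort's vocabulary.

`bdm()` implements the Block Decomposition Method: partition into
non-overlapping blocks (default 4×4; boundary remainders discarded), and
sum $\mathrm{CTM}(b) + \log_2 m_b$ over distinct blocks $b$ with
multiplicities $m_b$. Published Coding-Theorem-Method tables are external
precomputed data and can be plugged in via `ctm_table()` /
`read_ctm_table()`-style text files; when a block (or the whole table) is
missing, the fallback scores it by its Shannon entropy in bits and the
result reports the fallback fraction. With the entropy fallback BDM is an
entropy-flavored complexity, which suffices for the contrasts and
monotonicity properties the pipeline tests; with a genuine CTM table it
tightens toward algorithmic complexity.

## The synthetic cohort generator

There is no public dataset behind this pipeline, so the generator *is*
the study design, and every downstream stage is validated against its
programmed ground truth:

* **Archetype structure** (`archetype_spec()`): two intra-hemispheric
  blocks of mean coupling 0.1 (fully dense — pseudo-likelihood fits of
  real parcellated data are dense), strong positive homotopic mirror-pair
  links (0.6), weak negative other interhemispheric links (−0.02),
  Gaussian coupling jitter (sd 0.05) and fields with sd 0.05, on 16
  parcels by default. These scales put the archetype's critical
  temperature near 0.7–0.8, below the nominal fitting temperature 1 —
  the regime the analysis assumes (personalized temperatures in the
  paramagnetic phase, above the critical point).
* **Cohort** (`cohort_config()`): 15 subjects × 2 conditions × 2 sessions
  of 217 time points. Subject baseline temperatures are log-normal around
  1 (sd 0.05 on the log scale — log-normal guarantees positivity);
  condition B is shifted by +7% relative with per-subject Gaussian noise
  of 5 percentage points on the shift. Sessions are independent Metropolis
  chains (fresh burn-in of 1000 sweeps, one retained lattice per sweep).
* **What it does not emulate**: hemodynamics, autocorrelated scanner
  noise, spatial smoothing, motion, or any non-stationarity. Passing
  tests on this generator shows the estimators recover what the model
  family can express; it does not certify behavior on real BOLD data,
  where the binarized process is not an equilibrium Ising sample.

`render_pseudo_bold()` exists solely to exercise the binarization stage
with known ground truth (levels ±amplitude plus Gaussian noise).

## Statistics

Condition contrasts are paired tests on per-subject metrics
(`paired_condition_test()`): Wilcoxon signed-rank with the exact null for
$n \le 25$, paired $t$ with Cohen's $d$ of the differences. The pipeline
reports both one-tailed Wilcoxon and two-tailed $t$ rather than picking a
canonical sidedness. No multiple-testing correction is applied across the
handful of contrasts; the report labels every p-value as uncorrected, and
link-level archetype comparisons carry an explicit caveat that links are
treated as independent samples when they are not.

The **parcel-label permutation test** asks whether the temperature
contrast depends on the fitted architecture: each permutation scrambles
$h$ and the rows/columns of $J$ jointly, refits every subject/condition
temperature against the scrambled archetype, and recomputes the
one-sample $t$ of the paired differences. The p-value uses the add-one
estimator $p = (1 + \#\{t_{\mathrm{perm}} \ge t_{\mathrm{obs}}\})/(1 +
n_{\mathrm{perm}})$, which cannot return zero and is valid by
construction (the raw fraction is reported alongside). Two properties of
this test are worth knowing before interpreting it. First, temperature is
a *global scale* parameter, so scrambled architectures still recover a
substantial share of a true temperature shift; the permutation null is
not centered at zero, and the test's power comes from the sharpening the
true architecture provides. Second, at small $N$ and short series that
sharpening is modest: on the default generator (16 parcels, 434 time
points per subject/condition) per-cohort power at $\alpha = 0.05$ is
around 0.65 for a +7% shift, while type-I error is calibrated. With more
parcels or longer series the test sharpens considerably.

## Problem sizes in the shipped tests

The suite validates at sizes chosen for a desk machine: enumeration
oracles at $N \le 10$, sampler equivalence at $N = 8$ with $10^6$ flip
attempts, parameter recovery at $N = 10$ with $5\times10^4$ exact
samples, temperature recovery at $N = 16$ with $10^4$ sweeps, criticality
oracles on the 16×16 periodic lattice and the $N = 50$ complete graph,
and 20-replicate cohort studies at the generator defaults. Production
analyses can raise chain lengths and grid resolutions freely; everything
scales as stated above.

## Known limitations

* Pseudo-likelihood moment matching is consistent but not efficient;
  at BOLD-scale $t_{\max}$ the coupling estimates carry visible noise
  (the tests quantify this by recovery correlation rather than
  elementwise agreement).
* The $c\log_2 c$ description length overshoots the entropy rate at
  finite $n$ (see above); compare $\rho_0$ values only at matched string
  lengths.
* BDM with the entropy fallback degrades gracefully toward a block
  entropy; algorithmic (beyond-entropy) sensitivity requires an external
  CTM table.
* The permutation test's power depends strongly on parcel count and
  series length; a non-significant permutation p at small $N$ does not
  contradict a significant paired contrast.
* Exact enumeration stops at $N = 20$ by design; beyond that the sampler
  is validated only through its small-$N$ equivalence and its closed-form
  limits.
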