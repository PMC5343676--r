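---
title: "Graph-based subtyping of disease cohorts from cortical atrophy patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based subtyping of disease cohorts from cortical atrophy patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrophynet)
```

## The problem

Alzheimer's disease is anatomically heterogeneous: different patients lose
cortex in different places. A robust way to identify anatomical subtypes is
to compare patients by the *shape* of their cortical thinning pattern and to
cluster patients whose patterns agree. `atrophynet` implements that pipeline
as composable, tested stages:

1. **Atrophy z-scoring.** Patient thickness at location $i$ is standardized
   against the cognitively normal (CN) group:
   $z_{ij} = (t_{ij} - \mu_i)/\sigma_i$, with $\mu_i$, $\sigma_i$ the CN mean
   and (sample, $n-1$) standard deviation at that location. Dividing by
   $\sigma_i$ matters: where healthy anatomy is naturally variable, a thin
   cortex is weak evidence of atrophy; where it is tightly regulated, the
   same thinning is strong evidence.
2. **Patient similarity network.** The similarity of two patients is the
   Pearson correlation of their z-score vectors over the masked cortex.
   Correlation is invariant to each patient's overall atrophy severity (any
   per-patient positive affine transform of the pattern leaves it
   unchanged), so the network encodes *where* patients are atrophied, not
   *how much*.
3. **Subtyping by modularity maximization.** Communities in the similarity
   network are found by maximizing weighted modularity with a resolution
   parameter $\gamma$,
   $$Q = \frac{1}{2m}\sum_{jk}\Bigl(w_{jk} - \gamma\,\frac{k_j
   k_k}{2m}\Bigr)\,\delta(c_j, c_k),$$
   with a Louvain-type two-phase greedy optimizer. Because the optimizer is
   stochastic, the final partition is a majority vote over $N$ runs whose
   labels are aligned to the highest-$Q$ run by maximum-overlap matching.
4. **Validation and characterization.** A permutation test for the
   similarity structure, a leave-subset-out reproducibility statistic,
   a cross-cohort subtype-matching test, and an ROI-level "hallmark"
   analysis (permutation ANCOVA over subtypes adjusted for age, sex and
   education, with Benjamini–Hochberg FDR control).

A synthetic-cohort generator with planted subtype templates makes all of
this testable without clinical data, which is restricted for the cohorts
this kind of method is developed on.

## The synthetic cohort generator

`generate_cohort()` simulates thickness as
$t_{ij} = \mu_i + \sigma_i\,x_{ij}$ with per-location CN means and sds drawn
uniformly from configurable ranges (defaults give a CN grand mean of about
2.36 mm, matching published cohort summaries). For CN subjects
$x_{ij}\sim N(0,1)$: the CN group *defines* the z unit. For a patient of
subtype $k$, $x_{ij}\sim N(\mathrm{shift}_k(i) + g_j,\ \mathrm{noise\_sd}^2)$,
where $\mathrm{shift}_k$ is the subtype's template (a z-shift map) and $g_j$
an optional per-patient global severity offset. One construction detail is
deliberate: patient-level noise (`noise_sd`, default 0.2 z) is the patient's
deviation from their subtype template, while CN dispersion is unit variance
by definition — this is what makes the planted template depth come back as
the mean downstream z-score, so tests can assert recovery exactly.

The default templates mirror the three anatomical subtypes reported for
very mild Alzheimer's disease: **MT** (medial temporal-predominant; depth
−0.6 z on entorhinal, parahippocampal, temporal pole, insula, both
hemispheres), **P** (parietal-predominant; −0.6 z on precuneus,
supramarginal, inferior and superior parietal) and **D** (diffuse; −0.3 z
everywhere). Depths sit at the extremes of the reported subtype
median-atrophy band (−0.6 to −0.3 z). Default cohort composition is 320 CN
and 225 patients split 82/79/64 across MT/P/D, matching the published
cohort. Covariates (age ~ N(70, 8) years, education ~ N(10, 5) years, sex
~ Bernoulli(0.6 female)) are matched across groups by construction, with an
optional linear age slope on thickness for ANCOVA power studies.

**Location granularity.** The generator works at ROI-block resolution: each
of the 68 Desikan-style ROIs contributes `n_loc_per_roi` locations. The
default is 10 (680 locations). This is a deliberate compromise: the real
pipeline operates on ~82,000 surface vertices, where the Monte-Carlo noise
of a correlation across locations is negligible; at very coarse resolution
that noise (sd $\approx 1/\sqrt{p}$) becomes unrealistically large relative
to between-subtype signal and the diffuse subtype — whose template is flat,
so its within-subtype correlation is structurally near zero — frays into
neighbouring communities. 680 locations keep tests fast while staying in
the signal-to-noise regime the method actually faces.

What the generator does *not* emulate: spatial autocorrelation of noise
(cortical maps are smooth; independent noise is optimistic about effective
degrees of freedom), site/scanner effects, registration error, and
non-Gaussian thickness distributions. Passing tests therefore demonstrate
the statistical machinery is correct under its stated model, not that
clinical effect sizes will match.

## Parameters that matter

* `gamma` (resolution, default 0.9): scales the null-model penalty; larger
  values favor more, smaller communities. Following the practice of fixing
  the subtype count a priori (three, per post-mortem evidence),
  `tune_gamma()` scans a grid (default 0.5–1.5 by 0.05) and returns the
  value whose consensus has the target count, ties broken by Q.
* `n_runs` (default 1000 in `run_config()`): consensus votes. Inside
  resampling loops (reproducibility, permutation tests) the default drops
  to ~100 and ~10 respectively for tractability; vote fractions are the
  diagnostic for whether more runs would change anything.
* `noise_sd` (0.2 z) and template depths (−0.6/−0.3 z): the planted-effect
  scale of the generator, chosen from the reported median z band.
* `alpha` (Euclidean-exp comparator): regularization factor in
  $w = e^{-d/\alpha}$; `"auto"` uses the median off-diagonal distance so
  the weights occupy a comparable dynamic range on any cohort.
* `q` (FDR level, default 0.05) and `n_perm` (default 999) for the
  hallmark analysis.

## Numerical and design choices

* **Negative similarities.** Classical weighted modularity assumes
  nonnegative weights. Negative correlations are clipped to zero before
  optimization (the clipped fraction is logged on every partition); a
  signed variant with separate positive/negative null models is available
  via `negative = "signed"`.
* **Sample sd.** The CN reference uses the $n-1$ denominator. Zero-variance
  locations are dropped from the mask with a warning rather than erroring:
  frozen vertices occur in real exports and should not kill a pipeline.
* **Label alignment.** Consensus voting and reproducibility both need to
  match community labels across partitions; both use maximum-overlap
  matching on the label contingency table (exact assignment up to 7 labels,
  greedy beyond), with unmatched communities receiving fresh ids — in
  reproducibility those members count as inconsistent, which is the
  conservative direction. Vote ties break toward the lower aligned label
  id, so consensus is deterministic given a seed.
* **Louvain convergence.** Node visit order is a seeded random permutation
  per pass; a pass that improves Q by less than $10^{-12}$ stops the level.
  A node whose every candidate move has negative gain is parked in a fresh
  singleton community (gain exactly 0), which classical formulations
  require for correctness at large $\gamma$.
* **Permutation-test null.** What to permute is the one genuinely open
  design point, and the naive choice is wrong in an instructive way:
  shuffling each patient's z-vector across locations destroys not only
  shared atrophy structure but also the per-location offset and scale that
  *all* patients inherit from the finite CN reference fit ($\hat\mu_i$,
  $\hat\sigma_i$ are noisy). Under a true null the shuffled graphs then
  look sparser and *more* modular than the observed one, and the test's p
  collapses to 1. The implemented null therefore permutes each patient's
  *standardized deviation from the cohort-average per-location profile* and
  restores that profile afterwards — a Freedman–Lane-style residual
  permutation whose null hypothesis is "no patient-specific spatial
  structure beyond the shared profile". Type-I error was verified ≈ nominal
  under the null generator (the acceptance suite re-checks the 5% level
  across 200 null cohorts). Joint row/column permutation of the similarity
  matrix is retained as `scheme = "matrix-permute"`.
* **Permutation ANCOVA.** The partial F compares covariates+group against
  covariates only; the null is Freedman–Lane (permute reduced-model
  residuals, add back reduced fits). The observed F equals the closed-form
  ANCOVA partial F to machine precision, and permutation p matches the
  parametric p under Gaussian errors — both are asserted in the suite.
  Raw-response permutation is available via `scheme = "raw"`.
* **Hallmark attribution.** A surviving ROI is assigned to the subtype with
  the lowest covariate-adjusted mean normalized thickness. "Reveals a
  distinct pattern" is a verbal criterion in the source literature; lowest
  adjusted mean is our operationalization, and the per-subtype adjusted
  means are returned so users can apply stricter post-hoc contrasts.
* **Normalization coupling.** Normalized ROI thickness (ROI mean divided by
  the subject's whole-cortex mean, location-weighted) removes global
  severity but couples ROIs through the shared denominator: under a focal
  template, strictly "null" ROIs acquire a small systematic between-subtype
  difference of opposite sign. With large cohorts the ANCOVA correctly
  flags these as real differences, so FDR calibration is assessed on
  signal-free response simulations, and hallmark *recovery* (the planted
  focal regions are found and attributed to the right subtype) is assessed
  on generator cohorts.

## Scale of the shipped experiments

The test suite and the acceptance script rerun every stage from scratch at
sizes chosen to finish in minutes while keeping Monte-Carlo error well
inside the asserted margins: the modularity oracle enumerates all
partitions of 200 random graphs of up to 8 nodes (Bell(8) = 4140);
end-to-end recovery, metric contrast, reproducibility and the hallmark
analysis run on full-size default cohorts (320 CN / 225 AD / 680
locations); the permutation-test calibration uses 200 null cohorts of 30
patients with 99 permutations each; consensus inside resampling uses
N = 100 (full runs use N = 1000 by default).

## Known limitations

* Communities are hard assignments; borderline patients are visible only
  through low vote fractions, not posterior probabilities.
* The generator's independence assumptions (noise across locations,
  patients) understate the effective correlation of real surface data;
  absolute Q and reproducibility values on synthetic cohorts are therefore
  optimistic and should be read as mechanism checks, not forecasts.
* Only the Louvain family is implemented; Leiden-style refinements and
  overlapping communities are out of scope, as are surface reconstruction,
  vertex resampling and smoothing, which belong upstream.
* Permutation schemes for this family of analyses are rarely reported in
  enough detail to replicate exactly; the schemes here were chosen for
  statistical validity and are documented above, with the alternatives
  available behind flags.
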