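# atrophynet

Graph-based subtyping of disease cohorts from cortical atrophy patterns.

Neurodegenerative diseases such as Alzheimer's disease are anatomically
heterogeneous: different patients lose cortex in different places, and
those anatomical subtypes differ clinically. `atrophynet` is for
researchers who have cortical thickness measurements for a patient group
and a cognitively normal (CN) control group and want to extract, validate
and characterize anatomical subtypes. The package implements the full
pipeline:

1. **Atrophy z-scoring.** Thickness at location *i* for patient *j* is
   standardized against the CN distribution,
   `z_ij = (t_ij − μ_i) / σ_i`, so a patient's concatenated z-scores are
   their *cortical atrophy pattern* (negative = thinning). Dividing by the
   CN standard deviation weights thinning by how tightly that location is
   regulated in healthy anatomy.
2. **Patient similarity network.** Similarity between two patients is the
   Pearson correlation of their atrophy patterns over the masked cortex —
   invariant to each patient's overall severity, so the network captures
   *where* patients are atrophied, not *how much*. An exponential-Euclidean
   comparator, `w_jk = exp(−d_jk/α)`, is included for method comparison.
3. **Subtyping.** Communities of mutually similar patients are found by
   maximizing weighted modularity with a resolution parameter γ,

   `Q = (1/2m) Σ_jk [ w_jk − γ k_j k_k / (2m) ] δ(c_j, c_k)`,

   using a Louvain-type two-phase greedy optimizer (implemented in C++),
   with a majority-vote consensus over N stochastic runs and optional γ
   tuning to a target subtype count. Hierarchical-clustering comparators
   are provided.
4. **Validation and hallmarks.** Permutation test of the similarity
   structure, leave-subset-out reproducibility (the average fraction of
   patients keeping their subtype when 10% of the sample is removed),
   cross-cohort subtype matching, and per-ROI hallmark analysis:
   permutation-based ANCOVA of normalized ROI thickness across subtypes
   (adjusted for age, sex, education) with Benjamini–Hochberg FDR control.

A synthetic-cohort generator with planted subtype templates (medial
temporal-predominant MT, parietal-predominant P, diffuse D) makes every
stage testable without access to restricted clinical data.

## Worked example

Simulate a cohort with three planted subtypes, score atrophy, build the
similarity network, and extract consensus subtypes:

```r
library(atrophynet)

sim <- generate_cohort(cohort_config(n_cn = 120, n_ad = 90,
                                     n_loc_per_roi = 4,
                                     subtype_proportions = c(1, 1, 1)/3),
                       default_templates(), seed = 42)
sim$cohort
#> <cohort> 210 subjects (120 CN / 90 AD), 272 locations (272 masked), 68 ROIs

patterns <- compute_atrophy(sim$cohort)
net      <- correlation_similarity(patterns)
subtypes <- consensus_vote(net, gamma = 0.9, n_runs = 200, seed = 1)
subtypes
#> <subtype_partition> 90 subjects in 3 communities (sizes 30/30/30)
#>   Q = 0.3927 at gamma = 0.9, 200 run(s), mean vote fraction 1.000

table(planted = sim$truth$subtype, assigned = subtypes$labels)
#>        assigned
#> planted  0  1  2
#>      D   0 30  0
#>      MT 30  0  0
#>      P   0  0 30
```

The partition's `Q` is the modularity of the consensus labels at the given
resolution; `vote fraction` is the per-patient agreement across the 200
stochastic runs (1.0 = every run assigned the patient to the same aligned
community). Here the three planted subtypes are recovered exactly.

Stability under sample perturbation:

```r
reproducibility(sim$cohort, gamma = 0.9, n_runs = 50, n_subsets = 10,
                seed = 2)
#> <reproducibility> 100.00% over 10 subsets (range 100.0-100.0%)
```

Each of the 10 reruns removes one tenth of the patients, repeats the whole
pipeline (z-scoring, similarity, consensus) and reports the fraction of
retained patients keeping their subtype label after maximum-overlap
alignment to the full-cohort reference.

Downstream, `select_hallmarks()` tests every ROI's normalized thickness
across subtypes (permutation ANCOVA, FDR) and attributes each surviving
ROI to the subtype with the lowest covariate-adjusted mean;
`run_pipeline()` chains all stages and writes delimited outputs, and
`inst/cli/atrophynet.R` exposes `simulate`, `run` and `compare`
subcommands for shell use.

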