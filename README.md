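# odorcolor

Analysis of crossmodal **color–odor associations** from forced-choice
matching experiments, for sensory and crossmodal-perception researchers.
In the underlying task, participants from several groups smell each of 14
odors and pick, from a 36-color palette (the 32 Berkeley Color Project
colors plus white, light gray, dark gray and black), the **three most
congruent** and **three most incongruent** colors per odor. The package
answers three questions about such data:

1. **Within-group consistency.** For each odor, the pooled congruent and
   incongruent 36-count vectors are tested against uniform random choice
   with Pearson chi-square statistics, χ² = Σᵢ (Oᵢ − Eᵢ)²/Eᵢ with
   Eᵢ = 3n/36, combined over the two choice types (df = 70) and flagged at
   the Bonferroni threshold α/m (0.05/84 ≈ 0.0006 for 6 groups × 14
   odors). A finite-population correction (35/33) calibrates the statistic
   for the 3-distinct-choices design.
2. **Odor identifiability.** A Fisher linear discriminant on the
   72-feature color patterns (36 congruent + 36 incongruent counts), with
   the pooled covariance shrunk toward (tr(S)/p)·I, is evaluated by
   3-fold cross-validation over participants under many random refoldings.
   Significance comes from a permutation null: color identities are
   permuted independently per trial, destroying any stable color–odor
   association; chance level is 1/14 ≈ 7%.
3. **Representational structure.** Each group's odors are compared by the
   correlation distance d = 1 − Pearson r between pooled patterns, giving
   a 14×14 representational dissimilarity matrix (RDM, zero diagonal); the
   **second-order** 6×6 RDM compares groups by 1 − r between the upper
   triangles of their odor RDMs.

A seeded generator produces synthetic datasets with the study's structure
(6 groups of 20/22 participants, 122 total) from Dirichlet color-propensity
profiles, with tunable within-group consistency (`kappa`) and cross-group
sharing (`rho`), so the full pipeline is testable without the original
human data.

## Worked example

```r
library(odorcolor)

cfg <- generator_config(seed = 42)   # study-scale synthetic data
ds  <- generate_dataset(cfg)
ds
#> <odor_dataset> 10248 choice records; 6 group(s), 122 participant(s), 14 odor(s), 36 colors

cons <- test_group_consistency(ds, "us")
head(as.data.frame(cons)[, c("group","odor","chi2","df","p","significant_bonferroni")], 4)
#>   group   odor chi2 df        p significant_bonferroni
#> 1    us  burnt  196 70 8.29e-14                   TRUE
#> 2    us  candy  198 70 3.86e-14                   TRUE
#> 3    us   fish  179 70 1.51e-11                   TRUE
#> 4    us flower  208 70 1.18e-15                   TRUE

res <- permutation_test(ds, "us", n_shuffles = 200, n_permutations = 500, seed = 42)
res
#> Odor classification from color patterns -- group 'us'
#>   mean accuracy: 96.9% (SD = 0.026, 200 refoldings)
#>   permutation null: mean 7.2% (500 repetitions, per_trial scheme)
#>   p = 0.001996

rdms <- lapply(ds$groups, function(g) compute_rdm(ds, g)); names(rdms) <- ds$groups
so <- second_order_rdm(rdms)
round(so$matrix["us", ], 2)
#>               dutch              german               malay   malaysian_chinese
#>                0.87                1.11                0.97                0.87
#> netherlands_chinese                 us
#>                0.81                0.00
```

Reading the output: every odor's choice pattern is wildly non-uniform
(p ≪ 0.0006), so the synthetic "US" group is internally consistent; the
classifier identifies odors from color patterns almost perfectly (96.9%
versus the 7.2% permutation null — synthetic groups share one profile, so
they are easier than real participants), and the second-order row shows
which groups' association geometries resemble the US group's most
(smaller = more similar). `run_pipeline(pipeline_config(...))` executes
all stages at once and writes tables, figures and a provenance manifest.

## Package layout

* `R/` — palette and dataset I/O, the Dirichlet generator, pattern
  compilation, chi-square consistency, shrinkage FLD +
  cross-validation + permutation null, RDMs, pipeline and figures.
* `tests/testthat/` — unit, property and acceptance suites (all fixtures
  generated in code).
* `vignettes/color-odor-associations.Rmd` — the methods vignette: model
  assumptions, calibration choices, numerical details, limitations.
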