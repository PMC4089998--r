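---
title: "Analysing color-odor associations across groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing color-odor associations across groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorcolor)
```

## The problem and the data model

People associate odors with colors: a fruity smell with pinks and reds, a
musty one with browns. When participants from several cultural groups pick,
for each of 14 odors, the three colors that match it best (*congruent*) and
the three that match it worst (*incongruent*) out of a 36-color palette,
three questions arise:

1. **Consistency** -- within one group, are the color choices for an odor
   non-random?
2. **Specificity** -- do the odors' color profiles differ enough that an
   odor can be identified from its color pattern alone?
3. **Structure** -- how similar is the geometry of odor-color associations
   *between* groups?

`odorcolor` answers each with a dedicated stage: chi-square consistency
tests, a cross-validated linear discriminant classifier with a
color-permutation null, and first- and second-order representational
dissimilarity matrices (RDMs).

The unit of data is one choice: a row `(group, participant, odor,
choice_type, color_id)`. A valid dataset has exactly 3 congruent and 3
incongruent choices per participant and odor, the six colors distinct;
`validate_dataset()` enforces this, and the reader rejects any file that
breaks it. All statistics depend only on `color_id`; the palette's RGB
entries are used for rendering figures alone.

## The synthetic-data generator

The human data are not redistributed with the package, so every stage is
exercised against a generative stand-in whose defaults emulate the study
design: **6 groups** (five of 20 participants, one of 22 -- 122 in total),
**14 odors**, **36 colors**, 3 + 3 choices per trial.

For each odor, each group carries a pair of propensity vectors over the 36
colors (one congruent, one incongruent), drawn from symmetric Dirichlet
distributions:

* `kappa` (concentration) controls spikiness. Small `kappa` concentrates
  mass on few colors, so participants agree -- high within-group
  consistency and high classifier accuracy. `kappa = 5` is close to
  uniform; `kappa = 0.05` is highly consistent. The default `kappa = 0.5`
  produces strong but non-degenerate profiles: every consistency test
  fires, and -- because profiles are shared by a whole group (see below) --
  classification on default synthetic data runs near ceiling, markedly
  higher than on real, participant-heterogeneous data of the same size.
* `rho` mixes a shared global profile into every group's profile
  (`rho = 1`: all groups identical; `rho = 0`: independent). The default
  `rho = 0.3` reflects that real groups share substantial common structure
  (e.g. fruity-pink) while differing in the details.
* `group_pairs_shared` plants exact cross-group structure for testing the
  second-order analysis.

A trial samples 3 distinct congruent colors by sequential weighted sampling
without replacement, then 3 incongruent colors from the remaining 33
(renormalised), which guarantees the disjointness invariant by
construction. Every `(group, participant, odor)` trial draws from its own
RNG substream derived by counter-based mixing of the master seed with
hashes of the group and odor labels, so a dataset is a pure function of its
configuration, stable under reordering of groups, odors or loops.

What the generator does **not** emulate: participant-level heterogeneity
(all members of a group share one profile), odor intensity or pleasantness
effects, response times, and any dependence between an individual's
congruent and incongruent propensities beyond disjointness. Tests passing
on synthetic data therefore demonstrate that the *pipeline* recovers
planted structure at realistic sizes -- not that real populations behave
like Dirichlet profiles.

## Color patterns and the fold scheme

The analysis never models single trials; it pools them. A **color
pattern** for one odor in one group is a 72-feature count vector -- for
each of the 36 colors, the number of congruent choices and the number of
incongruent choices. With `n` participants each half sums to `3n`.

Cross-validation needs several pattern samples per odor. Participants are
partitioned at random into 3 near-equal folds (7/7/6 for 20), one pattern
compiled per fold and odor; training uses two folds, testing the third,
and each fold rotates through the test role. One such rotation is one
cross-validation pass, repeated over many seeded refoldings to obtain a
stable accuracy sample. Fold sizes may differ, so for classification each
fold pattern is divided by its participant count (`normalize = TRUE`);
the raw-count variant remains available. Correlation-based dissimilarities
use raw pooled counts -- Pearson correlation is location/scale invariant,
so normalisation is irrelevant there.

## Chi-square consistency testing

For each odor the congruent and incongruent 36-vectors are tested against
the uniform expectation `3n/36` per color; the two statistics (df = 35
each) are reported separately and summed (df = 70) for the headline
per-odor test, flagged at the Bonferroni threshold `alpha / m` with
`m = groups x odors` (0.05 / 84 ≈ 0.0006 at study scale).

One calibration choice deserves a note. Each participant's 3 choices per
type are *distinct* -- sampling without replacement -- so the count
vector is slightly underdispersed relative to the multinomial model behind
the chi-square reference. Simulation shows the plain Pearson statistic
rejects true-null data at only ≈2--2.5% when the nominal level is 5%.
`test_group_consistency()` therefore rescales the statistic by the
standard finite-population factor `(K-1)/(K-m) = 35/33` (K = 36 colors,
m = 3 choices per type), which restores the empirical type-I error to
≈4.5%. `correct = FALSE` gives the uncorrected statistic. At study-scale
group sizes the expected count per cell is below 5 (≈1.7), which the
function flags with a warning; the chi-square approximation is coarse
there, which is why the package's calibration checks rely on simulation
rather than asymptotics.

## Classification and the permutation null

The classifier is Fisher's linear discriminant: class (odor) means under a
pooled within-class covariance, equal priors, ties broken by class-label
order. With 72 features and ~28 training patterns the pooled covariance is
singular, so shrinkage toward the scaled identity `(tr(S)/p) I` is
mandatory. The default coefficient is the analytic variance-minimising
(Ledoit-Wolf-type) estimate computed from the training patterns;
`shrinkage = 1` reduces the classifier exactly to nearest-class-mean
(verified against a brute-force oracle in the tests), and any fixed
coefficient can be supplied. The pooled covariance uses the
maximum-likelihood denominator `n`, making the fit invariant under
duplicating the training set.

The significance of an observed accuracy is assessed against a null that
destroys color-odor structure: for each of `n_permutations` repetitions,
an independent random permutation of the 36 color identities is applied to
every participant x odor trial, patterns are recompiled, and one
cross-validation pass is run (one refolding per repetition). The p-value
is add-one smoothed, `(1 + #(null >= observed)) / (1 + n_permutations)`,
so it is never zero. Permuting *per trial* is the default because a single
shared permutation would relabel colors coherently for all participants,
preserving within-group agreement -- it cannot serve as a stability null
(the `"global"` scheme is available for comparison and the tests
demonstrate its powerlessness).

Two properties worth knowing when interpreting accuracies:

* each refolding accuracy is a multiple of `1 / (odors x folds)`;
* on association-free data the *expected* accuracy is `1/14 ≈ 7%`, but one
  20-participant dataset's cross-validated accuracy scatters around that
  with an SD of several percentage points, because spurious structure in a
  finite sample persists across refoldings. The permutation-null mean,
  which redraws the randomness each repetition, is far more stable. The
  package's chance-level checks average over groups and use standard-error
  intervals accordingly.

## Representational dissimilarity

The dissimilarity between two patterns is `1 - Pearson r` (0 identical,
1 unrelated, 2 anti-correlated). A group's first-order RDM compares the
whole-group pooled patterns of all odor pairs; the diagonal is set to
exactly zero by construction rather than computed, avoiding `1 - r`
round-off of order 1e-16. Off-diagonal values are clamped to `[0, 2]`
against the same round-off. A color-shuffle null distribution for the RDM
reuses the per-trial permutation scheme; since shuffled patterns are
independent, it centres at dissimilarity 1. A participant-level bootstrap
(`method = "participant_bootstrap"`) is provided for uncertainty -- as
opposed to null -- estimation.

The second-order RDM compares groups: `1 - r` between the vectorised
strict upper triangles of two groups' odor RDMs. Pearson is the default
for consistency with the first-order measure; a Spearman variant is
exposed because rank correlation is common in the RSA literature and the
choice is not neutral -- cross-group orderings can change with the metric.
A congruent-only (or incongruent-only) feature mask is available for
sensitivity analyses; the full 72-feature pattern is the default because
incongruent choices carry independent information about the association
space.

## Numerical and design choices

* **Determinism.** Every stochastic stage takes a seed and derives
  substreams per logical unit; the full pipeline is a pure function of its
  configuration, and its provenance manifest (config hash, seed, versions)
  is timestamp-free so re-runs are byte-identical.
* **Identifiers** are trimmed and lower-cased on input; odor and group
  orderings are taken from the configuration when given, else
  lexicographic, so matrix outputs are reproducible.
* **Degenerate inputs.** Constant patterns make the correlation distance
  undefined and raise errors rather than NaNs; a zero within-class
  covariance (identical replicates) falls back to the isotropic metric,
  i.e. nearest-class-mean; profiles with fewer than 3 positive-mass colors
  are generation errors.
* **Ties** in the discriminant are broken by class-label order,
  deterministically.

## Problem sizes used by the test suite

The package's own checks run at reduced but structure-preserving sizes
chosen to keep the suite fast while leaving every statistical property
detectable: consistency calibration at 1,000 replicate null groups of 20
participants; classifier chance-level checks at 200 refoldings and 500
permutation repetitions; planted second-order recovery at 100 replicates
of three 20-participant groups with `kappa = 0.1`; power and monotonicity
probes at 6-12 participants and 3-5 odors. Study-scale defaults (1,000
refoldings, 10,000 permutations) remain the function defaults.

## Limitations

* The chi-square calibration factor corrects the marginal variance of
  without-replacement sampling but not the (small) negative covariance
  between the congruent and incongruent halves induced by disjointness;
  the combined test is accordingly still very slightly conservative
  (≈4.5% empirical type-I at the 5% level).
* With ~20 participants per group, cross-validated accuracy estimates
  carry dataset-level noise of a few percentage points; comparisons
  between groups of this size should lean on the permutation test, not on
  point accuracies.
* The generator's group-shared profiles mean synthetic within-group
  consistency is an upper bound on what participant-heterogeneous real
  data would show at the same `kappa`.

## A minimal run

```{r, eval = FALSE}
cfg <- pipeline_config(
  generator = generator_config(seed = 1),
  n_shuffles = 1000, n_permutations = 10000,
  out_dir = "odorcolor_out", seed = 1)
bundle <- run_pipeline(cfg)
bundle$accuracy_table
bundle$second_order
```
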