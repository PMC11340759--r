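---
title: "Tracking donor-strain engraftment after FMT and linking it to clinical outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking donor-strain engraftment after FMT and linking it to clinical outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmtlink)
```

## The problem

A fecal microbiota transplantation (FMT) is not one intervention but dozens:
each donor strain either engrafts in the recipient or it does not, and any
clinical benefit may be carried by a few engrafting strains rather than by a
wholesale shift of the community.  Community-level summaries (beta-diversity
ordinations) are typically too blunt to resolve this.  `fmtlink` implements a
strain-resolved framework: it decides, species by species and recipient by
recipient, whether the post-FMT strain came from the donor or was retained
from the recipient, and then asks whether those engraftment events track
changes in clinical parameters and circulating metabolites.

The unit of analysis is the **FMT triad**: the donor sample, the recipient's
pre-FMT sample, and the recipient's post-FMT sample.  A donor may serve
several recipients, so triads share donors and form small networks.

## Strain identity from phylogenetic distances

There is no universal genomic definition of "same strain".  The framework
uses an operational, species-specific one.  For each species-level genome
bin (SGB) we have pairwise normalized phylogenetic distances between the
dominant strain profiles of all samples (from per-SGB marker trees;
distances are patristic path lengths divided by the tree's total branch
length, and precomputed matrices may be supplied directly).  Two empirical
distance distributions are contrasted:

* **related pairs** — pairs that plausibly carry the same strain: the
  same subject before and after FMT, and donor/post-FMT pairs within a
  triad (the donor's strain may have engrafted);
* **unrelated pairs** — cross-subject pairs with no triad relation.

Within-triad donor/pre pairs precede any transplantation link; they are
placed in the unrelated class by the labeling rule's exclusion logic
(they belong to neither contrast class and are dropped).

The per-SGB strain-identity threshold *t* is estimated as:

* with at least 50 related pairs: the more conservative (smaller) of the
  Youden-optimal cutoff (maximizing sensitivity + specificity − 1 for
  classifying related pairs by *d* ≤ *t*) and the 5th percentile of the
  unrelated distances;
* with fewer than 50 related pairs: the 3rd percentile of the unrelated
  distances, which by construction calibrates the false-sharing rate among
  unrelated pairs to about 3%.

Numerical conventions, fixed and tested because they change results at the
margin: percentiles use linear interpolation between order statistics
(type 7); the sharing boundary is inclusive (*d* = *t* counts as shared);
the Youden scan uses the sorted unique observed distances as its candidate
grid — under the inclusive rule every threshold between consecutive
observations classifies identically to its left endpoint, so this grid is
an exhaustive scan over achievable classifications — and ties in J break
toward the smallest threshold (fewest sharing calls).  "At least 50
related" counts related *pairs* passing the profile filters.  Samples enter
an SGB's analysis only with at least 20 markers; a marker-prevalence helper
(kept if present in at least half the samples) is provided for callers with
marker-level data.

### Origin assignment

For each SGB present in a post-FMT sample, sharing with the donor and with
the pre-FMT sample is called at the threshold.  Shared only with the donor:
origin `donor`.  Only with pre-FMT: `recipient`.  With both: the side with
the *lowest* distance wins.  Absent pre-FMT but shared with the donor:
`novel_donor` — engraftment into an empty niche, the pattern *Prevotella
copri* clade A shows in MetSyn cohorts.  Shared with neither:
`retained_unshared` (flagged `de_novo` when the SGB is new post-FMT).  The
binary engraftment matrix marks `donor` and `novel_donor` origins.

Engrafted strains are further classified by their abundance behaviour:
`novel` (absent pre-FMT), `expansion` (significant paired abundance
increase across engrafted subjects, two-sided Wilcoxon signed-rank — the
test is not named by the strain-tracking literature; the signed-rank test
was chosen for robustness on compositional fractions), or `replacement`
(engraftment into a fixed niche).

## Cohort-level metrics

The strain-sharing rate of a sample pair is the number of shared strains
over the SGBs strain-profiled in both samples.  Post-FMT anchored fractions
divide by the strains profiled at post-FMT: `f_donor` and `f_pre` can sum
to more than 1 because a strain shared with both sides counts in both
numerators.  Sharing networks (nodes = samples, edge weight = squared
shared-strain count, Fruchterman-Reingold layout under a fixed seed) are
exported per sub-study.

A dissimilarity regression quantifies the donor signal: for every
(recipient sample, donor sample) combination, dissimilarity = 1 − shared /
common, regressed on sample type (pre/post), true-donor status, and their
interaction.  The interaction coefficient (`beta_donor_post`) is the
engraftment-attributable drop in dissimilarity of post-FMT samples toward
their own donor.  The interaction reading is the default because the
reported quantity is a combined donor-by-post effect; a main-effects-only
switch is provided.  The pair universe defaults to within-sub-study
combinations (donors are only comparable to recipients recruited under the
same protocol); all-pairs pooling is available.

## Linking engraftment to outcomes

With ~19–29 subjects and dozens of candidate strains, a direct regression
per (strain, parameter) pair would be hopelessly multiple.  The framework
follows a funnel:

1. **Regularized CCA.**  X = binary engraftment of the top-engrafting
   strains, Y = post-minus-pre clinical deltas, both centered and scaled;
   ridge penalties on both sides because subjects are few relative to
   features.  Canonical directions solve the generalized eigenproblem of
   (Cxx + λ₁I)⁻¹Cxy(Cyy + λ₂I)⁻¹Cyx, computed by SVD of the
   doubly-whitened cross-covariance.  Penalties are tuned by leave-one-out
   cross-validation on a 21-point log-spaced grid in [10⁻⁴, 1]: each
   held-out subject is scored on the first canonical pair fit without it
   (standardization parameters from the training fold), the pooled held-out
   score pairs are correlated, and the best grid point wins, ties breaking
   toward larger penalties (more shrinkage at equal evidence).  Fold
   loadings are sign-aligned to a full-data reference fit before pooling —
   a joint sign flip of a fold's X and Y loadings leaves its model
   equivalent, and without alignment the pooled correlation is corrupted by
   arbitrary SVD signs.
2. **Correlation circle and inner products.**  Each feature is placed at
   its correlations with the first two canonical variates of its own
   dataset.  Features in the outer ring (radius ≥ 0.5; the radius is a
   convention of correlation-circle plots, not a published constant, and is
   configurable) are considered well represented; all cross-dataset pairs
   of outer features are scored by the 2-D inner product of their
   coordinates and the top 10 absolute values are kept.  Within-dataset
   pairs are not scored — the question is strain-to-outcome links.
3. **Mixed-effects confirmation.**  Each selected (strain, parameter) pair
   is tested on the long pre/post data with
   `value ~ engrafted * time + (1 | subject)`; the interaction is the
   engraftment-attributable change in the parameter's own units, p-values
   use Satterthwaite degrees of freedom on the REML fit (via `lmerTest`),
   and Benjamini–Hochberg FDR is applied across the selected set.  The
   mixed model uses all subjects, including those dropped from the
   complete-case rCCA.  On balanced complete noiseless data the interaction
   equals the difference-in-differences of cell means exactly — a useful
   identity for validation.  On zero-residual data the fit is degenerate;
   estimates remain the difference-in-differences but singular fits are
   flagged and their p-values should not be trusted.
4. **Metabolite mediation candidates.**  Metabolite intensities are
   normalized per metabolite by imputing missing cells with half the lowest
   observed value (below-detection semantics) *then* scaling the column to
   median 1; the impute-then-scale order is a documented choice, tested by
   a worked example, as the verbal description admits both orders.
   Metabolites whose pre/post change tracks engraftment of the selected
   strains (same mixed model, metabolite as outcome) are then correlated
   (Spearman; exact p below 10 untied pairs, t-approximation otherwise)
   with the clinical deltas.  Global concordance between data modalities is
   tested by Procrustes superposition of principal-coordinate reductions
   (default 2 dimensions; the ordination fed to the test is a package
   choice) with a 999-permutation test, and a multilevel (between/within
   subject) split with PCA on the within part isolates the repeated-measures
   component of the metabolome.  Which test links the within-subject
   metabolite structure to a specific clinical parameter is left to the
   analyst; the package supplies the decomposition, not a canned test.

## The synthetic cohort generator

Every stage is testable without any sequencing data through
`simulate_cohort()`.  Its defaults emulate the structure of a pooled
MetSyn FMT cohort: 29 triads over 3 sub-studies, 8 donors assigned
round-robin (so donors serve several recipients, as in real sharing
networks), 50 SGBs, and 10 subjects of the second sub-study missing
diastolic blood pressure (complete cases for blood-pressure analyses:
19).  Per SGB and triad, engraftment is drawn by a per-SGB probability;
engrafted post strains sit at same-strain distance from the donor
(truncated normal, mean 0.01, sd 0.004) and different-strain distance from
the pre sample (mean 0.20, sd 0.06), and conversely for retained strains;
all cross-subject pairs draw from the different-strain distribution.  The
same-strain location matches the scale of published strain-identity
thresholds on normalized phylogenetic distances; truncated normals are
used because every downstream step consumes only orderings and quantiles.
Engraftment probabilities are long-tailed (three effect-carrying SGBs at
0.5, the rest decaying to 0.05), mirroring the strongly skewed transfer
frequencies of real cohorts in which the outcome-associated strains are
among the most transferred.  Planted effects add fixed deltas to clinical
parameters and metabolites of engrafted subjects (defaults: −16.0, −19.5
and −13.2 mmHg on diastolic blood pressure and a −0.5 shift of metabolite
`M01`, against a 5 mmHg within-subject change noise), giving a known
engraftment → metabolite → clinical chain.  A master seed fixes
everything; per-SGB sub-seeds are derived deterministically so adding SGBs
does not reshuffle earlier ones, and fixtures written twice with one seed
are byte-identical.

What the generator does *not* emulate, and hence what green tests do not
establish about real data: distance matrices are not transitively
consistent (two recipients engrafting the same donor strain still draw an
unrelated-level distance from each other) and need not satisfy the
triangle inequality; abundances are compositional only to a fixed 0.95
total; there are no batch effects between sub-studies, no marker-level
dropout structure, and clinical/metabolite noise is Gaussian and
homoscedastic.  The generator validates the *inference machinery*, not the
biology.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_markers` | 20 | per-sample marker minimum for an SGB profile |
| `min_related` | 50 | related-pair count switching pct3 → Youden/pct5 |
| `r_outer` | 0.5 | correlation-circle outer-ring radius |
| `k_pairs` | 10 | pairs carried into mixed-model testing |
| `lambda_grid` | 21 points, 10⁻⁴–1 (log) | ridge tuning grid per side |
| `n_perm` | 999 | Procrustes permutations |
| `pattern_alpha` | 0.05 | abundance-increase level for `expansion` |
| `fdr_method` | BH | multiplicity correction over selected pairs |

## Design choices where the design was open

* **"Most conservative" threshold** is read as the *smaller* of Youden and
  pct5 — conservative with respect to declaring engraftment.
* **Distance normalization** divides patristic distance by total branch
  length; precomputed matrices declare themselves already normalized via
  the `normalizer` field.  The convention is declared, not asserted, to
  match any particular upstream tool.
* **Selection-stage penalties vs. testing**: rCCA selects candidates; all
  confirmatory inference happens in the mixed model on unreduced data, so
  the selection step's tuning noise does not propagate into p-values
  (though selection and testing share the data, as in the original design —
  the FDR is over the selected set only).
* **Reliability of inner-product selection degrades with panel size**: at
  19 subjects the planted-pair recovery of the top-10 selection is high
  for small pre-selected panels (around eight strains by four parameters)
  and falls as the pair universe grows.  This is why the framework, like
  the study design it follows, pre-selects a small clinical sub-panel and
  the top-engrafting strains before rCCA, and it is a real limitation for
  larger panels.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script validate calibration on 500
simulated SGBs (1000 unrelated pairs each), engraftment recovery on a
29-triad × 50-SGB noise-free cohort, rCCA oracle agreement on 100 random
instances, selection recovery on 200 replicates of a 19-subject cohort,
mixed-model type-I error on 1000 null simulations, Procrustes null
calibration on 100 replicates of 999 permutations, and a full default
pipeline run compared bit-for-bit against a stored manifest.

## Known limitations

* Threshold estimation needs unrelated pairs; SGBs observed in very few
  samples are flagged not estimable rather than given a default threshold
  (reproducing the behaviour of omitting low-prevalence species).
* The Satterthwaite degrees of freedom come from `lmerTest`'s two-moment
  approximation; they are validated by simulation calibration, not by
  bit-agreement with any other mixed-model implementation.
* The multilevel PCA stage provides the decomposition only; linking its
  components to outcomes requires an analyst-chosen test.
* With `sd = 0` distance distributions the percentile thresholds collapse
  onto the different-strain mode and *every* pair is inclusively shared;
  origin assignment still recovers the truth through the lowest-distance
  rule, but sharing-rate metrics are degenerate in that corner — use small
  positive spreads when exercising the metrics.
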