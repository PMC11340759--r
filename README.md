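# fmtlink

Strain-resolved analysis of fecal microbiota transplantation (FMT)
studies: who engrafted, in whom, and did it matter clinically?

An FMT delivers dozens of donor strains at once, and each either engrafts
in the recipient or is outcompeted by the native strain.  `fmtlink` treats
every (species, recipient) engraftment event as its own intervention and
provides the full chain of analysis for cohorts of **FMT triads** (donor
sample, recipient pre-FMT, recipient post-FMT):

* **Strain-identity thresholds.**  Per species-level genome bin (SGB), an
  operational "same strain" cutoff *t* on normalized phylogenetic
  distances, estimated by contrasting related pairs (same-subject pre/post
  and within-triad donor/post) with unrelated cross-subject pairs.  With
  ≥ 50 related pairs, *t* = min(Youden-optimal cutoff, 5th percentile of
  unrelated distances); with fewer, *t* = 3rd percentile of the unrelated
  distances, which calibrates false sharing among unrelated pairs to ≈ 3%.
* **Origin assignment.**  A post-FMT strain shared (d ≤ t) only with the
  donor is donor-derived; only with pre-FMT, recipient-derived; with both,
  the lowest distance wins; absent pre-FMT but shared with the donor,
  novel engraftment into an empty niche.
* **Engraftment metrics.**  Strain-sharing rates (shared strains over SGBs
  profiled in common), post-anchored donor/pre fractions, sharing networks
  (squared shared-strain edge weights, Fruchterman–Reingold layout), a
  dissimilarity regression whose donor × post interaction quantifies the
  engraftment signal, and novel / replacement / expansion pattern calls
  with paired Wilcoxon abundance tests.
* **Outcome integration.**  Ridge-regularized canonical correlation
  between binary engraftment and post-minus-pre clinical deltas
  (leave-one-out tuned penalties, pooled held-out scoring), candidate
  pairs picked by the top-10 absolute inner products of correlation-circle
  coordinates, then confirmed by linear mixed-effects models
  (`value ~ engrafted * time + (1 | subject)`, Satterthwaite df, BH-FDR),
  with metabolite normalization (half-minimum imputation, unit medians),
  Spearman links, Procrustes permutation tests and a multilevel
  between/within-subject decomposition.
* **Synthetic cohorts.**  A seeded generator of complete FMT cohorts
  (triads, distances, abundances, clinical and metabolite tables) with
  known engraftment ground truth and planted
  engraftment → metabolite → clinical effects, so the whole pipeline is
  testable end to end without any sequencing data.

## Worked example

```r
library(fmtlink)

bundle <- simulate_cohort(sim_config(seed = 42))   # 29 triads, 50 SGBs
thresholds <- estimate_thresholds(bundle$triads, bundle$distances)
head(thresholds[, c("sgb_id", "threshold", "rule", "n_related", "n_unrelated")], 3)
#>    sgb_id  threshold rule n_related n_unrelated
#> 1 SGB0001 0.08421851 pct3        47        1417
#> 2 SGB0002 0.07865571 pct3        38         936
#> 3 SGB0003 0.09020695 pct3        40        1323

origins <- call_origins(bundle$triads, bundle$distances, thresholds)
M <- build_engraftment_matrix(origins)
sum(M)            # 316 engraftment events across 1450 (SGB, recipient) cells

calls <- strain_calls(bundle$triads, bundle$distances, thresholds)
head(post_fractions(calls), 3)
#>   subject_id substudy n_post   f_donor     f_pre
#> 1        R01   study1     43 0.2790698 0.7674419
#> 2        R02   study1     40 0.3000000 0.7000000
#> 3        R03   study1     38 0.3947368 0.6315789

fit_dissimilarity_model(calls)$beta_donor_post
#> [1] -0.3341957
```

Each SGB gets its own threshold (here all by the 3rd-percentile rule — with
29 triads no SGB reaches 50 related pairs).  About a fifth to a third of
post-FMT strains derive from the donor (`f_donor`), most are retained
(`f_pre`), and post-FMT samples are ~0.33 *less* dissimilar to their own
donor than expected (the negative donor × post coefficient) — donor strains
demonstrably engrafted.  On this cohort the recovered engraftment matrix
agrees with the generator's ground truth in 100% of cells.

The full pipeline — simulate, thresholds, engraftment, metrics, rCCA
integration, mixed-model link statistics — runs as one reproducible,
file-based chain:

```r
manifest <- run_pipeline(default_run_config(seed = 20), "out")
manifest$statistics$top_lmm_sgb        # "SGB0002" (a planted effect strain)
manifest$statistics$top_lmm_estimate   # -12.3 mmHg on diastolic blood pressure
manifest$statistics$top_lmm_p_fdr      # 0.038
```

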