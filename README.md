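# flavormet

Harvest-time studies of herbal teas ask a deceptively simple question —
*when should the leaves be picked?* — and answer it with three blocks of
measurements: untargeted LC-MS metabolomics of the non-volatile
metabolome, GC-based profiling of aroma volatiles, and
spectrophotometric antioxidant assays. `flavormet` is an R package for
the computational side of such studies: a tested, seed-reproducible
pipeline from raw intensity tables to differential metabolites, key
odorants, antioxidant endpoints and their cross-block correlations,
together with a synthetic-data module that generates every input with
recorded ground truth so the whole chain can be validated without any
external download.

## What it computes

**Preprocessing.** Pooled-QC LOESS drift correction (QC-RLSC): per
feature, a degree-1 tricube local regression of QC intensity on
injection order; each injection is scaled by
`median(QC fit) / fit(order)`. Features with QC RSD
(`sd/mean × 100`) above 30% are filtered, intensities are
internal-standard normalized on request, left-censored values imputed
at half the feature minimum, log2-transformed and autoscaled.

**Chemometrics (from scratch).** PCA by SVD; PLS-DA by NIPALS on the
one-hot group matrix; OPLS-DA for pairwise contrasts (orthogonal-signal
filtering plus one predictive component); VIP scores with
`mean(VIP²) = 1`; stratified 7-fold cross-validated
`Q² = 1 − PRESS/TSS`; label permutation testing (default 200
permutations, add-one empirical p).

**Differential metabolites.** The two-step screening convention: per
group pair, features with **VIP > 1 and t-test p < 0.05** (t-tests on
log2 intensities, fold change as `log2(mean_B/mean_A)` on the raw
scale), BH q-values reported alongside; volcano tables; upset-style
disjoint intersection counts across comparisons with a prioritized DAM
union; superclass composition percentages.

**Enrichment.** Hypergeometric over-representation
(`P[X ≥ k]` for `k` hits of a size-`m` pathway in an `n`-feature DAM
list against an `N`-feature detected background), BH-corrected.

**Flavoromics.** Odor activity values `OAV = Peak/T`; relative odor
activity `ROAV_B = 100 · OAV_B / OAV_A` with the reference A (largest
OAV) scoring exactly 100 and key compounds at ROAV > 1; Kovats
retention indices by linear interpolation between n-alkanes; descriptor
radar grades (1–5); the bipartite compound–descriptor flavor network.

**Antioxidant endpoints.** Scavenging `100·(1 − A_sample/A_0)`; IC50 by
bracketing interpolation or a 4-parameter-logistic fit; FRAP via a
fitted Fe(II) calibration line, expressed as mmol Fe²⁺ per g dry
weight.

**Integration.** Between-block Pearson/Spearman correlations on
group-level means, and deterministic hierarchical clustering for
heatmaps.

## A worked example

```r
library(flavormet)
report <- run_pipeline(default_pipeline_config(seed = 1))
report
#> <pipeline_report>
#>   features retained: 300 of 300
#>   PLS-DA R2Y 0.626, Q2 0.190 (perm p(Q2) = 0.02488)
#>   DAM union: 98 features; key flavor compounds: 49
```

The default configuration simulates a four-harvest study (4 groups × 3
replicates + 6 pooled QC injections, 300 features of which 30 carry a
2-unit log2 shift in the last harvest). The report above says: all 300
features survived the 30% QC-RSD filter after drift correction; the
four harvests are separable (R2Y 0.626) with modest but genuinely
predictive class structure (cross-validated Q² 0.19, permutation
p ≈ 0.025, i.e. no permuted labelling matched the observed Q² more than
a handful of times in 200); 98 features are differential in at least one
pairwise comparison; and 49 (compound, group) ROAV records exceed the
key-odorant threshold. Drilling in:

```r
head(report$upset$union, 2)      # features flagged in most comparisons
#>   feature_id n_comparisons                                  comparisons consistent
#> 1      F0231             5 G1_vs_G3;G1_vs_G4;G2_vs_G3;G2_vs_G4;G3_vs_G4       TRUE
#> 2      F0239             5 G1_vs_G2;G1_vs_G4;G2_vs_G3;G2_vs_G4;G3_vs_G4       TRUE

report$assays$ic50$DPPH_G4       # strongest harvest, DPPH assay
#> <ic50_result> IC50 = 0.8198 (method: interpolation)
```

The estimated IC50 of 0.82 mg/mL for the last harvest recovers the
simulated value (0.8 mg/mL) from the noisy dose–response curve;
`subset(report$roav, is_reference)` shows every per-group ROAV
reference at exactly 100.

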