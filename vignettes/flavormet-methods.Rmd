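---
title: "Methods: harvest-time metabolomics, flavoromics and antioxidant profiling with flavormet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harvest-time metabolomics, flavoromics and antioxidant profiling with flavormet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavormet)
```

# Scope and data model

`flavormet` implements the computational chain of a harvest-time study of
an herbal tea: untargeted LC-MS metabolomics (sample groups by harvest
month, pooled QC injections), GC-based volatile profiling with odor
thresholds, and spectrophotometric antioxidant assays. The package works
on plain tables — a `feature_table` holds the sample-by-feature intensity
matrix plus group labels (QC injections carry the reserved label `"QC"`)
and injection orders; odor tables, assay curves and annotation maps are
ordinary data frames and lists with documented columns. Because studies
of this kind rarely deposit raw feature tables, every input can be
simulated with recorded ground truth, which is how the test suite and the
acceptance script exercise the pipeline end to end.

# The synthetic study generator

`generate_feature_table()` emulates the acquisition design, not the
instrument: features are "already identified", there are no spectra,
m/z values or retention-time shifts.

* **Abundances.** Per-feature baselines are drawn on the log2 scale
  (uniform over 10–20, i.e. raw intensities of about 10^3^–10^6^), and
  replicate variation is multiplicative log-normal with coefficient of
  variation `noise_cv` (default 0.1, a typical combined
  biological/technical CV for well-behaved untargeted features). The
  log-normal noise is mean-preserving (`meanlog = -sdlog^2/2`), so group
  means equal their design values in expectation.
* **Differential features.** `n_dam` features receive an additive
  `effect_log2` shift (default 2) in the *last* group, so every pairwise
  contrast against that group is a spiked comparison with known truth.
* **Drift.** Instrument drift is multiplicative and smooth: a linear
  trend plus one low-frequency sinusoid per feature, with per-feature
  amplitudes in `[0.5, 1] * drift_amplitude` and random phases. This is
  exactly the structure pooled-QC LOESS correction is designed to
  remove; drift factors are floored at 0.05 so intensities stay
  positive.
* **QC injections.** QC rows carry the pooled mean profile of all
  biological samples (an equal-volume pool), times drift and noise. They
  are placed at the first and last injection and evenly through the run,
  so the drift smoother has support over the whole injection order.
  The default of 6 QC injections for 12 samples (one QC per two to three
  biological injections) reflects common practice; the correction
  requires at least 4.

What the generator does *not* emulate — missing values from ionization
suppression, heteroscedastic "peak-shaped" noise, correlated feature
blocks from shared pathways, batch boundaries — means that passing
recovery tests demonstrate correctness of the algorithms under the
stated model, not performance guarantees on any particular real
dataset.

`generate_odor_table()` gives each volatile a positive odor threshold
(log-uniform over 0.01–10 area-consistent units), log-normal peak areas
per group, and one to four sensory descriptors from a bundled
16-descriptor dictionary (sweet, green, fruity, floral, woody, herbal,
...), recording the true odor-activity ranking.
`generate_assay_curves()` produces four-parameter-logistic scavenging
curves rising 0→100% with the 50% point at the requested IC50, plus
Gaussian noise on the percent scale, clipped to [0, 100]; emitted
absorbances are consistent with the scavenging formula so the assay
module can start from raw readings.

# Preprocessing

The default chain is **drift correction → RSD filter → (optional
internal standard) → half-minimum imputation + log2 → autoscaling**;
each stage returns a valid `feature_table`, so the order can be changed
when a study calls for it.

* **QC-LOESS drift correction** (`qc_loess_correct()`): per feature, a
  degree-1 tricube-weighted local regression (span 0.75, the usual
  QC-RLSC choice) of QC intensity on injection order estimates the
  drift curve; every injection is multiplied by
  `median(fitted QC) / fitted(order)`. Predictions beyond the outermost
  QC injections are clamped to the nearest QC order — extrapolating a
  local fit at the run edges is the classic failure mode. If the fitted
  drift is non-positive anywhere (or the smoother fails on a degenerate
  feature), the feature is left uncorrected and flagged; the anchor
  (`median`) makes the correction identity-preserving for drift-free
  features.
* **RSD filter** (`rsd_filter()`): features with QC relative standard
  deviation above 30% are removed, after drift correction — filtering
  first would discard features whose instability is pure drift.
* **Imputation** uses half the smallest positive value per feature, a
  conservative and widespread default for left-censored intensity data;
  autoscaling drops zero-variance features because they cannot be
  scaled and carry no discriminant information.

# Multivariate models

PCA, PLS-DA and OPLS-DA are implemented from scratch (SVD and NIPALS);
this is deliberate, since these models and their diagnostics are the
analytical core of the workflow.

* **PCA** is the truncated SVD of the column-centered matrix; explained
  variance is the squared singular value over the total.
* **PLS-DA** fits NIPALS components against the one-hot group matrix
  (convergence tolerance 1e-10, at most 500 iterations, logged on
  non-convergence). R2Y is the fraction of centered response variance
  explained.
* **OPLS-DA** handles exactly two groups (pairwise use): orthogonal
  components are removed from the feature matrix first
  (orthogonal-signal filtering), then one predictive component is
  fitted. With `n_orthogonal = "auto"`, components are added while the
  cross-validated Q2 improves by more than 0.01, capped at 5 — the rule
  popularized by commercial chemometrics software. For a single
  response, the OPLS model with 1+k components reproduces the
  predictions of a (1+k)-component PLS model; the test suite asserts
  this equivalence to 1e-6, along with the PCA/eigendecomposition
  equivalence to 1e-8.
* **Signs** follow one convention throughout: the largest-magnitude
  loading (or weight) of each component is positive, making all fits
  deterministic.
* **VIP** uses the standard formula over predictive components
  (`mean(VIP^2) = 1`); for OPLS-DA it is computed on the predictive
  component only (VIP~pred~), the common practice when orthogonal
  variation is explicitly modeled as non-predictive.
* **Q2** is `1 - PRESS/TSS` over stratified k-fold cross-validation
  (default k = 7). Stratification matters here: with three replicates
  per group, unstratified folds routinely lose a whole group from a
  training split. Fold assignment is seeded and round-robin within
  shuffled group blocks.
* **Permutation testing** permutes the labels (default 200 times),
  refits R2Y and Q2, and reports the add-one empirical p-value
  `(1 + #[perm >= obs]) / (n_perm + 1)`, so 200 permutations bound p at
  1/201. Calibration is verified in the tests on 100 label-independent
  datasets at a reduced 50 permutations (keeping that check under a
  minute) — the nominal 0.05 rejection rate must hold within binomial
  error.

# Differential metabolite screening

`pairwise_dam()` mirrors the two-step screening convention: per pair of
groups, a feature is differential when **VIP > 1** (from the pairwise
OPLS-DA on autoscaled log2 data) **and t-test p < 0.05** (two-sided, on
log2 intensities, pooled-variance Student by default with Welch
optional). Fold changes are reported as `log2(mean_B / mean_A)` on the
*raw* scale — tests on the log scale, ratios on the natural scale is
the common reporting convention. No multiplicity correction enters the
default call (the criterion is the conventional raw-p rule), but BH
q-values are always emitted alongside so users can screen on them.
Degenerate features (zero variance in both groups) get p = 1 when the
means agree and p = 0 otherwise.

`integrate_comparisons()` uses upset semantics: disjoint
intersection-class counts over the comparisons' DAM sets, plus a union
ranked by how many comparisons flag each feature; "consistently
altered" defaults to at least 2 comparisons (exposed as
`min_comparisons`).

A note on the recovery experiment used in the acceptance checks: with a
2-unit log2 effect and n = 10 per group, the sensitivity target is
easy, but the false-positive rate depends on the *spiked fraction*.
When only ~10% of features are spiked, VIP > 1 is implied by p < 0.05
and the expected FPR sits exactly at the 5% of the raw-p rule; at a
~30% spiked fraction — the differential fraction actually typical of
harvest-time studies — the VIP cut binds and the FPR drops an order of
magnitude. The recovery experiments therefore spike 60 of 200 features,
as their study condition.

# Enrichment

`enrich_pathways()` is a standard over-representation analysis: the
hypergeometric upper tail `P[X >= k]` for `k` hits among `n` DAMs, a
pathway of size `m`, and a background `N` of all annotated features
surviving preprocessing (the detected-universe convention), with BH
correction across pathways. The hypergeometric statistic is an
assumption — bubble-chart enrichment figures in this literature rarely
name their test — and the tests pin the tail against exact
combinatorial enumeration at N = 20 to 1e-12.

# Flavoromics

The odor activity value of a volatile is `OAV = Peak / T` (peak area
over odor threshold). The **default ROAV** is the OAV ratio scaled to
the in-scope maximum:
`ROAV_B = 100 * (Peak_B / T_B) / (Peak_A / T_A)`, reference A being the
compound with the largest OAV. This guarantees the two properties the
convention demands — the reference scores exactly 100 and every value
lies in (0, 100] with the ROAV ranking equal to the OAV ranking. A
`literal_eq3` mode computes the product form
`100 * (Peak_B * T_B) / (Peak_A * T_A)` with the smallest-threshold
compound as reference; that form circulates in print but contradicts
the "reference = 100, others below" semantics (a potent compound can
exceed 100), so it is provided for comparison, not as the default.
Whether references are chosen per sample group or once globally is
configurable (`reference_scope`, default per-group), since published
tables are usually ambiguous on this point. Key compounds are
**ROAV > 1**, strictly — a compound at exactly 1 is not key.

Kovats retention indices interpolate linearly between bracketing
n-alkanes (`RI = 100 * (n + (rt - rt_n)/(rt_{n+1} - rt_n))`), with no
extrapolation outside the alkane span. Descriptor radar grades map
per-group descriptor counts to 1–5 by equal-width binning between the
group's minimum and maximum count (ties at a single count grade 5, as
the maximum of itself), and `flavor_network()` emits the bipartite
compound-descriptor incidence structure with degrees, keeping
descriptor-less compounds as isolated nodes.

# Antioxidant endpoints

Scavenging is `100 * (1 - A_sample/A_0)`; out-of-range values (possible
with noisy or pro-oxidant readings) are flagged but never clipped, so
assay pathology stays visible. IC50 defaults to bracketing linear
interpolation on the concentration axis — robust, assumption-free, and
adequate when the 50% crossing is sampled — with a four-parameter
logistic least-squares fit (`minpack.lm`) available for smooth curves;
the noiseless 4PL recovery is exact to well under 1%. Replicates are
pooled into one curve by default. The FRAP calibration is an ordinary
least-squares line of absorbance on Fe(II) concentration; FRAP values
invert it and scale by assay volume over sample dry mass (mmol Fe^2+^
per g dry weight). The canonical calibration line used in the bundled
configuration (slope 0.9893, intercept -0.0999 over 0.15–1.5 mmol/L)
round-trips concentrations to 1e-9 in the tests.

# Cross-block correlation

`correlation_matrix()` correlates variables *between* blocks
(antioxidant endpoints, top key-compound ROAVs, top DAM abundances).
The default design correlates **group-level means** — antioxidant
endpoints exist once per group, so n equals the number of groups (4 in
the default study). With four points, |r| = 1 is attainable by ties or
monotone alignment and should be read as descriptive, not inferential;
a per-sample mode is simply a matter of passing per-sample blocks.
Pearson is the default, with Spearman emitted alongside for the
heavy-tailed ROAV block. Hierarchical clustering (`cluster_heatmap()`)
exposes Ward.D2 or average linkage over Euclidean or correlation
distances and returns orderings and merge heights for rendering.

# Pipeline, determinism and problem sizes

`run_pipeline()` chains every stage on simulated inputs and is fully
determined by its configuration: the single seed drives the generator,
fold assignment and permutations, and a rerun with the same
configuration produces byte-identical numeric outputs. A stage failure
aborts with the stage name and cause; outputs already written are
retained. The default study is 4 groups x 3 replicates + 6 QC
injections over 300 features (30 spiked), 40 volatiles, two assays at 8
concentrations per group, 200 permutations with 7-fold
cross-validation; the whole run takes a few seconds on one core. The
recovery experiments in the acceptance script use 2 x 10 samples over
200 features for DAM screening and 200 features x 8 QC injections for
drift correction — sizes chosen so each property is measured with
useful precision while the full script stays fast.

# Known limitations

* OPLS-DA is strictly two-group; multi-group contrasts are pairwise by
  design, as in the screening convention it implements.
* The enrichment test ignores pathway topology and inter-feature
  correlation; q-values inherit the independence caveats of BH.
* The synthetic generator's simplifications (no missingness, no
  correlated feature blocks) mean recovery rates here are upper bounds
  on real-data performance.
* Group-level correlations with n = 4 have essentially no degrees of
  freedom; they are reported for pattern description only.

# A compact worked example

```{r example, eval = FALSE}
cfg <- default_pipeline_config(seed = 1)
report <- run_pipeline(cfg, out_dir = "flavormet_run")
report            # headline diagnostics
head(report$upset$union)         # prioritized DAM union
head(report$enrichment)          # pathway over-representation
subset(report$roav, is_reference)  # ROAV references (all exactly 100)
report$assays$ic50$DPPH_G4$ic50  # strongest-harvest DPPH IC50 (mg/mL)
```
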