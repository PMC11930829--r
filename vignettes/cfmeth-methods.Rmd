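---
title: "Methods: cfDNA methylation marker panels for noninvasive cancer detection"
author: "cfmeth authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA methylation marker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmeth)
```

# Scope and data model

`cfmeth` implements the computational core of a cfDNA-methylation liquid
biopsy pipeline built on semi-targeted assays (MCTA-Seq-style) that
enrich hypermethylated CpG islands anchored at CGCGCGG motifs. The
quantitative unit throughout is MEPM — methylated alleles per million
mapped molecules: for a site with $c$ fully methylated molecules in a
sample with $T$ total molecules, $\mathrm{MEPM} = c/T \times 10^6$
(`compute_mepm()`). A `meth_matrix` bundles a samples-by-sites MEPM grid
with a sample sheet (specimen, condition, stage, tissue pairing, total
molecular count) and a BED-like CpG-site catalog carrying each site's
distance to the nearest CGCGCGG motif.

Two conventions matter downstream:

* **Zeros are measurements.** The absence of methylated molecules in
  this assay is a true zero signal, so matrices admit no missing values.
* **Positivity is strict.** A site is *positive* in a sample when its
  MEPM value strictly exceeds the per-marker threshold (default 0: any
  fully methylated molecule observed).

Quality control excludes samples with a total molecular count strictly
below 10,000 (`qc_filter_samples()`; the boundary itself is retained).
Cohorts are split 6:4 into discovery and validation sets, stratified by
condition with per-stratum rounding (`split_cohort()`): 50 cases and 52
controls yield 30 + 31 versus 20 + 21.

# Differential methylation

Per-site group comparisons use the two-tailed Mann–Whitney U test
(`mww_test()`). For pooled sizes up to 12 the p-value is computed by
exact enumeration of all $\binom{n_a+n_b}{n_a}$ assignments with
mid-rank tie handling — zero-inflated MEPM data are tie-heavy, and the
common exact algorithms do not admit ties. Above that size a
tie-corrected normal approximation with continuity correction is used;
the cutoff at 12 keeps the exact path under a thousand enumerated
assignments. False discovery rates are Benjamini–Hochberg step-up
q-values (`bh_fdr()`, one family per comparison). Fold changes are
pseudocounted, $(\bar a + 0.5)/(\bar b + 0.5)$ MEPM, because zero group
means are routine in plasma; 0.5 MEPM is well below any biologically
meaningful signal and bounds the fold change of an all-zero contrast at
values that cannot pass the screening threshold alone.
`differential_sites()` combines the three: keep sites with
$q < 0.05$ and fold change above 2 (hyper) or below 1/2 (hypo).

# Marker selection

Tumor-marker selection (`select_cancer_markers()`) is the conjunction of
four criteria, all boundaries strict as the assay's design dictates:

1. differential hypermethylation in tumor versus adjacent tissue at
   $p < 0.01$ (unpaired Mann–Whitney; pairing is kept in metadata but
   the test is unpaired — rank tests on 30+ pairs lose little power and
   the unpaired form tolerates unmatched samples);
2. site closer than 60 bp to the nearest CGCGCGG motif (sites far from
   the anchoring motif amplify poorly and quantify unreliably);
3. mean tumor-tissue level of at least 10 MEPM (detectability floor);
4. background positivity frequency in normal plasma below 5%
   (specificity floor), with positivity meaning any nonzero signal.

Cross-cancer discrimination (`select_pairwise_discriminative_markers()`)
replaces the motif criterion with a tumor-versus-tumor fold change above
2, lowers the MEPM floor to 5, and keeps the normal-plasma background
criterion; it returns the two directional panels, which are disjoint by
construction.

# The positivity-counting classifier

The diagnostic statistic for a sample is the number of panel markers
with positive methylation (`positive_count()`); `total_methylation()`
sums the positive values. A sample is called positive when its count
strictly exceeds the panel's cutoff.

**Panel sizing.** `monte_carlo_panel_size()` repeats a stratified 50/50
train/test split (default 1000 times), and for each candidate panel size
fits a univariate logistic model mapping the training positive counts to
case probabilities, scoring the held-out half with the Brier score
(mean squared error of the predicted probability). The selected size
minimizes the mean Brier score; ties go to the smallest panel. The
candidate ordering is part of the method: candidates passing the tissue
criteria are ranked by ascending background positivity frequency
measured on an *independent* preselection normal set. Two facts force
both choices. Ranking on the study's own controls selects markers that
are accidentally silent in those exact samples, and because Monte Carlo
cross-validation resplits the same cohort, the resulting Brier curve is
optimistically biased at small panel sizes. And ranking by a quantity
unrelated to plasma background (for example the tissue p-value) gives a
curve with no interior minimum: every marker beyond the true panel is
exchangeable noise, so panel growth is never penalized. With
background-frequency ranking, growth first adds clean markers (Brier
falls as weakly shedding patients accumulate counts) and then
increasingly leaky ones (control counts inflate; Brier rises), giving a
genuine optimum near the number of clean markers.

**Cutoff calibration.** `calibrate_count_cutoff()` sets the count cutoff
on normal plasma, by default policy `max` — the largest count observed
among the calibration normals — which fixes specificity at 100% on the
calibration set; a quantile policy is available. For the multi-panel
typing application the operating cutoff additionally respects the
deployed floor of more than 5 counts per panel, the operating point the
assay is published to run at; calibrated maxima on a 96-sample normal
set land at that floor for the larger panels and below it for the
smallest.

**ROC.** `roc_auc()` uses the rank-statistic identity
$\mathrm{AUC} = U/(n_1 n_0)$ with tied pairs counted one half; the
pairwise $O(n^2)$ definition serves as the test oracle.

# The methylation score

`lasso_select_features()` fits an L1-penalized logistic regression of
case status on candidate-marker MEPM values (glmnet), choosing the
penalty by stratified 10-fold cross-validation with the one-standard-
error rule; values are standardized internally for the penalized fit and
coefficients are reported on the raw MEPM scale. The surviving markers
enter an unpenalized logistic refit (`fit_score_model()`), and the score
of a sample is the linear predictor

$$\mathrm{score} = \beta_0 + \sum_i \mathrm{Coef}_i \, A_i,$$

with $A_i$ the sample's MEPM value at marker $i$. The intercept is
included deliberately: the score is thresholded at zero
(`waterfall_classify()`, score > 0 means patient; zero classifies as
control, favoring specificity), and without the intercept the zero
threshold would not coincide with the logistic decision boundary. When
the refit separates the training classes perfectly — common when the
selected markers are strong — the fit falls back to a lightly
ridge-penalized logistic model ($\lambda = 10^{-3}$, flagged in
`training_meta`), which preserves the decision boundary while keeping
coefficients finite.

`stage_flag()` encodes the late-stage rule on the full PAC panel: only
samples with more than 8 positive markers or a total positive
methylation above 150 MEPM are compatible with stage III/IV disease;
below both bounds the early and late ranges overlap and the flag is
indeterminate.

# Consensus-clustering subtypes

`consensus_matrix()` estimates co-clustering probabilities by repeated
80% subsampling with Ward-linkage hierarchical clustering on Euclidean
distances of log1p-transformed MEPM (log1p because MEPM magnitudes are
heavy-tailed and zero-inflated; Ward because it is insensitive to the
chaining artifacts single/average linkage show on such data). Feature
space defaults to the selected marker panel. `consensus_cluster()`
computes, per k, the empirical CDF of the off-diagonal consensus
entries, the area under it, and the relative delta-area
$\Delta(k) = (A(k) - A(k-1))/A(k-1)$ (with $\Delta(2) = A(2)$); the
chosen k is the largest with $\Delta(k)$ at or above the threshold, with
a floor of 2 for structureless data.

The delta-area threshold deserves comment because it is often quoted
as ~0.1. The area under the consensus CDF equals one minus the mean
consensus, so partitioning one true cluster of $m$ samples (out of $n$)
at $k+1$ — however unstable the partitions are — raises the area by
roughly $0.5\,m^2/n^2$, a *frozen-geometry* floor that for a two-cluster
cohort sits at a relative gain of 0.2–0.3. A 0.1 threshold therefore
over-segments any two-cluster data set. The default here is 0.4,
calibrated on planted geometries: genuine additional clusters gain
upwards of 0.45 relative area, spurious subdivisions 0.35 or less. The
threshold is a parameter (`delta_threshold`) for users who prefer the
conventional value.

`assign_cimp()` labels, in a two-cluster solution, the cluster with the
larger median per-sample total panel methylation as the CpG-island
methylator phenotype (CIMP) group; exact median ties are an error rather
than an arbitrary pick.

# Multi-panel tumor typing

`evaluate_panels()` scores a sample against the four per-cancer panels;
`typing_decision()` applies the clinical rule: no positive panel means
non-cancer; one positive panel names the cancer; several positive panels
go to the highest fraction of positive markers, compared as exact
rationals by integer cross-multiplication so that 30/120 versus 20/80 is
a true tie (indeterminate) and no floating-point artifact can break it.
The decision is invariant to panel order.

# The synthetic cohort generator

Real MCTA-Seq cohorts of this design are access-restricted, so the
package ships a ground-truthed generator (`sim_config()`,
`simulate_site_catalog()`, `simulate_tissue_cohort()`,
`simulate_plasma_cohort()`, `simulate_multicancer_plasma()`) whose
defaults are fixed once to emulate the study conditions the pipeline is
designed for. The noise model is Bernoulli occupancy times log-normal
magnitude at every site; tumor signal is an independent additional
channel at planted markers.

The defaults encode, in order of importance:

* **Panels.** 120 PAC, 38 HCC, 80 CRC and 153 GC planted markers among
  3000 sites — the deployed panel sizes. Panels are disjoint; within
  each, 25% of markers are pan-cancer responsive (they fire in tumors of
  any type), the remainder type-private. Planted markers always lie
  closer than 60 bp to the motif; half of the decoy sites lie at 60 bp
  or farther.
* **Normal plasma background.** Mean per-marker positivity 1% with two
  kinds of heterogeneity: a per-sample scale factor (log-sd 0.5,
  sample quality/input variation) that spreads control positive counts
  over the 0–10 range with median ~1–2 on a 120-marker panel, and a
  per-marker level spread (log-sd 0.8, capped at 4.5% so planted markers
  stay below the 5% selection bound).
* **A sensitivity–background trade-off.** A marker's case
  responsiveness scales as $(b_j/\bar b)^{0.5}$ (capped at 2.5,
  normalized to mean 1 over the panel): near-silent markers are also
  weakly shed by tumors, leakier ones fire in more patients. Together
  with 50% extra "leaky" tumor-responsive sites per panel (background
  15–40%, the site class the background criterion exists to remove),
  this is what gives panel growth diminishing and then negative returns,
  i.e. an interior Brier optimum.
* **Patient heterogeneity.** Each case draws a log-normal tumor-burden
  factor (log-sd 0.8) and a stage multiplier (I and II at 1, III at 1.5,
  IV at 3, so early-stage ranges overlap); per-marker positivity is
  0.25 × burden × stage multiplier × marker responsiveness. This spreads
  case positive counts over roughly 5–110 of 120 with a median near
  35–50 and puts a few percent of cases near the count cutoff.
* **Tissue.** All tissue sites carry a 0.5-occupancy background of mean
  5 MEPM (per-site mean ≈ 2.5 MEPM, panel totals ≈ 300); tumor samples
  replace that at their responsive markers with 0.9-occupancy signal
  whose mean is 8-fold the adjacent level (≈ 20 MEPM per marker, panel
  totals ≈ 2400). A configurable fraction of tumors (default 2/33) is
  CIMP: concerted hypermethylation, raising both the signal magnitude
  (×3) and the occupancy (zero rate shrunk ×3). Modeling CIMP as a
  magnitude boost alone makes CIMP tumors internally *more* dispersed
  (zeros at boosted markers dominate distances) and destroys the planted
  two-cluster geometry.

Everything is deterministic given the config seed; the cohort simulators
derive fixed offsets from it so that the catalog, tissue, plasma and
multicancer draws are distinct but jointly reproducible.

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: sequencing depth and molecule-count
variation coupled to MEPM precision (counts are drawn directly on the
MEPM scale), correlated methylation of neighboring CpG sites within an
island, batch and center effects, fragment-length signal,
age/sex-related background drift, and any real marker identity. Results
on synthetic cohorts validate the computational pipeline, not the
biology of any particular marker set.

# Problem sizes and numerical choices

The test suite runs the full pipeline at the study scale it targets —
3000 sites, 33 tissue pairs, 30 + 31 discovery plasma samples, a
96-sample preselection normal set, 25 cases per cancer type in the
typing cohort — with Monte Carlo panel sizing at 200 splits over sizes
20–170, consensus clustering at 150–250 resamples, and 10–20 seed
replicates for recovery properties; these sizes keep the default suite
in the low minutes on one core while leaving every statistical check
comfortably powered. Other numerical choices collected in one place:
exact Mann–Whitney enumeration up to pooled size 12; fold-change
pseudocount 0.5 MEPM; BH applied per comparison family; positivity and
cutoff comparisons strict; score of exactly zero classifies as control;
typing fractions compared as exact rationals; consensus delta-area
threshold 0.4; ridge fallback $\lambda = 10^{-3}$ on separation.

# Known limitations

* The typing operating floor (> 5 counts) cannot deliver literal 100%
  control specificity under realistic background heterogeneity: a
  normal sample at the upper end of the background distribution can
  exceed it on a large panel. The same tension is visible in the
  published operating characteristics this design follows (control
  counts reaching 10 on a 120-marker panel alongside "approximately
  100%" specificity).
* The delta-area rule, under any threshold, identifies cluster numbers
  reliably only when clusters are of comparable size; a two-sample
  subgroup among 33 tumors is found by the k = 2 *assignment* (and
  labelled by `assign_cimp()`), but no CDF criterion will select k = 2
  over k = 3 for such imbalance on its own.
* The unpaired tissue test ignores the pairing structure; a paired
  (signed-rank) variant would gain power at small n but is not what
  this pipeline deploys.
* LASSO feature selection at 10-fold cross-validation is variable at
  n ≈ 60; the selected marker count is stable only to within a factor
  of ~2 across fold assignments, which is why the refit and the zero
  threshold, not the selection count, define the classifier.
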