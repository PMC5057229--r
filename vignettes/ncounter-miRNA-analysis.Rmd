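---
title: "Differential miRNA expression from nCounter counts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential miRNA expression from nCounter counts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncounterDE)
```

## The analysis problem

NanoString nCounter miRNA assays count barcoded probe molecules directly, one
lane per sample, without amplification. Each lane carries three kinds of
probes: *positive controls* (spike-ins at known concentrations, used to absorb
lane-to-lane efficiency differences), *negative controls* (probes with no
target, measuring non-specific background), and the *endogenous* miRNA probes
of interest. `ncounterDE` implements a complete two-group
differential-expression analysis for such data, motivated by tumor-versus-
normal miRNA profiling designs that are often strongly unbalanced (the default
simulated design is 72 tumor lanes against 3 osteoblast control lanes).

The pipeline, in the fixed order applied by `ncounter_de()`:

1. **Boxplot QC** (`qc_boxplot_stats`). Per-lane medians and quartiles of
   log2(count + 1). A lane is flagged when its log-median is more than
   `f = 3` cohort IQRs from the cohort median of log-medians. Flags are
   advisory: no lane is ever removed automatically, mirroring the practice of
   inspecting boxplots and proceeding with all lanes when nothing gross shows.
2. **Positive-control scaling** (`positive_control_normalize`). Lane factor =
   (mean over lanes of the per-lane geometric mean of positive-control
   counts) / (this lane's geometric mean); all probes in the lane are
   multiplied by the factor. After scaling, all lanes share one
   positive-control geometric mean. The geometric mean is the standard
   summary for a 4-fold spike-in ladder because it is the log-scale average.
3. **Background thresholding** (`compute_background`). Per lane, threshold =
   mean + k·SD of that lane's negative-control values, with k = 2 by default.
   The SD is the sample (n−1) SD: negative-control probe counts are few
   (6–8), so the unbiased estimator matters. Thresholds are computed on the
   positive-control-scaled matrix so probe and threshold sit on one scale.
4. **Prevalence filtering** (`filter_low_expressed`). An endogenous miRNA is
   dropped iff *more than* 90% of lanes sit below their lane's threshold —
   strictly more: a probe below background in exactly 9 of 10 lanes is kept.
   Control probes leave the analysis set here.
5. **Quantile normalization** (`quantile_normalize`). Classic rank-mean
   normalization: the reference at rank r is the cross-lane mean of r-th
   order statistics; ties receive the mean of the reference values over the
   tied rank span, so column multisets are exactly equal afterwards.
6. **Per-miRNA linear-model testing** (`fit_linear_de`). Ordinary least
   squares of expression on a 0/1 group indicator, on the log2(value + 1)
   scale by default; the slope's two-sided t-test with n − 2 degrees of
   freedom is, for a two-group contrast, identical to the pooled-variance
   two-sample t-test and to one-way ANOVA (F = t²) — an identity the test
   suite asserts to 1e−10 against `t.test`, `aov` and `lm`.
7. **Expected-false-positive cutoff** (`expected_fp_cutoff`). Significance at
   α = 1/m, with m the number of miRNAs tested: under the global null about
   one of the m tests is expected to pass, i.e. the cutoff "spends" one
   expected false positive. For m = 519 this is 1/519 ≈ 0.0019. This is
   deliberately not an FDR procedure; no Benjamini–Hochberg machinery is
   layered on top.
8. **Signed fold changes and the signature** (`fold_change`,
   `build_signature`). The ratio r = 2^(Δ mean log2) is reported as r when
   r ≥ 1 and −1/r otherwise, so a halving is −2 rather than 0.5 and
   |fold change| ≥ 1 always. Significant miRNAs are partitioned into up and
   down lists sorted by |fold change|.
9. **Supervised clustering** (`supervised_cluster`). Only the signature
   miRNAs (rows) are clustered — average linkage on 1 − Pearson correlation
   of the per-row z-scored profiles; the samples stay in their known group
   order. "Supervised" refers to exactly this: class labels fix the columns,
   the dendrogram organizes only the features.

The ΔΔCt layer (`ddct`, `anova_compare`) covers qPCR validation: replicate
Ct values are averaged per sample and assay, ΔCt = target − reference,
ΔΔCt = ΔCt − mean ΔCt of the calibrator group, RQ = 2^−ΔΔCt. Group
comparison is one-way ANOVA on ΔΔCt — not on RQ, which is log-normal by
construction; ΔΔCt is the natural (log2) scale for a linear model.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 2 | SD multiplier in the background threshold (counts scale) |
| `frac` | 0.90 | prevalence cutoff; strictly "more than" |
| `background` | per_sample | negative-control pooling (`pooled` available) |
| `scale` | log2p1 | analysis scale for testing (`linear` available) |
| `alpha` | 1/m | significance cutoff |
| `qc_f` | 3 | QC flagging multiplier (cohort IQRs) |
| `metric`, `linkage` | pearson, average | clustering options (euclidean/complete available) |

Design choices behind the defaults, where the convention was genuinely open:

* **Per-sample background** rather than pooled: lane-to-lane background
  varies, and the filter compares each lane's value to its own lane's
  threshold. The pooled variant is one switch away for sensitivity analysis.
* **log2(value + 1) analysis scale**: fold changes are ratios, implying a
  multiplicative model; +1 guards zeros after filtering. The fold change is
  computed from the same log-scale means (a geometric-style ratio),
  consistent with the regression scale.
* **No covariates**: the two-group indicator is the entire design matrix;
  batch labels are carried for QC only.
* **"Flat" direction** is reserved for exactly equal group means; ranking
  ties break lexicographically by probe id, making output deterministic.

## The synthetic-data generator

No public raw dataset accompanies the motivating design, so the package
ships a generator (`simulate_ncounter`) whose defaults *are* the emulated
study conditions: 600 endogenous probes, 6 positive and 8 negative controls,
72 + 3 lanes, log-normal lane scale factors (sdlog 0.2), per-probe baselines
2^N(6, 2) on the count scale, shared negative-binomial dispersion (size 10),
background counts round-N(25, 6) truncated at zero, a planted differential
set of 70/600 probes with 26/70 up-regulated and |log2 fold changes| drawn
from [1, 6.5] (2-fold to ≈93-fold, the span seen in signed fold-change
tables for this kind of tumor-versus-osteoblast signature), and 12% of
probes "absent" (background only), calibrated so roughly 519 of 600 probes
survive the prevalence filter.

Three structural choices deserve explanation:

* **Additive background.** Endogenous counts are a negative-binomial signal
  *plus* a background draw from the same model as the negative controls.
  The total mean is still lane_scale·baseline·2^(indicator·lfc) +
  background_mean, but a probe with no signal is now distributed exactly
  like a negative control — which is the premise that makes a mean + 2·SD
  negative-control threshold meaningful at all. Folding the background into
  a single NB mean would give absent probes far heavier tails than the
  negatives and quietly neuter the filter.
* **Positive-control ladder.** A fixed 4-fold geometric ladder topping at
  32768 expected counts, Poisson noise only. The top is chosen so the lowest
  rung (32) cannot plausibly produce a zero count, which would violate the
  scaling stage's own precondition.
* **Down-regulated probes get a baseline floor** of 3·background·2^|lfc|.
  In a 72-vs-3 design the repressed group holds 96% of the lanes; a
  down-regulated probe whose repressed-group mean sits below background is
  removed by the prevalence filter *by construction* and could never appear
  in a detected signature. Planted down probes therefore emulate what a
  detected down-regulated miRNA must be: expressed above background in both
  groups.

What the generator does **not** model: probe cross-hybridization, ligation
bias, cartridge position effects, batch structure, correlated miRNA modules,
or heavy-tailed per-probe dispersion. Passing tests on simulated data
therefore demonstrate the pipeline's arithmetic and statistical behavior
under a clean generative model — not robustness to every artifact of real
cartridges.

## Calibration findings the tests expose

Two properties of the *method itself* — not of the implementation — show up
quantitatively in the acceptance suite and are worth knowing about:

* **Mild null inflation with 3 control lanes.** Under the global null, the
  mean number of significant calls at α = 1/519 is ≈1.2 per dataset rather
  than 1.0. The pooled t-test is exact for Gaussian data (simulating
  Gaussian matrices gives ≈0.95), but log2 of overdispersed counts is
  left-skewed, and with only 3 lanes in one group the group mean inherits
  that skew, inflating the far tail. This is intrinsic to running a t-test
  at a 0.002 cutoff with n = 3; it is documented here rather than patched,
  because reshaping the generator's noise to hide it would only hide it.
* **Quantile normalization redistributes strong asymmetric signal.** With a
  planted signature of 26 up / 44 down at |log2FC| ≥ 3, the two groups'
  count distributions genuinely differ; forcing identical column
  distributions then shifts null probes upward in the tumor group, producing
  ≈12 spurious up-calls per dataset (skipping the normalization recovers the
  planted 26/44 exactly, with zero false positives). Sensitivity stays at
  1.0 and the false-discovery proportion ≈0.13–0.16, inside its bound, but
  the recovered up-count overshoots. This is the textbook failure mode of
  quantile normalization when the "most features unchanged" assumption is
  badly violated — worth remembering when a large fraction of a small panel
  is truly differential.

## Numerical and degenerate-input rules

* Zero positive-control counts abort the scaling stage (geometric mean
  undefined) with the offending lane named.
* Background estimation requires ≥ 2 negative probes (sample SD needs n ≥ 2).
* A miRNA with zero residual variance gets p = 0 when group means differ and
  p = 1 when equal, with a warning, rather than an NaN.
* Quantile-normalization ties take the mean of the reference over the tied
  span; the rule is pinned by a brute-force test that enumerates every rank
  assignment consistent with sorting.
* Correlation with a constant clustering row is undefined; its distance is
  defined as 1 and the row displays as all-zero z-scores.
* Undetermined qPCR wells are excluded from replicate means with a counted
  message; replicate SD > 0.5 cycles warns.
* Contrast groups need ≥ 2 samples each; the n = 3 control group of the
  default design is handled by the same code path as any other size (tests
  cover n = 2 and n = 3 explicitly).

## Problem sizes used in the shipped checks

The test suite simulates 519–600-probe, 75-lane datasets; the null-calibration
census uses 200 simulated datasets and the recovery check 20; the acceptance
script uses 50 and 10 respectively. These sizes give Monte-Carlo standard
errors comfortably below the decision thresholds they feed.

## Worked example

```{r example}
sim <- simulate_ncounter(sim_config(seed = 1))
fit <- ncounter_de(sim$counts, sim$metadata, contrast = c("OS", "Ob"))
fit
head(as.data.frame(fit$table), 5)[, c("probe_id", "fold_change", "p_value", "direction")]
```

```{r qpcr}
val <- simulate_qpcr(6, c(Ob = 1, OS = 8), ct_noise_sd = 0.2, seed = 2)
rel <- ddct(val$ct, "miR-9", "U6", calibrator_group = "Ob")
rel
anova_compare(rel)
```

## Known limitations

* The expected-false-positive cutoff controls E[false positives] = 1 under
  the global null; it is neither FWER nor FDR control and should be read as
  the screening rule it is.
* With 3 control lanes the per-test p-values are only approximate in the
  extreme tail (see the calibration note above).
* Quantile normalization assumes most features are unchanged; for panels
  where a large fraction of probes move in one direction, consider the
  positive-control-scaled matrix (`scale` stages are exposed individually)
  and interpret the signature accordingly.
* The RCC reader ingests only the Code_Summary section of lane files; vendor
  archive bundles and normalized exports are out of scope.
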