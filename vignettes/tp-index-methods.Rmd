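---
title: "Trend patterns and the tumor progressive index: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trend patterns and the tumor progressive index: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpindex)
```

## The problem

Lung adenocarcinoma (LUAD) develops through two pre-invasive stages,
adenocarcinoma in situ (AIS) and minimally invasive adenocarcinoma (MIA),
whose surgical prognosis is excellent, before becoming invasive disease with
sharply worse outcomes. Bulk expression cohorts sampled along this
progression — adjacent normal lung, AIS, MIA, LUAD — let one ask which genes
change at which step, and whether the balance between tumor-intrinsic growth
programs and the immune microenvironment predicts outcome. `tpindex`
implements that analysis as a tested pipeline over plain tabular inputs: a
genes-by-samples TPM matrix, a clinical table with ordered stage labels, and
a minimal mutation table.

## Adjacent-stage trend patterns

For each gene, the three adjacent transitions (normal→AIS, AIS→MIA,
MIA→LUAD) each receive a direction call. A transition is called **up** when
its two-sided test on `log2(TPM + 1)` gives `p < alpha` *and* the fold change
(ratio of arithmetic mean TPM, later over earlier stage) is at least
`fc_min`; **down** symmetrically with `FC <= 1/fc_min`; otherwise **none**.
The defaults, `alpha = 1e-4` and `fc_min = 2`, are the conventional raw
screening gates for this design; no multiplicity correction is applied,
because the gate is a screen rather than an inference, and the raw threshold
is part of the method's definition.

The triple of calls is looked up in a fixed table of twelve templates —
six up-trend patterns (e.g. pattern 1 = up/up/up, pattern 3 = up only at
normal→AIS) and their six mirror images (pattern 7 = down/down/down, …,
pattern 12 = down only at MIA→LUAD). Triples outside the templates, including
all-`none` and any mixed up/down triple, are left `"unclassified"` rather
than forced into a nearest pattern; the labels therefore partition the gene
set, and negating every planted effect maps pattern *k* to *k* + 6.

### Choice of test statistic

The natural model here — stage as a factor with patient as a random effect —
is not identifiable for every transition: normal and tumor samples are
paired within patients, but AIS, MIA and LUAD samples come from different
patients, so the AIS-vs-MIA contrast has no within-patient information. The
package therefore screens each transition with a plain two-sample test on
`log2(TPM + 1)` and exposes two variants:

* `method = "welch"` (default): Welch's unequal-variance t-test, robust to
  heteroscedasticity between stages.
* `method = "anova"`: the pooled-variance test. For two groups the one-way
  ANOVA F statistic is exactly the square of this pooled t, so this is the
  two-group reduction of a stage-factor ANOVA.

One behaviour worth knowing about: this screen operates at a very deep tail
(`alpha = 1e-4`), and the Welch–Satterthwaite degrees-of-freedom
approximation degrades out there when group sizes are as unbalanced as the
default cohort's 150 normals versus 16 AIS. On exactly normal
homoscedastic data the Welch variant rejects at roughly twice the nominal
rate at that threshold (still a few parts in ten thousand), while the pooled
variant is exact. The package's calibration tests assert the strict
3-binomial-SD band on the pooled variant and a factor-of-two bound on the
Welch variant. For planted effects of the default size the distinction is
immaterial — both variants recover the planted patterns — but users
screening at extreme thresholds with very unbalanced groups and no variance
heterogeneity may prefer `method = "anova"`.

### Numerical conventions

* Fold change is computed on arithmetic means of TPM (the screening-pipeline
  convention), with a symmetric pseudocount `fc_eps = 1e-9` added to both
  means so an all-zero stage cannot divide by zero.
* Degenerate groups: if both stages are constant and equal the p-value is 1;
  constant and unequal, 0. These conventions only matter for pathological
  fixtures; real TPM data never hits them.
* The fold-change gate is inclusive (`FC >= fc_min`); the p-value gate is
  strict (`p < alpha`).

## The tumor progressive index

Genes are first filtered on mean TPM across *all* samples, tumor and normal
alike, with an inclusive threshold of 1.0 (a gene averaging exactly 1.0 TPM
is kept). The tumor signature is the filtered pattern-1 genes — those rising
at every step. The immune signature is the filtered down-trend genes that
also appear in an a-priori immune-related gene list; the package exposes both
the pattern-7-plus-8 source (default) and a pattern-8-only mode, because the
two are both defensible readings of the method and differ only in which
monotone-decrease genes are eligible. The published 4-gene tumor /
8-gene immune signature is shipped as a fixture (`published_signatures()`)
and bypasses selection entirely, which is the recommended route for scoring
external cohorts.

Per sample,

* tumor index = mean of `log2(TPM + pseudocount)` over the tumor signature,
* immune index = the analogous mean over the immune signature,
* **TP index = tumor index − immune index**, exactly, per sample.

The log2 pseudocount defaults to 1 because signature genes can be zero in
individual samples; `pseudocount = 0` is supported (and errors on any zero
TPM) for exact algebra: with it, doubling every tumor-signature TPM in a
sample raises the TP index by exactly 1, and doubling the immune signature
lowers it by exactly 1. A negative TP index reads as immune control
outpacing tumor growth; positive, the reverse.

Stage-wise comparison reports per-stage quartiles of the TP index and a
two-sided Wilcoxon rank-sum test between each adjacent stage pair. The
rank-sum (rather than signed-rank) test is used because adjacent tumor
stages are independent groups, not paired measurements; p-values use the
normal approximation so ties are handled uniformly.

## Survival stratification

Patients are split at the cohort median TP index: strictly above the median
is `"high"`, at or below is `"low"` (ties at the median deterministically go
low). Per group the package reports the Kaplan–Meier product-limit curve;
between groups, the log-rank test and a Cox proportional-hazards hazard
ratio for high versus low with a Wald 95% CI. Ties in the Cox partial
likelihood use the Breslow approximation — the simplest choice, and with
continuous simulated event times ties are measure-zero anyway. When one
group has no events the partial likelihood is monotone and has no interior
maximum; the fit is flagged `estimable = FALSE` instead of reporting a
runaway hazard ratio, which is exactly the situation a degenerate published
estimate like an HR of 4.8 × 10⁸ with CI 0–Inf reflects.

These steps are computed with the `survival` package (`survfit`, `survdiff`,
`coxph`); the test suite checks them against independently hand-coded
oracles — a literal product-limit loop, a hypergeometric
observed-minus-expected sum, and a 1-D grid search of the Breslow partial
likelihood at 1e-4 resolution.

## Cohort descriptive statistics

Cross-tabulations of clinical variables use input-order category ordering;
cell percentages are rounded **half-up** to one decimal, matching the
printed style of clinical characteristics tables (e.g. 66/69 → 95.7%,
6/64 → 9.4%, where banker's rounding would give 9.4 ≠ 9.38 → 9.4 but
0.05 → 0.0). Categorical comparisons use the uncorrected Pearson chi-square
(all margins must be positive) or Fisher's exact test for 2×2 tables.

Tumor mutation burden is the count of qualifying records — nonsynonymous
point variants plus indel classes, via a configurable class set, since MAF
dialects disagree on class strings — divided by a 30 Mb exome footprint.
Tumor-suppressor mutation frequency per group counts samples with at least
one mutation in a configurable TSG list (default: TP53, RB1, STK11, NF1,
KEAP1, PTEN, CDKN2A, SMAD4), consistent with per-sample x/n percentages.

## The synthetic-cohort generator

Every stage of the pipeline is exercised on simulated cohorts from
`simulate_cohort()`, whose defaults are the study conditions the analysis
assumes:

| Parameter | Default | Meaning |
|---|---|---|
| `n_per_stage` | 150 / 16 / 52 / 82 | samples per normal / AIS / MIA / LUAD |
| `n_genes_per_pattern` | 25 | planted genes per template |
| `n_null_genes` | 1000 | unperturbed genes |
| `base_log2_tpm` | 5 | baseline mean log2 TPM (≈ 32 TPM) |
| `step_log2fc` | 2 | log2 step per called transition (FC 4) |
| `noise_sd` | 0.5 | within-group SD on the log2 scale |
| `mutation_rate_by_stage` | 0.001 / 0.011 / 0.007 / 0.06 | per-gene TSG mutation probability |
| `survival_baseline_hazard` | 0.01 / month | exponential baseline |
| `survival_log_hr_per_index_unit` | 0.5 | log-HR per centred index unit |
| `censor_time` | 60 months | administrative censoring |

Noise is Gaussian on log2 TPM (log-normal TPM), the standard bulk-expression
approximation; values are exponentiated so all TPM are positive. The
per-transition step of 2 log2 units clears the `|FC| ≥ 2` gate with margin —
deliberately, so pattern-recovery tests measure the machinery rather than
sit on the gate boundary. Every tumor sample belongs to a distinct patient
and every patient also contributes a paired normal sample. Radiology class
is sampled conditional on stage with AIS/MIA mostly pure ground-glass and
LUAD mostly solid (proportions 66/31/1 and 3/32/64), purely so
radiology-by-pathology cross-tabs are non-degenerate. The TSG rates were
chosen so that, with the 8-gene default list, the per-sample probability of
carrying ≥ 1 TSG mutation lands near the reported stage profile (≈ 8%, 5%,
38%). Survival times are exponential with hazard
`baseline × exp(log_hr × index)` where the index is the realised TP-style
contrast of each tumor sample (centred), censored administratively — the
simplest generator whose log hazard ratio is analytically known, which is
what the recovery and CI-coverage tests need.

What the generator does **not** emulate: gene–gene correlation, library-size
or composition artefacts in TPM, heteroscedasticity across stages,
mean–variance trends, isoform structure, copy number, or informative
censoring. Passing tests therefore demonstrate that the machinery is correct
under the stated model, not that the biological findings of any particular
cohort would replicate; the headline published gene counts and hazard ratios
depend on a controlled-access cohort and are not reproducible from
simulation.

## Problem sizes in the shipped tests

The default simulated cohort used by the recovery checks is 1300 genes
(300 planted, 1000 null) by 300 samples; the type-I calibration uses 10⁵
null genes (3 × 10⁵ transition tests); hazard-ratio recovery uses 500
patients and CI coverage 200 replicates of 200 patients. These sizes give
the property checks comfortable binomial resolution while keeping a full
test run in well under a minute of compute per file.

## Known limitations

* Gene symbols are matched as case-sensitive exact strings; no alias
  resolution.
* The shipped immune-related list is a compact default sufficient for the
  simulator and fixtures; real analyses should supply their own list
  (`read_gene_list()`).
* Only two-group, single-covariate survival comparisons are provided — no
  multivariable Cox, time-dependent covariates, or competing risks.
* The de-novo signature route requires non-empty pattern-1 and
  immune-listed down-pattern gene sets and errors with diagnostic counts
  otherwise; on cohorts without a clean monotone axis the published
  signature is the sensible fallback.
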