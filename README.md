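# tpindex

Trend-pattern discovery and the tumor progressive (TP) index for staged
lung-adenocarcinoma expression cohorts.

Lung adenocarcinoma (LUAD) progresses from adjacent normal lung through the
pre-invasive stages adenocarcinoma in situ (AIS) and minimally invasive
adenocarcinoma (MIA) to invasive disease. `tpindex` takes a genes × samples
TPM matrix and a clinical table with these ordered stage labels and:

1. **Classifies genes into twelve trend patterns.** Each adjacent transition
   (normal→AIS, AIS→MIA, MIA→LUAD) gets an up/none/down call from a
   two-sample test on log2(TPM + 1) (`p < 1e-4`) gated by fold change
   (|FC| ≥ 2 on mean TPM); the triple of calls is matched against the twelve
   monotone-and-partial trend templates (pattern 1 = up at every step, …,
   pattern 7 = down at every step, …), everything else `"unclassified"`.
2. **Builds the TP index.** After filtering genes with mean TPM < 1 across
   all samples, the tumor signature comes from pattern 1 and the immune
   signature from the down-trend patterns intersected with an a-priori
   immune gene list (the published 4-gene tumor / 8-gene immune signature is
   shipped as a fixture). Per sample,

   `TP index = mean(log2 tumor-signature expression) − mean(log2 immune-signature expression)`

   — positive when tumor-intrinsic growth outruns immune control.
3. **Stratifies survival.** Patients split at the median TP index
   (ties → low) are compared with Kaplan–Meier curves, the log-rank test,
   and a Cox hazard ratio (Breslow ties; monotone-likelihood fits are
   flagged non-estimable instead of returning runaway estimates).
4. **Reproduces cohort descriptive statistics.** Radiology × pathology
   cross-tabs with half-up-rounded percentages, Pearson chi-square and
   Fisher tests, tumor mutation burden (qualifying variants / 30 Mb), and
   per-group tumor-suppressor mutation frequencies.

A synthetic-cohort generator (`simulate_cohort()`) with planted trend
patterns, stage-dependent mutation rates and index-linked exponential
survival makes the whole pipeline testable without controlled-access
patient data.

## Worked example

```r
library(tpindex)

cohort <- simulate_cohort(sim_config(seed = 7))  # 1300 genes x 300 samples
run <- run_tp_pipeline(cohort)
run
#> TP-index progression analysis
#>
#> Genes assigned to trend patterns: 300 of 1300
#> Signature set (de_novo)
#>   tumor  (25): P01_G001, P01_G002, P01_G003, P01_G004, P01_G005, P01_G006, P01_G007, P01_G008, ...
#>   immune (50): P07_G001, P07_G002, P07_G003, P07_G004, P07_G005, P07_G006, P07_G007, P07_G008, ...
#>
#> TP-index median-split survival stratification
#>   groups: high n=75, low n=75
#>   log-rank chi-square 48.216, p = 3.818e-12
#> Hazard ratio 5.475 (95% CI 3.207-9.348), 76 events

run$index_by_stage$by_stage
#> # A tibble: 4 × 5
#>   stage      n      q1 median     q3
#>   <fct>  <int>   <dbl>  <dbl>  <dbl>
#> 1 normal   150 -0.0468 0.0255 0.0833
#> 2 AIS       16  3.73   3.85   3.93
#> 3 MIA       52  6.54   6.62   6.67
#> 4 LUAD      82  9.80   9.88   9.94
```

Reading the output: all 300 planted genes land in a trend pattern (the 1000
null genes stay unclassified); the de-novo signature recovers exactly the
planted pattern-1 (tumor) and pattern-7/8 (immune) genes; the TP index
median climbs monotonically with stage; and the simulated prognostic effect
(log-HR 0.5 per index unit) surfaces as a hazard ratio of ~5.5 for
high-versus-low median split with a vanishing log-rank p.

For real data, read your own tables and score the published signature:

```r
expr <- read_expression_tsv("tpm_matrix.tsv")
idx  <- compute_indices(expr, published_signatures())
sf   <- stratify_survival(idx, read_clinical_csv("clinical.csv"))
glance(sf)      # log-rank p, HR and CI
autoplot(sf)    # KM curves by TP-index group
```

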