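#' Simulation configuration for a synthetic staged cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator. The
#' defaults reproduce the statistical structure the downstream analysis
#' assumes: stage sizes 150/16/52/82 (normal/AIS/MIA/LUAD), log-normal TPM
#' noise, planted genes stepping by `step_log2fc` log2 units per called
#' transition, stage-dependent tumor-suppressor mutation rates, and
#' exponential survival whose log-hazard is linear in the tumor progressive
#' index with administrative censoring.
#'
#' @param n_per_stage Named integer vector of samples per stage.
#' @param n_genes_per_pattern Genes planted per pattern; either a single
#'   count applied to all twelve patterns or a length-12 vector.
#' @param n_null_genes Number of unperturbed (null) genes.
#' @param base_log2_tpm Mean log2 TPM of a gene at its baseline stage.
#' @param base_by_pattern Optional named numeric vector overriding
#'   `base_log2_tpm` for specific patterns (names `"1"`–`"12"`, and `"null"`
#'   for null genes); lets tumor-signature genes start low and immune genes
#'   high, for instance.
#' @param step_log2fc Per-transition effect size in log2 units (default 2,
#'   i.e. fold change 4 per called step).
#' @param noise_sd Within-group standard deviation on the log2 scale
#'   (must be > 0).
#' @param frac_below_tpm_filter Fraction of planted genes whose baseline is
#'   set below TPM 1 so they fall to the low-expression filter.
#' @param mutation_rate_by_stage Named per-gene mutation probability by
#'   stage, applied independently to each tumor-suppressor gene.
#' @param tsg_genes Tumor-suppressor gene list the mutation generator draws
#'   from.
#' @param survival_baseline_hazard Baseline event hazard per month.
#' @param survival_log_hr_per_index_unit Log hazard ratio per unit of
#'   (centred) index.
#' @param censor_time Administrative censoring time in months (> 0).
#' @param seed Integer seed; the same seed and config give a bit-identical
#'   cohort.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_stage = c(normal = 150, AIS = 16, MIA = 52, LUAD = 82),
                       n_genes_per_pattern = 25,
                       n_null_genes = 1000,
                       base_log2_tpm = 5,
                       base_by_pattern = NULL,
                       step_log2fc = 2,
                       noise_sd = 0.5,
                       frac_below_tpm_filter = 0,
                       mutation_rate_by_stage = c(normal = 0.001, AIS = 0.011,
                                                  MIA = 0.007, LUAD = 0.06),
                       tsg_genes = default_tsg_genes(),
                       survival_baseline_hazard = 0.01,
                       survival_log_hr_per_index_unit = 0.5,
                       censor_time = 60,
                       seed = 1L) {
  if (length(n_genes_per_pattern) == 1) {
    n_genes_per_pattern <- rep(n_genes_per_pattern, 12)
  }
  stopifnot(length(n_genes_per_pattern) == 12)
  if (!setequal(names(n_per_stage), STAGES)) {
    abort("`n_per_stage` must be named with exactly the four stages.")
  }
  if (any(n_per_stage < 0) || any(n_genes_per_pattern < 0) || n_null_genes < 0) {
    abort("Counts must be non-negative.")
  }
  if (noise_sd <= 0) abort("`noise_sd` must be > 0.")
  if (censor_time < 0) abort("`censor_time` must be >= 0.")
  if (frac_below_tpm_filter < 0 || frac_below_tpm_filter > 1) {
    abort("`frac_below_tpm_filter` must be in [0, 1].")
  }
  if (any(mutation_rate_by_stage < 0) || any(mutation_rate_by_stage > 1)) {
    abort("`mutation_rate_by_stage` entries must be probabilities in [0, 1].")
  }
  if (survival_baseline_hazard <= 0) abort("`survival_baseline_hazard` must be > 0.")
  structure(list(
    n_per_stage = n_per_stage[STAGES],
    n_genes_per_pattern = as.integer(n_genes_per_pattern),
    n_null_genes = as.integer(n_null_genes),
    base_log2_tpm = base_log2_tpm,
    base_by_pattern = base_by_pattern,
    step_log2fc = step_log2fc,
    noise_sd = noise_sd,
    frac_below_tpm_filter = frac_below_tpm_filter,
    mutation_rate_by_stage = mutation_rate_by_stage,
    tsg_genes = tsg_genes,
    survival_baseline_hazard = survival_baseline_hazard,
    survival_log_hr_per_index_unit = survival_log_hr_per_index_unit,
    censor_time = censor_time,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Direction triple -> cumulative log2 offsets at the four stages.
pattern_stage_offsets <- function(step_log2fc) {
  tmpl <- trend_pattern_templates()
  signs <- function(d) c(up = 1, none = 0, down = -1)[d]
  offs <- t(apply(tmpl[, TRANSITIONS], 1, function(d) {
    cumsum(c(0, signs(d))) * step_log2fc
  }))
  colnames(offs) <- STAGES
  rownames(offs) <- as.character(tmpl$pattern)
  offs
}

# Table 1 radiology composition conditional on pathology, used to make
# radiology x pathology cross-tabs non-degenerate (AIS/MIA mostly pure GGO).
radiology_probs <- function(stage) {
  if (stage %in% c("AIS", "MIA")) c(66, 31, 1) / 98 else c(3, 32, 64) / 99
}

#' Generate a synthetic staged expression cohort
#'
#' Builds a paired normal/tumor cohort with the structure assumed by the
#' trend-pattern, index, survival and mutation analyses. Each tumor sample
#' belongs to a distinct patient, and every patient also contributes one
#' adjacent-normal sample. Planted genes follow one of the twelve trend
#' templates on the log2 scale; per-sample TPM is
#' `2^(group mean + N(0, noise_sd))`, so expression is log-normal and always
#' positive. Survival is generated from the realised tumor progressive index
#' (planted pattern-1 genes minus planted immune-type pattern-7/8 genes) via
#' [simulate_survival()]; tumor-suppressor mutations via
#' [simulate_mutations()].
#'
#' @param config A [sim_config()].
#' @return A list of class `tp_cohort`:
#' \describe{
#'   \item{expression}{genes-by-samples TPM tibble (first column `gene`).}
#'   \item{clinical}{tibble of `patient_id`, `sample_id`, `stage`,
#'     `radiology`, `time`, `event` (survival on tumor rows only).}
#'   \item{mutations}{tibble of `sample_id`, `gene`, `variant_class`.}
#'   \item{truth}{tibble of `gene`, `pattern` (`"1"`–`"12"` or `"null"`).}
#'   \item{immune_genes}{planted pattern-7/8 gene symbols, usable as the
#'     a-priori immune list in signature selection.}
#'   \item{true_log_hr}{the log hazard ratio per index unit used.}
#'   \item{config}{the configuration.}
#' }
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_genes_per_pattern = 2,
#'                                      n_null_genes = 5, seed = 7))
#' dim(cohort$expression)
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  n_tumor <- sum(config$n_per_stage[c("AIS", "MIA", "LUAD")])
  tumor_stage <- rep(c("AIS", "MIA", "LUAD"),
                     times = config$n_per_stage[c("AIS", "MIA", "LUAD")])
  patients <- sprintf("PT%03d", seq_len(n_tumor))
  tumor_ids <- paste0(patients, "_T")
  # every patient contributes a paired normal; extra normals (if the normal
  # count exceeds the tumor count) come from additional patients
  n_normal <- config$n_per_stage[["normal"]]
  extra <- max(0, n_normal - n_tumor)
  normal_patients <- c(patients[seq_len(min(n_tumor, n_normal))],
                       sprintf("PT%03d", n_tumor + seq_len(extra)))
  normal_ids <- paste0(normal_patients, "_N")

  sample_ids <- c(normal_ids, tumor_ids)
  sample_stage <- c(rep("normal", n_normal), tumor_stage)

  # gene panel: planted pattern genes, then null genes
  truth <- tibble(
    gene = character(0), pattern = character(0)
  )
  for (p in 1:12) {
    np <- config$n_genes_per_pattern[p]
    if (np > 0) {
      truth <- dplyr::bind_rows(truth, tibble(
        gene = sprintf("P%02d_G%03d", p, seq_len(np)),
        pattern = as.character(p)
      ))
    }
  }
  if (config$n_null_genes > 0) {
    truth <- dplyr::bind_rows(truth, tibble(
      gene = sprintf("NULL_G%04d", seq_len(config$n_null_genes)),
      pattern = "null"
    ))
  }
  if (nrow(truth) == 0) abort("Configuration generates zero genes.")

  base_for <- function(pattern) {
    b <- config$base_by_pattern
    if (!is.null(b) && pattern %in% names(b)) b[[pattern]] else config$base_log2_tpm
  }
  offs <- pattern_stage_offsets(config$step_log2fc)

  # per-gene baseline; a fraction of planted genes is parked below TPM 1
  gene_base <- vapply(truth$pattern, base_for, numeric(1))
  planted <- which(truth$pattern != "null")
  if (config$frac_below_tpm_filter > 0 && length(planted) > 0) {
    n_low <- round(config$frac_below_tpm_filter * length(planted))
    low_idx <- planted[seq_len(n_low)]
    gene_base[low_idx] <- -2  # mean TPM 0.25, safely under the filter
  }

  # group-mean matrix on log2 scale (genes x stages)
  mean_by_stage <- matrix(gene_base, nrow = nrow(truth), ncol = 4,
                          dimnames = list(truth$gene, STAGES))
  is_planted <- truth$pattern != "null"
  mean_by_stage[is_planted, ] <- mean_by_stage[is_planted, , drop = FALSE] +
    offs[truth$pattern[is_planted], , drop = FALSE]

  log2_mu <- mean_by_stage[, sample_stage, drop = FALSE]
  noise <- matrix(stats::rnorm(length(log2_mu), sd = config$noise_sd),
                  nrow = nrow(log2_mu))
  tpm <- 2^(log2_mu + noise)
  colnames(tpm) <- sample_ids

  expression <- dplyr::bind_cols(tibble(gene = truth$gene), as_tibble(tpm))

  radiology <- vapply(sample_stage, function(st) {
    if (st == "normal") NA_character_
    else sample(RADIOLOGY, 1, prob = radiology_probs(st))
  }, character(1))

  clinical <- tibble(
    patient_id = c(normal_patients, patients),
    sample_id = sample_ids,
    stage = sample_stage,
    radiology = radiology
  )

  # realised TP-style index of each tumor sample drives its patient's hazard
  tumor_cols <- tumor_ids
  p1_genes <- truth$gene[truth$pattern == "1"]
  imm_genes <- truth$gene[truth$pattern %in% c("7", "8")]
  if (length(p1_genes) > 0 && length(imm_genes) > 0) {
    lt <- log2(tpm[, tumor_cols, drop = FALSE] + 1)
    idx <- colMeans(lt[p1_genes, , drop = FALSE]) -
      colMeans(lt[imm_genes, , drop = FALSE])
    idx <- idx - mean(idx)  # centred so the baseline hazard stays interpretable
  } else {
    idx <- stats::rnorm(length(tumor_cols))
  }
  surv <- simulate_survival(tibble(patient_id = patients, index = unname(idx)),
                            config)
  clinical <- dplyr::left_join(clinical, surv, by = "patient_id")

  mutations <- simulate_mutations(config, clinical)

  structure(list(
    expression = expression,
    clinical = clinical,
    mutations = mutations,
    truth = truth,
    immune_genes = imm_genes,
    true_log_hr = config$survival_log_hr_per_index_unit,
    config = config
  ), class = "tp_cohort")
}

#' Simulate right-censored survival from a per-patient index
#'
#' Event times are exponential with hazard
#' `baseline * exp(log_hr_per_index_unit * index)`; times beyond
#' `censor_time` are administratively censored there. Called by
#' [simulate_cohort()] but usable on its own (it does not touch the random
#' seed, so wrap in `set.seed()` for reproducibility).
#'
#' @param index Tibble with `patient_id` and numeric `index`.
#' @param config A [sim_config()]; uses its `survival_*` and `censor_time`
#'   fields.
#' @return Tibble of `patient_id`, `time`, `event` (1 = event, 0 = censored).
#' @export
simulate_survival <- function(index, config = sim_config()) {
  if (!is.data.frame(index) || nrow(index) == 0) {
    abort("`index` must be a non-empty data frame with patient_id and index.")
  }
  stopifnot(all(c("patient_id", "index") %in% names(index)))
  hazard <- config$survival_baseline_hazard *
    exp(config$survival_log_hr_per_index_unit * index$index)
  t_event <- stats::rexp(nrow(index), rate = hazard)
  time <- pmin(t_event, config$censor_time)
  tibble(
    patient_id = index$patient_id,
    time = time,
    event = as.integer(t_event <= config$censor_time)
  )
}

#' Simulate a tumor-suppressor mutation table
#'
#' Each tumor-suppressor gene is mutated independently in each sample with
#' the sample's stage-specific probability; records carry variant class
#' `"nonsynonymous"`. Does not reset the random seed.
#'
#' @param config A [sim_config()]; uses `mutation_rate_by_stage` and
#'   `tsg_genes`.
#' @param clinical Clinical tibble with `sample_id` and `stage`.
#' @return Tibble of `sample_id`, `gene`, `variant_class` (possibly empty).
#' @export
simulate_mutations <- function(config, clinical) {
  rates <- config$mutation_rate_by_stage
  missing <- setdiff(unique(clinical$stage), names(rates))
  if (length(missing) > 0) {
    abort(paste0("No mutation rate for stage(s): ", paste(missing, collapse = ", ")))
  }
  genes <- config$tsg_genes
  rows <- purrr::map_dfr(seq_len(nrow(clinical)), function(i) {
    p <- rates[[clinical$stage[i]]]
    if (p == 0) return(NULL)
    hit <- stats::runif(length(genes)) < p
    if (!any(hit)) return(NULL)
    tibble(sample_id = clinical$sample_id[i], gene = genes[hit],
           variant_class = "nonsynonymous")
  })
  if (nrow(rows) == 0) {
    rows <- tibble(sample_id = character(0), gene = character(0),
                   variant_class = character(0))
  }
  rows
}

#' @export
print.tp_cohort <- function(x, ...) {
  cat("Synthetic staged cohort\n")
  cat("  genes:   ", nrow(x$expression),
      " (", sum(x$truth$pattern != "null"), " planted, ",
      sum(x$truth$pattern == "null"), " null)\n", sep = "")
  cat("  samples: ", ncol(x$expression) - 1, "\n", sep = "")
  st <- table(factor(x$clinical$stage, levels = STAGES))
  cat("  stages:  ", paste(names(st), st, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  mutations:", nrow(x$mutations), "records\n")
  invisible(x)
}
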