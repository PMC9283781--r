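#' The twelve adjacent-stage trend-pattern templates
#'
#' Each pattern is a triple of direction calls over the three adjacent-stage
#' transitions (normal→AIS, AIS→MIA, MIA→LUAD). Patterns 1–6 are the up-trend
#' templates, 7–12 their mirror images: negating every step maps pattern 1↔7,
#' 2↔8, 3↔9, 4↔10, 5↔11 and 6↔12. Triples outside these twelve (including the
#' all-`none` triple) are "unclassified".
#'
#' @return A tibble with columns `pattern` (integer 1–12) and the direction of
#'   each transition (`normal_vs_AIS`, `AIS_vs_MIA`, `MIA_vs_LUAD`), each one
#'   of `"up"`, `"none"`, `"down"`.
#' @export
#' @examples
#' trend_pattern_templates()
trend_pattern_templates <- function() {
  tibble(
    pattern = 1:12,
    normal_vs_AIS = c("up", "up", "up", "none", "none", "none",
                      "down", "down", "down", "none", "none", "none"),
    AIS_vs_MIA    = c("up", "none", "none", "up", "up", "none",
                      "down", "none", "none", "down", "down", "none"),
    MIA_vs_LUAD   = c("up", "up", "none", "up", "none", "up",
                      "down", "down", "none", "down", "none", "down")
  )
}

# Vectorised Welch (or pooled) two-sample t-test across matrix rows.
# Returns two-sided p-values. Zero-variance conventions: both groups constant
# and equal -> p = 1; both constant and unequal -> p = 0.
row_t_test <- function(mat, idx1, idx2, pooled = FALSE) {
  n1 <- length(idx1)
  n2 <- length(idx2)
  x1 <- mat[, idx1, drop = FALSE]
  x2 <- mat[, idx2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, nrow(mat))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m2 - m1) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  p
}

#' Differential test between two adjacent stages for every gene
#'
#' For each gene, compares the two stages of each adjacent transition with a
#' two-sided two-sample location test on `log2(TPM + 1)` and computes the fold
#' change as the ratio of arithmetic mean TPM (later stage over earlier
#' stage), with a small pseudocount added to both means to avoid division by
#' zero. Direction calls combine a significance gate `p < alpha` with a
#' fold-change gate `FC >= fc_min` (up) or `FC <= 1/fc_min` (down).
#'
#' @param expr Expression tibble: a `gene` column followed by one numeric TPM
#'   column per sample.
#' @param clinical Clinical tibble with `sample_id` and `stage` columns; every
#'   expression sample must appear.
#' @param alpha Significance threshold on the raw p-value (no multiplicity
#'   correction, matching the screening convention). Default `1e-4`.
#' @param fc_min Fold-change threshold (ratio scale, >= 1). Default `2`.
#' @param method `"welch"` (default) for Welch's unequal-variance t-test, or
#'   `"anova"` for the pooled-variance test (the exact two-group reduction of
#'   a one-way stage-factor ANOVA, whose F statistic is the square of the
#'   pooled t).
#' @param fc_eps Pseudocount added to both group means before taking their
#'   ratio. Default `1e-9`.
#' @return A tibble with one row per gene and transition: `gene`,
#'   `transition`, `p_value`, `fold_change`, `direction`.
#' @export
test_transitions <- function(expr, clinical, alpha = 1e-4, fc_min = 2,
                             method = c("welch", "anova"), fc_eps = 1e-9) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1, fc_min >= 1, fc_eps >= 0)
  mat <- expr_matrix(expr)
  stage_of <- stage_lookup(expr, clinical)
  lmat <- log2(mat + 1)

  purrr::map_dfr(seq_along(TRANSITIONS), function(k) {
    one_transition(mat, lmat, stage_of, k, alpha = alpha, fc_min = fc_min,
                   pooled = method == "anova", fc_eps = fc_eps)
  })
}

one_transition <- function(mat, lmat, stage_of, k, alpha, fc_min, pooled, fc_eps) {
  earlier <- STAGES[k]
  later <- STAGES[k + 1]
  idx1 <- which(stage_of == earlier)
  idx2 <- which(stage_of == later)
  if (length(idx1) < 2 || length(idx2) < 2) {
    abort(paste0(
      "Transition ", TRANSITIONS[k], " needs >= 2 samples per stage (found ",
      length(idx1), " ", earlier, ", ", length(idx2), " ", later, ")."
    ))
  }
  p <- row_t_test(lmat, idx1, idx2, pooled = pooled)
  fc <- (rowMeans(mat[, idx2, drop = FALSE]) + fc_eps) /
    (rowMeans(mat[, idx1, drop = FALSE]) + fc_eps)
  tibble(
    gene = rownames(mat),
    transition = TRANSITIONS[k],
    p_value = unname(p),
    fold_change = unname(fc),
    direction = call_transition(p, fc, alpha = alpha, fc_min = fc_min)
  )
}

#' Differential test for one gene over one transition
#'
#' Single-gene convenience wrapper around the same test used by
#' [test_transitions()].
#'
#' @inheritParams test_transitions
#' @param gene A gene symbol present in `expr`.
#' @param transition One of `"normal_vs_AIS"`, `"AIS_vs_MIA"`,
#'   `"MIA_vs_LUAD"`.
#' @return A one-row tibble: `gene`, `transition`, `p_value`, `fold_change`,
#'   `direction`.
#' @export
adjacent_group_test <- function(expr, clinical, gene, transition,
                                alpha = 1e-4, fc_min = 2,
                                method = c("welch", "anova"), fc_eps = 1e-9) {
  transition <- match.arg(transition, TRANSITIONS)
  method <- match.arg(method)
  if (!gene %in% expr$gene) {
    abort(paste0("Gene not found in expression matrix: ", gene))
  }
  sub <- expr[expr$gene == gene, , drop = FALSE]
  mat <- expr_matrix(sub)
  stage_of <- stage_lookup(sub, clinical)
  one_transition(mat, log2(mat + 1), stage_of, match(transition, TRANSITIONS),
                 alpha = alpha, fc_min = fc_min, pooled = method == "anova",
                 fc_eps = fc_eps)
}

#' Direction call from a p-value and fold change
#'
#' `"up"` if `p < alpha` and `FC >= fc_min`; `"down"` if `p < alpha` and
#' `FC <= 1/fc_min`; otherwise `"none"`. Vectorised.
#'
#' @param p_value Numeric vector of p-values in `[0, 1]`.
#' @param fold_change Numeric vector of positive fold changes (ratio scale).
#' @inheritParams test_transitions
#' @return Character vector of `"up"`, `"none"`, `"down"`.
#' @export
#' @examples
#' call_transition(c(1e-5, 1e-5, 0.01), c(4, 1.5, 8))  # up, none, none
call_transition <- function(p_value, fold_change, alpha = 1e-4, fc_min = 2) {
  if (any(fold_change <= 0, na.rm = TRUE)) {
    abort("`fold_change` must be positive (a ratio of means).")
  }
  sig <- p_value < alpha
  dplyr::case_when(
    sig & fold_change >= fc_min ~ "up",
    sig & fold_change <= 1 / fc_min ~ "down",
    .default = "none"
  )
}

#' Classify a direction triple into one of the twelve patterns
#'
#' Looks the triple up in the fixed template table; triples outside the
#' twelve templates (including all-`none`) are `"unclassified"`. Vectorised
#' over the three direction vectors.
#'
#' @param d1,d2,d3 Direction calls (`"up"`, `"none"`, `"down"`) for the
#'   normal→AIS, AIS→MIA and MIA→LUAD transitions.
#' @return Character vector: `"1"`–`"12"` or `"unclassified"`.
#' @export
#' @examples
#' classify_gene_pattern("up", "up", "up")       # "1"
#' classify_gene_pattern("down", "none", "down") # "8"
#' classify_gene_pattern("up", "up", "none")     # "unclassified"
classify_gene_pattern <- function(d1, d2, d3) {
  ok <- c("up", "none", "down")
  if (!all(c(d1, d2, d3) %in% ok)) {
    abort("Directions must be one of \"up\", \"none\", \"down\".")
  }
  tmpl <- trend_pattern_templates()
  key <- paste(d1, d2, d3, sep = "|")
  tmpl_key <- paste(tmpl$normal_vs_AIS, tmpl$AIS_vs_MIA, tmpl$MIA_vs_LUAD, sep = "|")
  hit <- match(key, tmpl_key)
  ifelse(is.na(hit), "unclassified", as.character(tmpl$pattern[hit]))
}

#' Assign every gene to a trend pattern
#'
#' Runs the adjacent-stage tests for all genes and transitions, calls
#' directions, and classifies each gene's direction triple against the twelve
#' templates. Genes with no significant transition, or a triple outside the
#' templates, are `"unclassified"`; the labels partition the gene set.
#'
#' @inheritParams test_transitions
#' @return A tibble of class `tp_patterns` with one row per gene: `gene`,
#'   the three per-transition directions, `p_<transition>` and
#'   `fc_<transition>` columns, and `pattern` (`"1"`–`"12"` or
#'   `"unclassified"`). Summarise with [pattern_counts()].
#' @export
assign_patterns <- function(expr, clinical, alpha = 1e-4, fc_min = 2,
                            method = c("welch", "anova"), fc_eps = 1e-9) {
  calls <- test_transitions(expr, clinical, alpha = alpha, fc_min = fc_min,
                            method = method, fc_eps = fc_eps)
  wide <- tidyr::pivot_wider(
    calls,
    id_cols = "gene",
    names_from = "transition",
    values_from = c("direction", "p_value", "fold_change"),
    names_glue = "{.value}_{transition}"
  )
  out <- dplyr::mutate(
    wide,
    pattern = classify_gene_pattern(
      .data$direction_normal_vs_AIS,
      .data$direction_AIS_vs_MIA,
      .data$direction_MIA_vs_LUAD
    )
  )
  # preserve input gene order
  out <- out[match(expr$gene, out$gene), ]
  class(out) <- c("tp_patterns", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "fc_min") <- fc_min
  out
}

#' Per-pattern gene counts
#'
#' @param assignments Result of [assign_patterns()].
#' @return A tibble with `pattern` (`"1"`–`"12"`, `"unclassified"`) and
#'   `n_genes`; every level is present, empty ones with a zero count, so the
#'   counts always sum to the number of genes tested.
#' @export
pattern_counts <- function(assignments) {
  levels <- c(as.character(1:12), "unclassified")
  counts <- table(factor(assignments$pattern, levels = levels))
  tibble(pattern = levels, n_genes = as.integer(counts))
}

#' @method autoplot tp_patterns
#' @export
autoplot.tp_patterns <- function(object, ...) {
  counts <- pattern_counts(object)
  counts$pattern <- factor(counts$pattern, levels = counts$pattern)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$pattern, y = .data$n_genes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Trend pattern", y = "Genes",
                  title = "Genes per adjacent-stage trend pattern") +
    ggplot2::theme_minimal()
}
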