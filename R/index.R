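#' Published tumor and immune signature gene sets
#'
#' The four-gene tumor-growth signature (BCL2L15, COMP, CST1, FAM83A) and the
#' eight-gene immune signature (ITLN2, MARCO, C8B, MASP1, CD36, TAL1, PPBP,
#' CDH5) underlying the tumor progressive index. Shipped as a fixture so the
#' index can be scored on any conforming TPM matrix without re-running
#' signature selection.
#'
#' @return A list of class `signature_set` with character vectors
#'   `tumor_genes` and `immune_genes` and a `provenance` tag.
#' @export
#' @examples
#' published_signatures()
published_signatures <- function() {
  new_signature_set(
    tumor_genes = c("BCL2L15", "COMP", "CST1", "FAM83A"),
    immune_genes = c("ITLN2", "MARCO", "C8B", "MASP1", "CD36", "TAL1", "PPBP", "CDH5"),
    provenance = "published"
  )
}

new_signature_set <- function(tumor_genes, immune_genes, provenance) {
  if (length(tumor_genes) == 0 || length(immune_genes) == 0) {
    abort("Both signature gene sets must be non-empty.")
  }
  if (length(intersect(tumor_genes, immune_genes)) > 0) {
    abort("Tumor and immune signatures must be disjoint.")
  }
  structure(list(tumor_genes = tumor_genes, immune_genes = immune_genes,
                 provenance = provenance),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  show <- function(g) {
    if (length(g) > 8) paste(c(g[1:8], "..."), collapse = ", ")
    else paste(g, collapse = ", ")
  }
  cat("Signature set (", x$provenance, ")\n", sep = "")
  cat("  tumor  (", length(x$tumor_genes), "): ", show(x$tumor_genes), "\n", sep = "")
  cat("  immune (", length(x$immune_genes), "): ", show(x$immune_genes), "\n", sep = "")
  invisible(x)
}

#' Filter genes by mean expression across all samples
#'
#' Keeps genes whose mean TPM over all samples (tumor and normal alike) is at
#' least `min_mean_tpm`; the boundary is inclusive (a constant TPM of exactly
#' 1.0 is retained under the default threshold). This is the low-expression
#' gate applied before signature selection.
#'
#' @inheritParams test_transitions
#' @param min_mean_tpm Retention threshold on the mean TPM (default 1.0).
#' @return Character vector of retained gene symbols.
#' @export
filter_low_expression <- function(expr, min_mean_tpm = 1.0) {
  mat <- expr_matrix(expr)
  if (nrow(mat) == 0 || ncol(mat) == 0) abort("Expression matrix is empty.")
  expr$gene[rowMeans(mat) >= min_mean_tpm]
}

#' Select tumor and immune signatures from pattern assignments
#'
#' The tumor signature is the pattern-1 genes (monotone increase across all
#' three transitions) surviving the expression filter. The immune signature
#' is the expression-filtered genes from the down-trend patterns that also
#' appear in an a-priori immune-related gene list: patterns 7 and 8 under the
#' default mode, pattern 8 alone under `"pattern8_only"`.
#'
#' @param assignments Result of [assign_patterns()].
#' @param retained Character vector of genes passing
#'   [filter_low_expression()].
#' @param immune_list A-priori immune-related gene symbols.
#' @param mode `"pattern7_and_8"` (default) or `"pattern8_only"`.
#' @return A `signature_set` with provenance `"de_novo"`.
#' @export
select_signatures <- function(assignments, retained, immune_list,
                              mode = c("pattern7_and_8", "pattern8_only")) {
  mode <- match.arg(mode)
  if (length(immune_list) == 0) abort("`immune_list` must be non-empty.")
  tumor <- intersect(assignments$gene[assignments$pattern == "1"], retained)
  imm_patterns <- if (mode == "pattern8_only") "8" else c("7", "8")
  immune <- assignments$gene[assignments$pattern %in% imm_patterns]
  immune <- intersect(intersect(immune, retained), immune_list)
  if (length(tumor) == 0 || length(immune) == 0) {
    abort(paste0(
      "Signature selection produced an empty set (tumor: ", length(tumor),
      ", immune: ", length(immune), "). Candidate pattern-1 genes: ",
      sum(assignments$pattern == "1"), "; pattern-", paste(imm_patterns, collapse = "/"),
      " genes: ", sum(assignments$pattern %in% imm_patterns),
      "; of those in the immune list: ",
      length(intersect(assignments$gene[assignments$pattern %in% imm_patterns],
                       immune_list)), "."
    ))
  }
  new_signature_set(tumor, immune, provenance = "de_novo")
}

#' Compute tumor, immune and tumor progressive indices per sample
#'
#' For each sample, the tumor index is the mean of
#' `log2(TPM + pseudocount)` over the tumor-signature genes, the immune index
#' the analogous mean over the immune signature, and the tumor progressive
#' (TP) index their difference. `pseudocount = 0` gives the exact
#' log-of-expression algebra (doubling every tumor-gene TPM adds exactly 1)
#' but requires strictly positive TPM for all signature genes.
#'
#' @inheritParams test_transitions
#' @param signatures A `signature_set` ([published_signatures()] or
#'   [select_signatures()]).
#' @param pseudocount Added inside the log2; default 1 for robustness to
#'   zeros.
#' @return A tibble of class `tp_index_tbl`: `sample_id`, `tumor_index`,
#'   `immune_index`, `tp_index` (log2 TPM units).
#' @export
#' @examples
#' expr <- tibble::tibble(gene = c("BCL2L15", "COMP", "CST1", "FAM83A",
#'                                 "ITLN2", "MARCO", "C8B", "MASP1",
#'                                 "CD36", "TAL1", "PPBP", "CDH5"),
#'                        S1 = c(rep(4, 4), rep(2, 8)))
#' compute_indices(expr, published_signatures(), pseudocount = 0)
compute_indices <- function(expr, signatures, pseudocount = 1) {
  stopifnot(inherits(signatures, "signature_set"))
  mat <- expr_matrix(expr)
  sig_genes <- c(signatures$tumor_genes, signatures$immune_genes)
  missing <- setdiff(sig_genes, rownames(mat))
  if (length(missing) > 0) {
    abort(paste0("Signature gene(s) absent from expression matrix: ",
                 paste(missing, collapse = ", ")))
  }
  sub <- mat[sig_genes, , drop = FALSE]
  if (pseudocount == 0 && any(sub == 0)) {
    abort("pseudocount = 0 requires strictly positive TPM for all signature genes.")
  }
  lmat <- log2(sub + pseudocount)
  tumor <- colMeans(lmat[signatures$tumor_genes, , drop = FALSE])
  immune <- colMeans(lmat[signatures$immune_genes, , drop = FALSE])
  out <- tibble(
    sample_id = colnames(mat),
    tumor_index = unname(tumor),
    immune_index = unname(immune),
    tp_index = unname(tumor - immune)
  )
  class(out) <- c("tp_index_tbl", class(out))
  out
}

#' Summarise and compare the TP index across stages
#'
#' Per-stage median and quartiles of the TP index, plus a two-sided Wilcoxon
#' rank-sum test between each adjacent stage pair. Stages with no samples are
#' dropped with a warning; a pair where either stage has a single sample is
#' reported with `p_value = NA` (test not applicable).
#'
#' @param index Result of [compute_indices()].
#' @param clinical Clinical tibble with `sample_id` and `stage`.
#' @return A list with tibbles `by_stage` (`stage`, `n`, `q1`, `median`,
#'   `q3`) and `adjacent_tests` (`comparison`, `p_value`).
#' @export
compare_index_by_stage <- function(index, clinical) {
  df <- dplyr::inner_join(index, clinical[, c("sample_id", "stage")],
                          by = "sample_id")
  df$stage <- as_stage(df$stage)
  present <- STAGES[STAGES %in% unique(as.character(df$stage))]
  absent <- setdiff(STAGES, present)
  if (length(absent) > 0) {
    warn(paste0("Stage(s) with no samples excluded: ", paste(absent, collapse = ", ")))
  }
  if (length(present) < 2) abort("Need >= 2 stages with samples to compare.")

  by_stage <- df |>
    dplyr::group_by(stage = factor(as.character(.data$stage), levels = present)) |>
    dplyr::summarise(
      n = dplyr::n(),
      q1 = stats::quantile(.data$tp_index, 0.25, names = FALSE),
      median = stats::median(.data$tp_index),
      q3 = stats::quantile(.data$tp_index, 0.75, names = FALSE),
      .groups = "drop"
    )

  pairs <- purrr::map_dfr(seq_len(length(present) - 1), function(k) {
    a <- df$tp_index[df$stage == present[k]]
    b <- df$tp_index[df$stage == present[k + 1]]
    p <- if (length(a) < 2 || length(b) < 2) NA_real_ else {
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    }
    tibble(comparison = paste(present[k], "vs", present[k + 1]), p_value = p)
  })
  list(by_stage = by_stage, adjacent_tests = pairs)
}

#' Boxplot of the TP index by stage
#'
#' @param index Result of [compute_indices()].
#' @param clinical Clinical tibble with `sample_id` and `stage`.
#' @return A ggplot object.
#' @export
plot_index_by_stage <- function(index, clinical) {
  df <- dplyr::inner_join(index, clinical[, c("sample_id", "stage")],
                          by = "sample_id")
  df$stage <- as_stage(df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$tp_index)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::labs(x = NULL, y = "Tumor progressive index",
                  title = "TP index across pathological stages") +
    ggplot2::theme_minimal()
}
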