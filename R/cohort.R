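#' Default tumor-suppressor gene list
#'
#' A small configurable list of canonically inactivated tumor suppressors
#' used by the mutation-frequency summaries and the simulator; substitute
#' any list via the function arguments or [read_gene_list()].
#'
#' @return Character vector of gene symbols.
#' @export
default_tsg_genes <- function() {
  c("TP53", "RB1", "STK11", "NF1", "KEAP1", "PTEN", "CDKN2A", "SMAD4")
}

#' Cross-tabulate two clinical variables
#'
#' Patient counts per combination of two categorical clinical variables,
#' with category ordering following first appearance in the input (rows with
#' `NA` in either variable are dropped).
#'
#' @param clinical A clinical tibble.
#' @param row_var,col_var Column names to tabulate.
#' @return An integer matrix with named dimensions (a contingency table).
#' @export
#' @examples
#' cl <- tibble::tibble(path = c("AIS", "AIS", "LUAD"),
#'                      rad = c("pure_GGO", "solid", "solid"))
#' crosstab(cl, "path", "rad")
crosstab <- function(clinical, row_var, col_var) {
  for (v in c(row_var, col_var)) {
    if (!v %in% names(clinical)) abort(paste0("Unknown variable: ", v))
  }
  r <- clinical[[row_var]]
  c_ <- clinical[[col_var]]
  keep <- !is.na(r) & !is.na(c_)
  r <- factor(r[keep], levels = unique(r[keep]))
  c_ <- factor(c_[keep], levels = unique(c_[keep]))
  tab <- table(r, c_)
  m <- matrix(as.integer(tab), nrow = nlevels(r),
              dimnames = list(levels(r), levels(c_)))
  names(dimnames(m)) <- c(row_var, col_var)
  m
}

#' Percentage of a contingency-table cell
#'
#' `100 * count / denominator`, rounded half-up to one decimal — the printed
#' convention of clinical characteristics tables. The denominator is the
#' column total (default), row total, or grand total.
#'
#' @param tab A counts matrix (e.g. from [crosstab()]).
#' @param row,col Row/column name or position of the cell.
#' @param denominator `"column"`, `"row"` or `"total"`.
#' @return Percentage rounded to one decimal.
#' @export
#' @examples
#' tab <- matrix(c(66, 3, 31, 32, 1, 64), nrow = 2,
#'               dimnames = list(c("AIS/MIA", "LUAD"),
#'                               c("pure_GGO", "subsolid", "solid")))
#' cell_percent(tab, "AIS/MIA", "pure_GGO")  # 95.7
cell_percent <- function(tab, row, col, denominator = c("column", "row", "total")) {
  denominator <- match.arg(denominator)
  den <- switch(denominator,
                column = sum(tab[, col]),
                row = sum(tab[row, ]),
                total = sum(tab))
  if (den == 0) abort("Zero denominator; cannot compute a percentage.")
  round_half_up(100 * tab[row, col] / den, 1)
}

#' Pearson chi-square test on a contingency table
#'
#' The uncorrected Pearson statistic `sum((O - E)^2 / E)` with
#' `df = (r - 1)(c - 1)`, via [stats::chisq.test()] with
#' `correct = FALSE`.
#'
#' @param tab A counts matrix with all row and column margins positive.
#' @return A list: `statistic`, `df`, `p_value`.
#' @export
chisq_test_table <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Chi-square test requires all margins > 0.")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test via [stats::fisher.test()].
#'
#' @param tab A 2x2 counts matrix.
#' @return The two-sided p-value.
#' @export
fisher_test_2x2 <- function(tab) {
  if (!all(dim(tab) == c(2, 2))) abort("Fisher's exact test here requires a 2x2 table.")
  stats::fisher.test(tab)$p.value
}

# Variant classes counted toward TMB: nonsynonymous point variants plus
# indels. MAF dialects differ; the set is configurable.
default_tmb_classes <- function() {
  c("nonsynonymous", "nonsynonymous SNV", "missense", "nonsense", "stopgain",
    "stoploss", "indel", "frameshift insertion", "frameshift deletion",
    "nonframeshift insertion", "nonframeshift deletion")
}

#' Tumor mutation burden per sample
#'
#' TMB in mutations per megabase: the number of qualifying records
#' (nonsynonymous SNVs and indels by default) for each sample divided by the
#' exome-capture footprint `coverage_mb` (default 30 Mb).
#'
#' @param mutations Tibble with `sample_id`, `gene`, `variant_class`.
#' @param samples Samples to report; defaults to those present in
#'   `mutations`. A requested sample with no records gets TMB 0.
#' @param qualifying_classes Variant classes counted.
#' @param coverage_mb Sequenced footprint in Mb.
#' @return Tibble of `sample_id`, `n_mutations`, `tmb`.
#' @export
#' @examples
#' mut <- tibble::tibble(sample_id = "S1", gene = paste0("G", 1:60),
#'                       variant_class = "nonsynonymous")
#' compute_tmb(mut)$tmb  # 2
compute_tmb <- function(mutations, samples = NULL,
                        qualifying_classes = default_tmb_classes(),
                        coverage_mb = 30) {
  stopifnot(all(c("sample_id", "variant_class") %in% names(mutations)))
  if (is.null(samples)) samples <- unique(mutations$sample_id)
  qual <- mutations[mutations$variant_class %in% qualifying_classes, ]
  counts <- table(factor(qual$sample_id, levels = samples))
  tibble(
    sample_id = samples,
    n_mutations = as.integer(counts),
    tmb = as.integer(counts) / coverage_mb
  )
}

#' Tumor-suppressor mutation frequency by group
#'
#' Per clinical group: the number and percentage of samples carrying at
#' least one mutation in a tumor-suppressor gene, plus a chi-square test of
#' mutated/unmutated counts across groups. Percentages are rounded half-up
#' to one decimal, the printed convention.
#'
#' @param mutations Tibble with `sample_id`, `gene`.
#' @param clinical Tibble with `sample_id` and the grouping column; rows
#'   with `NA` group are dropped.
#' @param tsg_list Tumor-suppressor gene symbols.
#' @param group_var Name of the grouping column (e.g. `"stage"` or
#'   `"radiology"`).
#' @return A list with `by_group` (tibble of `group`, `n_mutated`, `n`,
#'   `percent`) and `chisq` (the across-group test, `NA` when fewer than
#'   two groups or a degenerate margin).
#' @export
tsg_frequency_by_group <- function(mutations, clinical, tsg_list = default_tsg_genes(),
                                   group_var = "stage") {
  if (length(tsg_list) == 0) abort("`tsg_list` must be non-empty.")
  if (!group_var %in% names(clinical)) {
    abort(paste0("Unknown grouping variable: ", group_var))
  }
  cl <- clinical[!is.na(clinical[[group_var]]), ]
  mutated_samples <- unique(mutations$sample_id[mutations$gene %in% tsg_list])
  cl$mutated <- cl$sample_id %in% mutated_samples
  groups <- unique(as.character(cl[[group_var]]))
  by_group <- purrr::map_dfr(groups, function(g) {
    sub <- cl[cl[[group_var]] == g, ]
    n <- nrow(sub)
    k <- sum(sub$mutated)
    tibble(group = g, n_mutated = k, n = n,
           percent = round_half_up(100 * k / n, 1))
  })
  chisq <- NA
  if (nrow(by_group) >= 2 && sum(by_group$n_mutated) > 0 &&
      sum(by_group$n - by_group$n_mutated) > 0) {
    tab <- rbind(mutated = by_group$n_mutated,
                 unmutated = by_group$n - by_group$n_mutated)
    colnames(tab) <- by_group$group
    chisq <- chisq_test_table(tab)
  }
  list(by_group = by_group, chisq = chisq)
}

#' Pairwise rank-sum comparison of TMB between groups
#'
#' Two-sided Wilcoxon rank-sum test of TMB between each pair of clinical
#' groups (normal-approximation p-values, so ties are handled). Groups with
#' no samples are excluded; pairs where either group has a single sample are
#' reported with `p_value = NA`.
#'
#' @param tmb Result of [compute_tmb()].
#' @param clinical Tibble with `sample_id` and the grouping column.
#' @param group_var Name of the grouping column.
#' @return Tibble of `group_a`, `group_b`, `p_value`.
#' @export
compare_tmb_groups <- function(tmb, clinical, group_var = "stage") {
  df <- dplyr::inner_join(tmb, clinical[, c("sample_id", group_var)],
                          by = "sample_id")
  df <- df[!is.na(df[[group_var]]), ]
  groups <- unique(as.character(df[[group_var]]))
  if (length(groups) < 2) abort("Need >= 2 groups with samples.")
  combos <- utils::combn(groups, 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(j) {
    a <- df$tmb[df[[group_var]] == combos[1, j]]
    b <- df$tmb[df[[group_var]] == combos[2, j]]
    p <- if (length(a) < 2 || length(b) < 2) NA_real_ else {
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    }
    tibble(group_a = combos[1, j], group_b = combos[2, j], p_value = p)
  })
}
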