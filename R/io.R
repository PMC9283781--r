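#' Read and write the pipeline's tabular formats
#'
#' The pipeline exchanges four plain-text tables: a genes-by-samples TPM
#' matrix (TSV, first column `gene`, header row of sample IDs), a clinical
#' CSV (`patient_id`, `sample_id`, `stage`, optionally `radiology`, `time`,
#' `event`), a minimal MAF-like mutation TSV (`sample_id`, `gene`,
#' `variant_class`), and one-symbol-per-line gene lists. Readers validate on
#' load (non-negative TPM, no duplicate genes, known stage labels) and each
#' write/read pair round-trips.
#'
#' @param path File path.
#' @return `read_expression_tsv()`: a validated expression tibble.
#' @name tp_io
NULL

#' @rdname tp_io
#' @export
read_expression_tsv <- function(path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(expr)[1] <- "gene"
  check_expression(expr)
  expr
}

#' @rdname tp_io
#' @param expr Expression tibble to write.
#' @export
write_expression_tsv <- function(expr, path) {
  check_expression(expr)
  readr::write_tsv(expr, path)
  invisible(path)
}

#' @rdname tp_io
#' @export
read_clinical_csv <- function(path) {
  cl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "stage") %in% names(cl))) {
    abort("Clinical file must have `sample_id` and `stage` columns.")
  }
  as_stage(cl$stage)  # validates labels
  if ("event" %in% names(cl)) {
    bad <- !is.na(cl$event) & !cl$event %in% c(0, 1)
    if (any(bad)) abort("`event` must be 0/1 (or missing).")
  }
  cl
}

#' @rdname tp_io
#' @param clinical Clinical tibble to write.
#' @export
write_clinical_csv <- function(clinical, path) {
  readr::write_csv(clinical, path)
  invisible(path)
}

#' @rdname tp_io
#' @export
read_mutations_tsv <- function(path) {
  mut <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "gene", "variant_class")
  if (!all(need %in% names(mut))) {
    abort(paste0("Mutation file must have columns: ", paste(need, collapse = ", ")))
  }
  mut
}

#' @rdname tp_io
#' @param mutations Mutation tibble to write.
#' @export
write_mutations_tsv <- function(mutations, path) {
  readr::write_tsv(mutations, path)
  invisible(path)
}

#' @rdname tp_io
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Default immune-related gene list shipped with the package
#'
#' A compact stand-in for an a-priori immune-related gene list: the eight
#' published immune-signature genes plus common immune/endothelial markers.
#' Users should substitute their own list via [read_gene_list()] for real
#' analyses.
#'
#' @return Character vector of gene symbols.
#' @export
default_immune_genes <- function() {
  read_gene_list(system.file("extdata", "immune_genes.txt", package = "tpindex"))
}
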