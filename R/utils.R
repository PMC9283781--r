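#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Canonical stage and radiology vocabularies; gene symbols are case-sensitive
# exact strings and no alias resolution is attempted.
STAGES <- c("normal", "AIS", "MIA", "LUAD")
TRANSITIONS <- c("normal_vs_AIS", "AIS_vs_MIA", "MIA_vs_LUAD")
RADIOLOGY <- c("pure_GGO", "subsolid", "solid")

#' Stage and transition vocabularies
#'
#' The four ordered pathological stages (`normal < AIS < MIA < LUAD`), the
#' three adjacent-stage transitions between them, and the three radiological
#' classes used throughout the package.
#'
#' @return A character vector.
#' @export
tp_stages <- function() STAGES

#' @rdname tp_stages
#' @export
tp_transitions <- function() TRANSITIONS

#' @rdname tp_stages
#' @export
tp_radiology_classes <- function() RADIOLOGY

as_stage <- function(x) {
  bad <- setdiff(unique(as.character(x)), STAGES)
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown stage label(s): ", paste(bad, collapse = ", "),
      ". Stages must be one of: ", paste(STAGES, collapse = ", ")
    ))
  }
  factor(as.character(x), levels = STAGES, ordered = TRUE)
}

#' Round half away from zero
#'
#' Decimal rounding with halves going up (`0.05 -> 0.1`), the convention used
#' for printed cohort percentages; base `round()` rounds halves to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @export
#' @examples
#' round_half_up(95.65, 1)  # 95.7, where round() gives 95.6
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Validate a genes-x-samples expression tibble: first column `gene`, then one
# numeric column per sample. Returns invisibly; errors are user-facing.
check_expression <- function(expr) {
  if (!is.data.frame(expr) || ncol(expr) < 2) {
    abort("`expr` must be a data frame with a `gene` column plus >= 1 sample column.")
  }
  if (names(expr)[1] != "gene") {
    abort("The first column of `expr` must be named `gene`.")
  }
  if (anyDuplicated(expr$gene)) {
    dup <- unique(expr$gene[duplicated(expr$gene)])
    abort(paste0("Duplicate gene symbol(s): ", paste(utils::head(dup, 5), collapse = ", ")))
  }
  mat <- expr[-1]
  if (!all(vapply(mat, is.numeric, logical(1)))) {
    abort("All sample columns of `expr` must be numeric TPM values.")
  }
  if (any(vapply(mat, function(col) any(col < 0, na.rm = TRUE), logical(1)))) {
    abort("TPM values must be non-negative.")
  }
  invisible(expr)
}

# Expression tibble -> numeric matrix with gene rownames.
expr_matrix <- function(expr) {
  check_expression(expr)
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$gene
  storage.mode(m) <- "double"
  m
}

# Map sample IDs (expression columns) to stages via the clinical table.
stage_lookup <- function(expr, clinical) {
  samples <- setdiff(names(expr), "gene")
  if (!all(c("sample_id", "stage") %in% names(clinical))) {
    abort("`clinical` must contain `sample_id` and `stage` columns.")
  }
  missing <- setdiff(samples, clinical$sample_id)
  if (length(missing) > 0) {
    abort(paste0(
      "Samples in `expr` missing from `clinical`: ",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  st <- as_stage(clinical$stage[match(samples, clinical$sample_id)])
  names(st) <- samples
  st
}
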