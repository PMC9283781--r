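test_that("low-expression filter keeps mean TPM >= 1 with an inclusive boundary", {
  expr <- tibble::tibble(
    gene = c("AT_ONE", "BELOW", "ABOVE"),
    S1 = c(1, 0.5, 10), S2 = c(1, 0.5, 20)
  )
  kept <- filter_low_expression(expr)
  expect_true("AT_ONE" %in% kept)   # boundary inclusive: "filtered out < 1.0"
  expect_false("BELOW" %in% kept)
  expect_true("ABOVE" %in% kept)

  # random matrix: retained set equals a brute-force row-mean recomputation
  set.seed(5)
  m <- matrix(rexp(200, rate = 1), nrow = 20,
              dimnames = list(paste0("G", 1:20), paste0("S", 1:10)))
  rexpr <- dplyr::bind_cols(tibble::tibble(gene = rownames(m)), tibble::as_tibble(m))
  brute <- rownames(m)[apply(m, 1, function(r) sum(r) / length(r)) >= 1]
  expect_setequal(filter_low_expression(rexpr), brute)

  expect_error(filter_low_expression(rexpr[0, ]), "empty")
})

test_that("signature selection honours patterns, the immune list and the filter", {
  cohort <- simulate_cohort(sim_config(n_genes_per_pattern = 5, n_null_genes = 20,
                                       seed = 51))
  pats <- assign_patterns(cohort$expression, cohort$clinical)
  retained <- filter_low_expression(cohort$expression)
  sigs <- select_signatures(pats, retained, cohort$immune_genes)
  p1 <- cohort$truth$gene[cohort$truth$pattern == "1"]
  p78 <- cohort$truth$gene[cohort$truth$pattern %in% c("7", "8")]
  expect_setequal(sigs$tumor_genes, intersect(p1, retained))
  expect_setequal(sigs$immune_genes, intersect(p78, retained))
  expect_equal(sigs$provenance, "de_novo")

  # pattern8_only mode drops the pattern-7 genes
  sig8 <- select_signatures(pats, retained, cohort$immune_genes,
                            mode = "pattern8_only")
  p8 <- cohort$truth$gene[cohort$truth$pattern == "8"]
  expect_setequal(sig8$immune_genes, intersect(p8, retained))

  # filter precedence: an immune-listed pattern-8 gene below TPM 1 is excluded
  low_gene <- p8[1]
  expr_low <- cohort$expression
  expr_low[expr_low$gene == low_gene, -1] <- 0.5
  pats_low <- assign_patterns(expr_low, cohort$clinical)
  retained_low <- filter_low_expression(expr_low)
  sigs_low <- select_signatures(pats_low, retained_low, cohort$immune_genes)
  expect_false(low_gene %in% sigs_low$immune_genes)

  # no pattern-1 genes -> selection error with diagnostic counts
  no_p1 <- pats[!pats$gene %in% p1, ]
  expect_error(select_signatures(no_p1, retained, cohort$immune_genes), "empty")
  expect_error(select_signatures(pats, retained, character(0)), "non-empty")
})

test_that("index algebra is exact", {
  sig <- published_signatures()
  genes <- c(sig$tumor_genes, sig$immune_genes)

  # all signature TPM = 1, pseudocount 0: all indices are 0
  expr1 <- dplyr::bind_cols(tibble::tibble(gene = genes),
                            tibble::tibble(S1 = rep(1, 12)))
  idx1 <- compute_indices(expr1, sig, pseudocount = 0)
  expect_equal(idx1$tumor_index, 0)
  expect_equal(idx1$immune_index, 0)
  expect_equal(idx1$tp_index, 0)

  # tumor TPM 4, immune TPM 2, pseudocount 0: tp = 2 - 1 = 1
  expr2 <- dplyr::bind_cols(tibble::tibble(gene = genes),
                            tibble::tibble(S1 = c(rep(4, 4), rep(2, 8))))
  idx2 <- compute_indices(expr2, sig, pseudocount = 0)
  expect_equal(idx2$tumor_index, 2)
  expect_equal(idx2$immune_index, 1)
  expect_equal(idx2$tp_index, 1)

  # missing signature gene named in the error
  expect_error(compute_indices(expr2[-1, ], sig), "BCL2L15")
  # pseudocount 0 with a zero TPM is a domain error
  expr0 <- expr2
  expr0$S1[1] <- 0
  expect_error(compute_indices(expr0, sig, pseudocount = 0), "strictly positive")
})

test_that("indices match a brute-force mean-of-logs oracle", {
  set.seed(61)
  sig <- published_signatures()
  genes <- c(sig$tumor_genes, sig$immune_genes, paste0("OTHER", 1:5))
  m <- matrix(rexp(length(genes) * 6, 0.2), nrow = length(genes),
              dimnames = list(genes, paste0("S", 1:6)))
  expr <- dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m))
  idx <- compute_indices(expr, sig, pseudocount = 1)
  for (s in colnames(m)) {
    tum <- mean(vapply(sig$tumor_genes, function(g) log2(m[g, s] + 1), numeric(1)))
    imm <- mean(vapply(sig$immune_genes, function(g) log2(m[g, s] + 1), numeric(1)))
    row <- idx[idx$sample_id == s, ]
    expect_equal(row$tumor_index, tum, tolerance = 1e-12)
    expect_equal(row$immune_index, imm, tolerance = 1e-12)
    expect_equal(row$tp_index, tum - imm, tolerance = 1e-12)
  }
})

test_that("tp_index is exactly tumor minus immune and equivariant under doubling", {
  set.seed(62)
  sig <- published_signatures()
  genes <- c(sig$tumor_genes, sig$immune_genes)
  m <- matrix(rexp(12 * 8, 0.1) + 0.01, nrow = 12,
              dimnames = list(genes, paste0("S", 1:8)))
  expr <- dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m))
  idx <- compute_indices(expr, sig, pseudocount = 0)
  expect_equal(idx$tp_index, idx$tumor_index - idx$immune_index, tolerance = 0)

  # doubling every tumor-gene TPM adds exactly 1 (pseudocount 0)
  m2 <- m
  m2[sig$tumor_genes, ] <- 2 * m2[sig$tumor_genes, ]
  expr_t2 <- dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m2))
  idx_t2 <- compute_indices(expr_t2, sig, pseudocount = 0)
  expect_equal(idx_t2$tumor_index, idx$tumor_index + 1, tolerance = 1e-12)
  expect_equal(idx_t2$tp_index, idx$tp_index + 1, tolerance = 1e-12)

  # doubling every immune-gene TPM subtracts exactly 1 from tp_index
  m3 <- m
  m3[sig$immune_genes, ] <- 2 * m3[sig$immune_genes, ]
  expr_i2 <- dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m3))
  idx_i2 <- compute_indices(expr_i2, sig, pseudocount = 0)
  expect_equal(idx_i2$tp_index, idx$tp_index - 1, tolerance = 1e-12)

  # permutation invariance over gene and sample order
  perm <- expr[sample(nrow(expr)), c(1, 1 + sample(8))]
  idx_perm <- compute_indices(perm, sig, pseudocount = 0)
  reord <- idx_perm[match(idx$sample_id, idx_perm$sample_id), ]
  expect_equal(reord$tp_index, idx$tp_index, tolerance = 1e-12)
})

test_that("tp_index separates normal from tumor on a constructed cohort", {
  # tumor-signature genes start low and rise; immune genes start high and fall
  cfg <- sim_config(
    n_genes_per_pattern = c(4, 0, 0, 0, 0, 0, 2, 6, 0, 0, 0, 0),
    n_null_genes = 10,
    base_by_pattern = c("1" = 1, "7" = 8, "8" = 8),
    step_log2fc = 2, noise_sd = 0.4, seed = 71
  )
  cohort <- simulate_cohort(cfg)
  pats <- assign_patterns(cohort$expression, cohort$clinical)
  retained <- filter_low_expression(cohort$expression)
  sigs <- select_signatures(pats, retained, cohort$immune_genes)
  idx <- compute_indices(cohort$expression, sigs)
  stage_of <- cohort$clinical$stage[match(idx$sample_id, cohort$clinical$sample_id)]
  expect_true(all(idx$tp_index[stage_of == "normal"] < 0))
  expect_true(all(idx$tp_index[stage_of == "LUAD"] > 0))
})

test_that("stage comparison reports medians and rank tests sensibly", {
  cfg <- sim_config(
    n_genes_per_pattern = c(4, 0, 0, 0, 0, 0, 2, 6, 0, 0, 0, 0),
    n_null_genes = 5,
    base_by_pattern = c("1" = 1, "7" = 8, "8" = 8),
    step_log2fc = 2, noise_sd = 0.4, seed = 72
  )
  cohort <- simulate_cohort(cfg)
  pats <- assign_patterns(cohort$expression, cohort$clinical)
  sigs <- select_signatures(pats, filter_low_expression(cohort$expression),
                            cohort$immune_genes)
  idx <- compute_indices(cohort$expression, sigs)
  cmp <- compare_index_by_stage(idx, cohort$clinical)
  meds <- cmp$by_stage$median[match(tp_stages(), as.character(cmp$by_stage$stage))]
  # construction guarantees strictly increasing stage medians
  expect_true(all(diff(meds) > 0))
  expect_equal(nrow(cmp$adjacent_tests), 3)
  expect_true(all(cmp$adjacent_tests$p_value < 0.05))

  # identical stage distributions: p ~ 1
  idx_flat <- tibble::tibble(sample_id = paste0("S", 1:40),
                             tumor_index = 0, immune_index = 0,
                             tp_index = rep(c(1, 2, 3, 4, 5), 8))
  cl_flat <- tibble::tibble(sample_id = paste0("S", 1:40),
                            stage = rep(c("normal", "AIS"), each = 20))
  cmp_flat <- suppressWarnings(compare_index_by_stage(idx_flat, cl_flat))
  expect_gt(cmp_flat$adjacent_tests$p_value[1], 0.99)

  # single sample per stage: medians are the values, tests not applicable
  idx1 <- tibble::tibble(sample_id = c("A", "B"), tumor_index = 0,
                         immune_index = 0, tp_index = c(1, 2))
  cl1 <- tibble::tibble(sample_id = c("A", "B"), stage = c("normal", "AIS"))
  expect_warning(compare_index_by_stage(idx1, cl1), "excluded")
  cmp1 <- suppressWarnings(compare_index_by_stage(idx1, cl1))
  expect_equal(cmp1$by_stage$median, c(1, 2))
  expect_true(all(is.na(cmp1$adjacent_tests$p_value)))
})
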