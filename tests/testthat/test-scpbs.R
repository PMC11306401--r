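# scPBS stages: per-cell gene sets, per-cell burden coefficients,
# trait-relevant gene ranking and the rvTRS.

small_linked <- function(seed = 91) {
  simulate_linked_dataset(n_cases = 150, n_controls = 150, n_genes = 200,
                          n_cell_types = 3, cells_per_type = 30,
                          marker_genes_per_type = 20, causal_or = 8,
                          seed = seed)
}

test_that("per-cell gene sets are deterministic functions of expression", {
  counts <- rbind(gB = c(4, 4, 9), gA = c(4, 4, 0), gC = c(2, 2, 1),
                  gZ = c(0, 0, 1))
  colnames(counts) <- paste0("c", 1:3)
  meta <- data.frame(cell = paste0("c", 1:3), type = c("t1", "t1", "t2"))
  expr <- expression_data(counts, meta)
  sp <- tpm_and_specificity(expr)
  sets <- per_cell_gene_sets(expr, sp, fraction = 0.4, min_genes = 2)
  # identical cells of the same type get identical sets
  expect_identical(sets[["c1"]], sets[["c2"]])
  # a zero-expression gene is never selected
  expect_false("gZ" %in% sets[["c1"]])
  # set size = ceiling(fraction * #expressed genes in the cell)
  expect_length(sets[["c1"]], ceiling(0.4 * 3))
})

test_that("cells with too few expressed genes are skipped with a warning", {
  counts <- rbind(g1 = c(5, 0), g2 = c(3, 1), g3 = c(2, 0))
  colnames(counts) <- c("rich", "poor")
  meta <- data.frame(cell = c("rich", "poor"), type = c("t1", "t2"))
  expr <- expression_data(counts, meta)
  sp <- tpm_and_specificity(expr)
  expect_warning(sets <- per_cell_gene_sets(expr, sp, min_genes = 3),
                 "skipped")
  expect_named(sets, "rich")
})

test_that("per-cell burden scores flag carrier-free sets and rank causal cells", {
  sim <- small_linked()
  expr <- normalize_expression(sim$expr)
  sp <- tpm_and_specificity(expr)
  sets <- per_cell_gene_sets(expr, sp)
  # a synthetic carrier-free set
  sets[["__null__"]] <- "gene0200"
  carriers <- sim$cohort$gene_carriers
  carriers["gene0200", ] <- 0
  scores <- per_cell_burden_score(sets, carriers, sim$cohort$design)
  expect_true(scores$null_flag[scores$cell == "__null__"])
  expect_identical(scores$scpbs[scores$cell == "__null__"], 0)

  meta <- expr$cell_meta
  causal_cells <- meta$cell[meta$type == sim$truth$causal_types]
  in_causal <- scores$cell %in% causal_cells
  expect_gt(median(scores$scpbs[in_causal]),
            median(scores$scpbs[!in_causal & scores$cell != "__null__"]))
})

test_that("permuted phenotypes give scPBS centred at zero", {
  # cells within one permutation share the cohort, so their scores are
  # correlated; average over independent label permutations instead
  sim <- small_linked(seed = 92)
  expr <- normalize_expression(sim$expr)
  sets <- per_cell_gene_sets(expr, tpm_and_specificity(expr))
  sub <- sets[seq(1, length(sets), by = 6)]
  means <- vapply(1:6, function(k) {
    design <- sim$cohort$design
    design$status <- withr::with_seed(92 + k, sample(design$status))
    scores <- per_cell_burden_score(sub, sim$cohort$gene_carriers, design)
    mean(scores$scpbs[!scores$null_flag])
  }, numeric(1))
  expect_gt(t.test(means)$p.value, 0.01)
})

test_that("trait-relevant genes are ranked by Pearson correlation", {
  set.seed(93)
  n_cells <- 30
  scpbs <- rnorm(n_cells)
  base <- matrix(rpois(20 * n_cells, 5), 20, n_cells,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 sprintf("c%02d", 1:n_cells)))
  expr <- expression_data(base, data.frame(cell = colnames(base),
                                           type = rep(c("a", "b"), 15)))
  expr <- normalize_expression(expr)
  # plant a gene whose normalized expression is an affine image of scpbs
  expr$normalized["g01", ] <- 2 * scpbs + 5
  expr$normalized["g02", ] <- 3      # constant: must be excluded
  scores <- data.frame(cell = colnames(base), scpbs = scpbs,
                       null_flag = FALSE)
  tr <- trait_relevant_genes(scores, expr, fraction = 0.10)
  expect_identical(names(tr$pcc)[1], "g01")
  expect_equal(unname(tr$pcc["g01"]), 1, tolerance = 1e-12)
  expect_false("g02" %in% names(tr$pcc))
  expect_length(tr$trait_genes, ceiling(0.10 * length(tr$pcc)))
  # sign flip reverses the ranking
  scores2 <- scores; scores2$scpbs <- -scores$scpbs
  tr2 <- trait_relevant_genes(scores2, expr, fraction = 0.10)
  expect_identical(names(tr2$pcc), rev(names(tr$pcc)))
  # too few usable cells is an error
  scores3 <- scores; scores3$null_flag <- TRUE
  expect_error(trait_relevant_genes(scores3, expr), "fewer than 3")
})

test_that("rvTRS is zero for a constant expression matrix", {
  counts <- matrix(5, 40, 12, dimnames = list(sprintf("g%02d", 1:40),
                                              sprintf("c%02d", 1:12)))
  meta <- data.frame(cell = colnames(counts), type = rep(c("a", "b"), 6))
  expr <- expression_data(counts, meta)
  rv <- suppressWarnings(
    rvtrs_score(expr, c("g01", "g05"), n_bins = 4, n_ctrl = 5, seed = 1))
  expect_true(all(abs(rv) < 1e-12))
})

test_that("rvTRS has mean ~ 0 under random trait-gene draws", {
  sim <- make_tiny_expression(seed = 94)
  expr <- normalize_expression(sim$expr)
  genes <- rownames(expr$counts)
  set.seed(94)
  draws <- replicate(200, {
    tg <- sample(genes, 6)
    mean(suppressWarnings(
      rvtrs_score(expr, tg, n_bins = 5, n_ctrl = 20,
                  seed = sample.int(1e6, 1))))
  })
  expect_lt(abs(mean(draws)), 3 * sd(draws) / sqrt(length(draws)) + 0.01)
})

test_that("rvTRS is deterministic given the seed and errors on unknown genes", {
  sim <- make_tiny_expression(seed = 95)
  tg <- sim$truth$markers[[1]][1:3]
  r1 <- suppressWarnings(rvtrs_score(sim$expr, tg, n_bins = 5, n_ctrl = 10,
                                     seed = 9))
  r2 <- suppressWarnings(rvtrs_score(sim$expr, tg, n_bins = 5, n_ctrl = 10,
                                     seed = 9))
  expect_identical(r1, r2)
  expect_error(rvtrs_score(sim$expr, "nope", seed = 1), "absent")
  expect_error(rvtrs_score(sim$expr, tg), "seed")
})

test_that("run_scpbs is reproducible and invariant to cell relabelling", {
  sim <- small_linked(seed = 96)
  res1 <- suppressWarnings(run_scpbs(sim$cohort$gene_carriers,
                                     sim$cohort$design, sim$expr, seed = 3))
  res2 <- suppressWarnings(run_scpbs(sim$cohort$gene_carriers,
                                     sim$cohort$design, sim$expr, seed = 3))
  expect_identical(res1$cells, res2$cells)
  expect_identical(res1$trait_genes, res2$trait_genes)

  # relabel cell ids: scores follow the cells, types keep their medians
  expr2 <- sim$expr
  relabel <- paste0("x_", expr2$cell_meta$cell)
  expr2$cell_meta$cell <- relabel
  colnames(expr2$counts) <- relabel
  res3 <- suppressWarnings(run_scpbs(sim$cohort$gene_carriers,
                                     sim$cohort$design, expr2, seed = 3))
  expect_equal(res3$type_summary$median_rvtrs,
               res1$type_summary$median_rvtrs, tolerance = 1e-12)

  # scpbs invariant to sample ordering
  perm <- sample(nrow(sim$cohort$design))
  design_p <- sim$cohort$design[perm, ]
  res4 <- suppressWarnings(run_scpbs(sim$cohort$gene_carriers, design_p,
                                     sim$expr, seed = 3))
  expect_equal(res4$cells$scpbs, res1$cells$scpbs, tolerance = 1e-8)
})

test_that("celltype burden enrichment flags marker sets with the signal", {
  sim <- small_linked(seed = 97)
  mk <- sim$truth$markers
  res <- celltype_burden_enrichment(mk, sim$cohort$gene_carriers,
                                    sim$cohort$design, test = "fet")
  expect_identical(res$unit[which.min(res$p)], sim$truth$causal_types)
  # a marker set with no carried variants is null-flagged
  carriers0 <- sim$cohort$gene_carriers
  carriers0[mk[["type2"]], ] <- 0
  res0 <- celltype_burden_enrichment(mk["type2"], carriers0,
                                     sim$cohort$design, test = "fet")
  expect_true(res0$null_flag)
})
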