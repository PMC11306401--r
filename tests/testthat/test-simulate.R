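# Synthetic-data generators: determinism, null behaviour and planted-effect
# recovery.

test_that("generators are pure functions of the seed", {
  s1 <- simulate_cohort(n_cases = 50, n_controls = 50, n_genes = 30, seed = 1)
  s2 <- simulate_cohort(n_cases = 50, n_controls = 50, n_genes = 30, seed = 1)
  expect_identical(s1$gene_carriers, s2$gene_carriers)
  expect_identical(s1$design, s2$design)
  expect_identical(s1$annotations, s2$annotations)

  e1 <- simulate_expression(n_genes = 40, n_cell_types = 2,
                            cells_per_type = 10, marker_genes_per_type = 4,
                            seed = 2)
  e2 <- simulate_expression(n_genes = 40, n_cell_types = 2,
                            cells_per_type = 10, marker_genes_per_type = 4,
                            seed = 2)
  expect_identical(as.matrix(e1$expr$counts), as.matrix(e2$expr$counts))
  expect_error(simulate_cohort(n_cases = 10, n_controls = 10, n_genes = 5),
               "seed")
})

test_that("a null cohort has matched case/control carrier rates", {
  sim <- simulate_cohort(n_cases = 400, n_controls = 400, n_genes = 150,
                         causal_or = 1, seed = 101)
  is_case <- sim$design$status == "case"
  case_rate <- mean(sim$gene_carriers[, is_case])
  ctrl_rate <- mean(sim$gene_carriers[, !is_case])
  n <- 150 * 400
  se <- sqrt(0.01 * 0.99 * 2 / n)
  expect_lt(abs(case_rate - ctrl_rate), 4 * se)
})

test_that("the planted odds ratio is recovered by the carrier FET", {
  sim <- simulate_cohort(n_cases = 449, n_controls = 9606, n_genes = 20,
                         baseline_carrier_rate = 0.001,
                         causal_genes = "gene0001", causal_or = 15,
                         seed = 102)
  is_case <- sim$design$status == "case"
  a <- sum(sim$gene_carriers["gene0001", is_case])
  cc <- sum(sim$gene_carriers["gene0001", !is_case])
  ft <- fisher_exact_2x2(a, 449 - a, cc, 9606 - cc)
  # planted value inside the realised 95% CI
  expect_gt(15, ft$ci[1])
  expect_lt(15, ft$ci[2])
})

test_that("annotations are qualifying PTVs in the package's TSV dialect", {
  sim <- simulate_cohort(n_cases = 30, n_controls = 30, n_genes = 10,
                         seed = 103)
  ann <- sim$annotations
  expect_true(all(ann$consequence %in% PTV_CONSEQUENCES))
  expect_identical(unique(classify_consequence(ann$consequence)), "PTV")
  expect_true(all(ann$af_gnomad < 0.005))
  expect_true(all(ann$loftee == "HC" & ann$vqsr_pass & !ann$low_complexity))
  # carrier matrix rebuilt from materialised variants matches the simulation
  gm <- ann[, c("variant_id", "gene")]
  cm <- build_carrier_matrix(as.matrix(sim$genotypes), gm)
  expect_identical(unname(cm[rownames(sim$gene_carriers), ]),
                   unname(sim$gene_carriers + 0))
})

test_that("marker recovery tracks the planted fold change", {
  sim0 <- simulate_expression(n_genes = 100, n_cell_types = 2,
                              cells_per_type = 40, marker_genes_per_type = 10,
                              marker_logfc = 0, seed = 104)
  mk0 <- suppressWarnings(celltype_marker_genes(sim0$expr))
  found0 <- length(intersect(attr(mk0, "markers")[["type1"]],
                             sim0$truth$markers[["type1"]]))
  sim2 <- simulate_expression(n_genes = 100, n_cell_types = 2,
                              cells_per_type = 40, marker_genes_per_type = 10,
                              marker_logfc = 2, seed = 104)
  mk2 <- celltype_marker_genes(sim2$expr)
  found2 <- length(intersect(attr(mk2, "markers")[["type1"]],
                             sim2$truth$markers[["type1"]]))
  expect_gte(found2, 9)     # >= 90% of planted markers recovered
  expect_lt(found0, found2)
})

test_that("the linked fixture plants enrichment in the causal type's markers", {
  sim <- simulate_linked_dataset(n_cases = 100, n_controls = 100,
                                 n_genes = 120, n_cell_types = 3,
                                 cells_per_type = 15,
                                 marker_genes_per_type = 10,
                                 causal_types = 2, seed = 105)
  expect_identical(sim$truth$causal_types, "type2")
  expect_identical(sim$truth$causal_genes, sim$truth$markers[["type2"]])
  expect_identical(sim$cohort$truth$causal_genes, sim$truth$causal_genes)
  # two designated causal types are both planted
  sim2 <- simulate_linked_dataset(n_cases = 60, n_controls = 60,
                                  n_genes = 120, n_cell_types = 3,
                                  cells_per_type = 15,
                                  marker_genes_per_type = 10,
                                  causal_types = c(1, 3), seed = 106)
  expect_setequal(sim2$truth$causal_genes,
                  unlist(sim2$truth$markers[c("type1", "type3")]))
})
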