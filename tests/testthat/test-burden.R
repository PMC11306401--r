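# Carrier matrices, unit burden tests, gene-set and collapsing scans,
# resampling nulls and genomic control.

test_that("carrier matrix reproduces the three-variant worked example", {
  fx <- make_kdelr3_fixture()
  cm <- build_carrier_matrix(fx$dosage, fx$gene_map)
  is_case <- fx$design$status == "case"
  expect_identical(sum(cm["KDELR3", is_case]), 8)
  expect_identical(sum(cm["KDELR3", !is_case]), 11)
  # count mode preserves allele sums
  cm2 <- build_carrier_matrix(fx$dosage, fx$gene_map, mode = "count")
  expect_identical(sum(cm2["KDELR3", ]), 19)
})

test_that("indicator coding collapses multi-allele carriers to presence", {
  dosage <- rbind(v1 = c(2L, 0L), v2 = c(1L, 1L))
  colnames(dosage) <- c("s1", "s2")
  gm <- data.frame(variant_id = c("v1", "v2"), gene = "G")
  cm <- build_carrier_matrix(dosage, gm)
  expect_identical(unname(cm["G", ]), c(1, 1))
  cmc <- build_carrier_matrix(dosage, gm, mode = "count")
  expect_identical(unname(cmc["G", ]), c(3, 1))
})

test_that("missing genotypes count as non-carrier and are logged", {
  dosage <- rbind(v1 = c(NA, 0L), v2 = c(1L, NA))
  colnames(dosage) <- c("s1", "s2")
  gm <- data.frame(variant_id = c("v1", "v2"), gene = "G")
  expect_message(cm <- build_carrier_matrix(dosage, gm), "2 missing")
  expect_identical(unname(cm["G", ]), c(1, 0))
  expect_warning(
    build_carrier_matrix(dosage, gm, units = list(empty = "NOPE")),
    "no variants")
  expect_error(build_carrier_matrix(unname(dosage), gm), "row names")
})

test_that("FET and Firth burden tests agree in direction", {
  set.seed(71)
  design <- make_design(200)
  carrier <- rbinom(200, 1, ifelse(design$status == "case", 0.3, 0.1))
  names(carrier) <- design$sample_id
  fet <- unit_burden_test(carrier, design, test = "fet")
  firth <- unit_burden_test(carrier, design, test = "firth")
  expect_gt(fet$or, 1)
  expect_gt(firth$or, 1)
  expect_identical(fet$n_case_carriers, firth$n_case_carriers)
})

test_that("zero carriers yield a flagged null result, not an error", {
  design <- make_design(50)
  r <- unit_burden_test(setNames(rep(0, 50), design$sample_id), design)
  expect_true(r$null_flag)
  expect_identical(r$p, 1)
})

test_that("gene-set scan applies BH across the collection", {
  set.seed(72)
  sim <- simulate_cohort(n_cases = 150, n_controls = 150, n_genes = 60,
                         causal_genes = sprintf("gene%04d", 1:10),
                         causal_or = 8, seed = 72)
  sets <- list(planted = sprintf("gene%04d", 1:10),
               decoy1 = sprintf("gene%04d", 21:30),
               decoy2 = sprintf("gene%04d", 31:40),
               planted_copy = sprintf("gene%04d", 1:10))
  scan <- geneset_scan(sets, sim$gene_carriers, sim$design)
  expect_identical(scan$unit[1], "planted")
  # duplicated set gets an identical p
  expect_equal(scan$p[scan$unit == "planted"],
               scan$p[scan$unit == "planted_copy"], tolerance = 1e-14)
  # BH output is monotone non-decreasing in rank-ordered p
  expect_true(all(diff(scan$fdr[order(scan$p)]) >= -1e-14))
  # single-set collection: FDR equals p
  one <- geneset_scan(sets["decoy1"], sim$gene_carriers, sim$design)
  expect_equal(one$fdr, one$p)
  expect_warning(geneset_scan(list(a = character(0), b = "gene0001"),
                              sim$gene_carriers, sim$design), "empty")
})

test_that("length-matched empirical p respects its bounds and seed", {
  set.seed(73)
  sim <- simulate_cohort(n_cases = 150, n_controls = 150, n_genes = 80,
                         causal_genes = sprintf("gene%04d", 1:8),
                         causal_or = 10, seed = 73)
  en <- length_matched_empirical_p(sprintf("gene%04d", 1:8),
                                   sim$gene_lengths, sim$gene_carriers,
                                   sim$design, B = 99, seed = 7)
  expect_gte(en$empirical_p, 1 / 100)
  expect_lte(en$empirical_p, 1)
  # strongly enriched set should beat (nearly) all random draws
  expect_lte(en$empirical_p, 5 / 100)
  en2 <- length_matched_empirical_p(sprintf("gene%04d", 1:8),
                                    sim$gene_lengths, sim$gene_carriers,
                                    sim$design, B = 99, seed = 7)
  expect_identical(en$resampled, en2$resampled)
  # a null set sits inside the resampled distribution
  en_null <- length_matched_empirical_p(sprintf("gene%04d", 41:48),
                                        sim$gene_lengths, sim$gene_carriers,
                                        sim$design, B = 99, seed = 7)
  expect_gt(en_null$empirical_p, 0.05)
})

test_that("collapsing scan computes the Bonferroni threshold and expected p", {
  set.seed(74)
  sim <- simulate_cohort(n_cases = 100, n_controls = 100, n_genes = 40,
                         seed = 74)
  out <- collapsing_scan(sim$gene_carriers, sim$design, B_perm = 50, seed = 5)
  expect_equal(out$bonferroni, 0.05 / 40)
  expect_identical(out$n_genes, 40L)
  expect_length(out$expected_p, 40)
  expect_true(!is.unsorted(out$expected_p))
  # null cohort: observed sorted p within a generous permutation envelope
  obs <- sort(out$results$p)
  expect_lt(max(abs(obs - out$expected_p)), 0.5)
  # a gene with zero carriers in both groups has p = 1
  zero <- matrix(0, 1, 200,
                 dimnames = list("dead", sim$design$sample_id))
  out0 <- collapsing_scan(zero, sim$design, B_perm = 0)
  expect_identical(out0$results$p, 1)
})

test_that("genomic control lambda is calibrated and halves inflated stats", {
  withr::with_seed(75, {
    gc <- genomic_control_lambda(p = runif(1e5))
    expect_equal(gc$lambda, 1, tolerance = 0.02)
  })
  chisq <- rep(qchisq(0.5, 1), 20)
  expect_equal(genomic_control_lambda(chisq = chisq)$lambda, 1)
  infl <- 2 * qchisq(runif(100, 0.01, 0.99), 1)
  gc2 <- genomic_control_lambda(chisq = infl)
  expect_equal(gc2$chisq_adj, infl / gc2$lambda)
  # deflation is never applied
  defl <- 0.5 * qchisq(seq(0.05, 0.95, length.out = 50), 1)
  expect_identical(genomic_control_lambda(chisq = defl)$chisq_adj, defl)
  expect_error(genomic_control_lambda(chisq = 1:5), "at least 10")
  expect_error(genomic_control_lambda(), "no statistics")
})
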