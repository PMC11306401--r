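# Small fixtures built in code and shared across test files.

# Minimal cohort design: n/2 cases then n/2 controls, with the full covariate
# set used by the Firth models.
make_design <- function(n, seed = 1) {
  withr::with_seed(seed, {
    data.frame(
      sample_id = sprintf("S%05d", seq_len(n)),
      status = rep(c("case", "control"), each = n / 2),
      sex = rbinom(n, 1, 0.5),
      matrix(rnorm(n * 10), n, 10,
             dimnames = list(NULL, paste0("PC", 1:10))),
      total_exome_count = rpois(n, 100),
      stringsAsFactors = FALSE
    )
  })
}

# Dosage matrix reproducing the three-variant carrier pattern of the worked
# collapsing example: case allele counts 6, 1, 1 and control counts 6, 3, 2,
# one variant per carrier, in a cohort of 449 cases and 9606 controls.
make_kdelr3_fixture <- function() {
  n_case <- 449; n_ctrl <- 9606
  n <- n_case + n_ctrl
  samples <- sprintf("S%05d", seq_len(n))
  dosage <- matrix(0L, 3, n,
                   dimnames = list(c("chr22-38875700-CT-C",
                                     "chr22-38875736-TAC-T",
                                     "chr22-38877305-T-TA"),
                                   samples))
  # cases occupy columns 1..449; one qualifying allele per carrier
  dosage[1, 1:6] <- 1L
  dosage[2, 7] <- 1L
  dosage[3, 8] <- 1L
  ctrl <- n_case + seq_len(11)
  dosage[1, ctrl[1:6]] <- 1L
  dosage[2, ctrl[7:9]] <- 1L
  dosage[3, ctrl[10:11]] <- 1L
  design <- data.frame(
    sample_id = samples,
    status = rep(c("case", "control"), c(n_case, n_ctrl)),
    stringsAsFactors = FALSE
  )
  list(dosage = dosage,
       gene_map = data.frame(variant_id = rownames(dosage),
                             gene = "KDELR3", stringsAsFactors = FALSE),
       design = design)
}

# Tiny expression fixture with two well-separated types and known markers.
make_tiny_expression <- function(seed = 3, n_genes = 60, cells_per_type = 20) {
  simulate_expression(n_genes = n_genes, n_cell_types = 2,
                      cells_per_type = cells_per_type,
                      marker_genes_per_type = 5, marker_logfc = 2,
                      seed = seed)
}
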