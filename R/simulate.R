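# Synthetic-data generators: a case-control cohort with rare-PTV carrier
# enrichment planted in chosen genes, a multi-type scRNA-seq count matrix with
# planted markers, and the linked fixture coupling the two (causal genes = one
# type's markers) that the scPBS recovery properties are asserted on.

#' Simulate a case-control rare-PTV cohort
#'
#' Simulates carrier status per gene and sample: controls carry a qualifying
#' PTV in a gene with probability \code{baseline_carrier_rate}; for causal
#' genes the case carrier probability is obtained by scaling the baseline
#' odds by \code{causal_or}, so the planted odds ratio is the estimand
#' targeted by the carrier-level tests. Each carrier is materialised as one
#' synthetic heterozygous PTV drawn uniformly from the gene's
#' \code{variants_per_gene} variants, and annotations are emitted in the
#' package's TSV dialect (gnomAD-style reference frequencies below 0.005,
#' LOFTEE HC, VQSR pass). Covariates are sex ~ Bernoulli(0.5), PC1..10 ~
#' standard normal, and a Poisson total exome count.
#'
#' @param n_cases,n_controls cohort sizes, defaults 500/500.
#' @param n_genes number of genes, default 1000.
#' @param baseline_carrier_rate per-gene carrier probability in controls,
#'   default 0.01.
#' @param causal_genes character vector of genes carrying the planted
#'   enrichment (possibly empty).
#' @param causal_or planted carrier odds ratio for causal genes, default 5.
#' @param variants_per_gene synthetic qualifying variants per gene, default 3.
#' @param texc_lambda Poisson mean of the total exome count covariate,
#'   default 100.
#' @param seed RNG seed (required).
#' @return list with \code{genotypes} (sparse variant x sample dosage matrix),
#'   \code{annotations} (data frame), \code{design} (data frame),
#'   \code{gene_carriers} (gene x sample 0/1 matrix), \code{gene_lengths}
#'   (named vector) and \code{truth} (causal genes, planted OR, carrier
#'   probabilities).
#' @export
simulate_cohort <- function(n_cases = 500, n_controls = 500, n_genes = 1000,
                            baseline_carrier_rate = 0.01,
                            causal_genes = character(0), causal_or = 5,
                            variants_per_gene = 3, texc_lambda = 100, seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  stopifnot(causal_or >= 1, baseline_carrier_rate >= 0,
            baseline_carrier_rate <= 1)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  bad <- setdiff(causal_genes, genes)
  if (length(bad)) stop("causal gene(s) outside registry: ",
                        paste(utils::head(bad, 3), collapse = ", "),
                        call. = FALSE)
  p0 <- baseline_carrier_rate
  odds1 <- causal_or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  if (p1 > 1) stop("case carrier probability exceeds 1", call. = FALSE)

  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  n <- n_cases + n_controls
  samples <- sprintf("S%05d", seq_len(n))
  status <- rep(c(1L, 0L), c(n_cases, n_controls))
  p_gene <- matrix(p0, n_genes, n, dimnames = list(genes, samples))
  if (length(causal_genes)) p_gene[causal_genes, status == 1L] <- p1
  gene_carriers <- matrix(stats::rbinom(n_genes * n, 1, p_gene), n_genes, n,
                          dimnames = list(genes, samples))

  # materialise one heterozygous PTV per carrier
  n_var <- n_genes * variants_per_gene
  variant_ids <- sprintf("chr1-%d-A-T", 1000L + 10L * seq_len(n_var))
  var_gene <- rep(genes, each = variants_per_gene)
  carrier_idx <- which(gene_carriers == 1L, arr.ind = TRUE)
  var_offset <- (carrier_idx[, 1] - 1L) * variants_per_gene +
    sample.int(variants_per_gene, nrow(carrier_idx), replace = TRUE)
  genotypes <- Matrix::sparseMatrix(
    i = var_offset, j = carrier_idx[, 2], x = 1,
    dims = c(n_var, n), dimnames = list(variant_ids, samples))

  annotations <- data.frame(
    variant_id = variant_ids,
    gene = var_gene,
    consequence = sample(PTV_CONSEQUENCES, n_var, replace = TRUE),
    polyphen = NA_character_,
    sift = NA_character_,
    cadd_phred = round(stats::runif(n_var, 25, 50), 1),
    loftee = "HC",
    af_gnomad = round(stats::runif(n_var, 0, 0.004), 6),
    af_1kg = 0,
    af_esp = 0,
    low_complexity = FALSE,
    vqsr_pass = TRUE,
    stringsAsFactors = FALSE
  )

  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(samples, paste0("PC", 1:10)))
  design <- data.frame(
    sample_id = samples,
    status = ifelse(status == 1L, "case", "control"),
    sex = stats::rbinom(n, 1, 0.5),
    pcs,
    total_exome_count = stats::rpois(n, texc_lambda),
    stringsAsFactors = FALSE
  )

  gene_lengths <- stats::setNames(
    round(stats::rlnorm(n_genes, meanlog = log(1500), sdlog = 0.6)), genes)

  list(genotypes = genotypes, annotations = annotations, design = design,
       gene_carriers = gene_carriers, gene_lengths = gene_lengths,
       truth = list(causal_genes = causal_genes, causal_or = causal_or,
                    p_control = p0, p_case = p1))
}

#' Simulate a multi-type scRNA-seq count matrix with planted markers
#'
#' Negative-binomial counts with lognormal baseline means per gene. Each cell
#' type owns a disjoint block of \code{marker_genes_per_type} genes whose mean
#' is up-shifted by \code{exp(marker_logfc)} in that type. Cell-type labels
#' and a 2-D embedding (per-type Gaussian blobs on a circle) are emitted.
#'
#' @param n_genes number of genes, default 1000 (gene ids shared with
#'   \code{\link{simulate_cohort}}).
#' @param n_cell_types,cells_per_type dataset shape, defaults 5 and 200.
#' @param marker_genes_per_type planted markers per type, default 50.
#' @param marker_logfc natural-log fold change of markers in their home type,
#'   default 2.
#' @param base_meanlog,base_sdlog lognormal parameters of baseline gene means,
#'   defaults log(0.5) and 1.
#' @param nb_dispersion negative-binomial dispersion (NB size = 1/dispersion),
#'   default 0.5.
#' @param seed RNG seed (required).
#' @return list with \code{expr} (an \code{\link{expression_data}}) and
#'   \code{truth} (named list of planted marker genes per type).
#' @export
simulate_expression <- function(n_genes = 1000, n_cell_types = 5,
                                cells_per_type = 200,
                                marker_genes_per_type = 50, marker_logfc = 2,
                                base_meanlog = log(0.5), base_sdlog = 1,
                                nb_dispersion = 0.5, seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (n_cell_types * marker_genes_per_type > n_genes) {
    stop("not enough genes for the requested marker blocks", call. = FALSE)
  }
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  genes <- sprintf("gene%04d", seq_len(n_genes))
  types <- sprintf("type%d", seq_len(n_cell_types))
  n_cells <- n_cell_types * cells_per_type
  cell_type <- rep(types, each = cells_per_type)
  cells <- sprintf("cell%05d", seq_len(n_cells))

  markers <- stats::setNames(lapply(seq_len(n_cell_types), function(k) {
    genes[((k - 1) * marker_genes_per_type + 1):(k * marker_genes_per_type)]
  }), types)

  base_mu <- stats::rlnorm(n_genes, meanlog = base_meanlog, sdlog = base_sdlog)
  mu <- matrix(base_mu, n_genes, n_cells, dimnames = list(genes, cells))
  for (k in seq_len(n_cell_types)) {
    mu[markers[[k]], cell_type == types[k]] <-
      mu[markers[[k]], cell_type == types[k]] * exp(marker_logfc)
  }
  size <- if (nb_dispersion > 0) 1 / nb_dispersion else Inf
  counts <- matrix(
    if (is.finite(size)) stats::rnbinom(length(mu), mu = mu, size = size)
    else stats::rpois(length(mu), lambda = mu),
    n_genes, n_cells, dimnames = dimnames(mu))

  theta <- 2 * pi * (seq_len(n_cell_types) - 1) / n_cell_types
  cx <- 8 * cos(theta)[match(cell_type, types)]
  cy <- 8 * sin(theta)[match(cell_type, types)]
  cell_meta <- data.frame(
    cell = cells, type = cell_type,
    x = stats::rnorm(n_cells, cx, 1), y = stats::rnorm(n_cells, cy, 1),
    stringsAsFactors = FALSE
  )
  list(expr = expression_data(Matrix::Matrix(counts, sparse = TRUE),
                              cell_meta),
       truth = list(markers = markers))
}

#' Simulate the linked genotype/expression fixture
#'
#' Couples the two generators the way scPBS assumes real data are coupled:
#' the rare-PTV case enrichment is planted exactly in the marker genes of one
#' (or more) designated causal cell types. Ground-truth labels are returned
#' for assertions.
#'
#' @param causal_types indices (or names) of the causal cell types, default 1.
#' @param causal_or planted carrier odds ratio, default 5.
#' @param n_cases,n_controls cohort sizes, defaults 500/500.
#' @param seed RNG seed (required); the cohort and expression stages derive
#'   independent sub-seeds from it.
#' @param ... further arguments passed to \code{\link{simulate_expression}}
#'   (dataset shape, marker strength) and \code{\link{simulate_cohort}} via
#'   the shared \code{n_genes}.
#' @inheritParams simulate_cohort
#' @inheritParams simulate_expression
#' @return list with \code{cohort}, \code{expr} and \code{truth}
#'   (\code{causal_types}, \code{causal_genes}, per-type markers).
#' @export
simulate_linked_dataset <- function(causal_types = 1, causal_or = 5,
                                    n_cases = 500, n_controls = 500,
                                    n_genes = 1000, n_cell_types = 5,
                                    cells_per_type = 200,
                                    marker_genes_per_type = 50,
                                    marker_logfc = 2,
                                    baseline_carrier_rate = 0.01,
                                    nb_dispersion = 0.5, seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  base_seed <- as.integer(seed %% 900000000)
  sim_expr <- simulate_expression(
    n_genes = n_genes, n_cell_types = n_cell_types,
    cells_per_type = cells_per_type,
    marker_genes_per_type = marker_genes_per_type,
    marker_logfc = marker_logfc, nb_dispersion = nb_dispersion,
    seed = base_seed + 1L)
  types <- names(sim_expr$truth$markers)
  if (is.numeric(causal_types)) causal_types <- types[causal_types]
  stopifnot(all(causal_types %in% types))
  causal_genes <- unique(unlist(sim_expr$truth$markers[causal_types]))

  cohort <- simulate_cohort(
    n_cases = n_cases, n_controls = n_controls, n_genes = n_genes,
    baseline_carrier_rate = baseline_carrier_rate,
    causal_genes = causal_genes, causal_or = causal_or,
    seed = base_seed + 2L)

  list(cohort = cohort, expr = sim_expr$expr,
       truth = list(causal_types = causal_types,
                    causal_genes = causal_genes,
                    markers = sim_expr$truth$markers))
}
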