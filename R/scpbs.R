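# Single-cell polygenic burden score (scPBS): per-cell specific gene sets,
# per-cell Firth burden coefficients, PCC-ranked trait-relevant genes and the
# rare-variant trait-relevance score (rvTRS) with bin-matched control-gene
# subtraction.

#' Cell-type burden enrichment of marker genes
#'
#' For each cell type, tests whether qualifying-variant carriers of the type's
#' marker-gene union are enriched among cases, via
#' \code{\link{unit_burden_test}}. A synonymous-class carrier matrix may be
#' supplied to report the negative-control test alongside.
#'
#' @param markers named list of character gene vectors (e.g. the
#'   \code{markers} attribute of \code{\link{celltype_marker_genes}}).
#' @param gene_carriers gene x sample carrier matrix for the class under test
#'   (typically PTVs).
#' @param design cohort design data frame.
#' @param test \code{"firth"} or \code{"fet"}.
#' @param covariates covariate set for the Firth model.
#' @param syn_carriers optional synonymous-class gene x sample carrier matrix;
#'   adds rows with \code{class = "SYNONYMOUS"}.
#' @return data frame of per-type burden results with a \code{class} column.
#' @export
celltype_burden_enrichment <- function(markers, gene_carriers, design,
                                       test = c("firth", "fet"),
                                       covariates = c("sex", "pcs",
                                                      "total_exome_count"),
                                       syn_carriers = NULL) {
  test <- match.arg(test)
  if (!length(markers)) stop("empty marker list", call. = FALSE)
  run <- function(cmat, cls) {
    rows <- lapply(names(markers), function(tp) {
      members <- intersect(markers[[tp]], rownames(cmat))
      carrier <- if (length(members)) {
        as.numeric(colSums(cmat[members, , drop = FALSE]) > 0)
      } else rep(0, ncol(cmat))
      names(carrier) <- colnames(cmat)
      r <- unit_burden_test(carrier, design, test = test,
                            covariates = covariates, unit = tp)
      r$class <- cls
      r$n_marker_genes <- length(members)
      r
    })
    do.call(rbind, rows)
  }
  out <- run(gene_carriers, "PTV")
  if (!is.null(syn_carriers)) out <- rbind(out, run(syn_carriers, "SYNONYMOUS"))
  out
}

#' Per-cell specific gene sets
#'
#' For each cell, genes are scored by the product of the cell's log-normalized
#' expression and the expression specificity of the cell's assigned type, and
#' the top \code{fraction} of the cell's expressed genes (count > 0) is
#' selected. Ties are broken lexicographically by gene id, so the selection is
#' deterministic. Cells with fewer than \code{min_genes} expressed genes are
#' skipped with a warning.
#'
#' @param expr an \code{\link{expression_data}} object.
#' @param specificity a \code{\link{tpm_and_specificity}} result.
#' @param fraction fraction of expressed genes selected per cell, default 0.10.
#' @param min_genes minimum expressed genes per usable cell, default 10.
#' @return named list mapping cell id to a character vector of genes; skipped
#'   cells are absent.
#' @export
per_cell_gene_sets <- function(expr, specificity, fraction = 0.10,
                               min_genes = 10) {
  stopifnot(inherits(specificity, "specificity_matrix"))
  expr <- normalize_expression(expr)
  norm <- expr$normalized
  genes <- rownames(norm)
  gene_order <- order(genes)   # lexicographic tie-break baked into ordering
  out <- vector("list", ncol(norm))
  names(out) <- colnames(norm)
  skipped <- 0L
  for (i in seq_len(ncol(norm))) {
    v <- norm[, i]
    tp <- as.character(expr$cell_meta$type[i])
    score <- v * specificity$s[, tp]
    expressed <- which(v > 0)
    if (length(expressed) < min_genes) {
      skipped <- skipped + 1L
      out[[i]] <- NULL
      next
    }
    k <- ceiling(fraction * length(expressed))
    # order by decreasing score, ties by gene id (ascending)
    sc <- score[expressed]
    ord <- expressed[order(-sc, genes[expressed])]
    out[[i]] <- genes[utils::head(ord, k)]
  }
  if (skipped > 0) {
    warning(sprintf("%d cell(s) with fewer than %d expressed genes skipped",
                    skipped, min_genes))
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Per-cell polygenic burden score
#'
#' For each cell's gene set, builds the carrier indicator (any qualifying
#' allele in any set gene) and fits Firth logistic regression of case status
#' on the indicator plus covariates. The scPBS of the cell is the fitted
#' carrier log odds ratio. Cells whose set yields zero carriers (or whose
#' indicator is constant) receive scPBS 0 with a null flag. Fits are cached by
#' carrier pattern, and the covariate-only model is shared across cells, so
#' repeated patterns cost one fit.
#'
#' @param cell_sets named list of per-cell gene sets
#'   (\code{\link{per_cell_gene_sets}}).
#' @param gene_carriers gene x sample carrier matrix (qualifying PTVs).
#' @param design cohort design data frame.
#' @param covariates covariate columns for the Firth model; \code{"pcs"}
#'   expands to all PC columns.
#' @return data frame with columns \code{cell}, \code{scpbs},
#'   \code{n_carriers}, \code{null_flag}.
#' @export
per_cell_burden_score <- function(cell_sets, gene_carriers, design,
                                  covariates = c("sex", "pcs",
                                                 "total_exome_count")) {
  y <- design_status(design)
  if (!is.null(design$sample_id)) {
    gene_carriers <- gene_carriers[, match(design$sample_id,
                                           colnames(gene_carriers)),
                                   drop = FALSE]
  }
  covm <- covariate_matrix(design, covariates)
  if (!is.null(covm)) {
    const <- apply(covm, 2, function(cl) length(unique(cl)) == 1)
    if (any(const)) {
      stop("constant covariate column(s): ",
           paste(colnames(covm)[const], collapse = ", "), call. = FALSE)
    }
  }
  genes <- rownames(gene_carriers)
  xmat <- gene_carriers > 0
  cache <- new.env(parent = emptyenv(), hash = TRUE)

  res <- data.frame(cell = names(cell_sets), scpbs = 0,
                    n_carriers = 0L, null_flag = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cell_sets)) {
    members <- intersect(cell_sets[[i]], genes)
    carrier <- if (length(members)) {
      as.numeric(Matrix::colSums(xmat[members, , drop = FALSE]) > 0)
    } else rep(0, ncol(xmat))
    n_car <- sum(carrier)
    res$n_carriers[i] <- n_car
    if (n_car == 0 || n_car == length(carrier)) {
      res$null_flag[i] <- TRUE
      next
    }
    key <- paste(which(carrier == 1), collapse = ",")
    beta <- cache[[key]]
    if (is.null(beta)) {
      X <- cbind(intercept = 1, carrier = carrier, covm)
      fit <- tryCatch(firth_logistic_fit(y, X),
                      rvburden_firth_error = function(e) NULL)
      beta <- if (is.null(fit)) NA_real_ else fit$beta[["carrier"]]
      cache[[key]] <- beta
    }
    if (is.na(beta)) {
      res$null_flag[i] <- TRUE
    } else {
      res$scpbs[i] <- beta
    }
  }
  res
}

#' Trait-relevant genes by correlation with scPBS
#'
#' Computes the Pearson correlation of each gene's log-normalized expression
#' with the per-cell scPBS (null-flagged cells excluded), drops genes with
#' zero expression variance across the retained cells, and returns the top
#' \code{fraction} of genes by signed descending correlation.
#'
#' @param scores data frame from \code{\link{per_cell_burden_score}}.
#' @param expr an \code{\link{expression_data}} object.
#' @param fraction fraction of ranked genes returned, default 0.10.
#' @return list with \code{pcc} (named vector over rankable genes, sorted
#'   decreasing) and \code{trait_genes} (character vector, length
#'   \code{ceiling(fraction * length(pcc))}).
#' @export
trait_relevant_genes <- function(scores, expr, fraction = 0.10) {
  expr <- normalize_expression(expr)
  use <- scores[!scores$null_flag, , drop = FALSE]
  if (nrow(use) < 3) stop("fewer than 3 cells with defined scPBS",
                          call. = FALSE)
  m <- as.matrix(expr$normalized[, use$cell, drop = FALSE])
  sds <- apply(m, 1, stats::sd)
  ok <- is.finite(sds) & sds > 0
  pcc <- drop(stats::cor(t(m[ok, , drop = FALSE]), use$scpbs))
  names(pcc) <- rownames(m)[ok]
  pcc <- sort(pcc, decreasing = TRUE)
  k <- ceiling(fraction * length(pcc))
  list(pcc = pcc, trait_genes = names(pcc)[seq_len(k)])
}

#' Rare-variant trait-relevance score (rvTRS)
#'
#' Module-score computation over the trait-relevant genes: all genes are
#' binned into \code{n_bins} equal-frequency bins of average log-normalized
#' expression; for each trait gene, \code{n_ctrl} control genes are drawn
#' (seeded) from its bin; the rvTRS of a cell is the mean normalized
#' expression of the trait genes minus the mean over the pooled control draws.
#' Bins smaller than \code{n_ctrl} are sampled with replacement, with a
#' warning.
#'
#' @param expr an \code{\link{expression_data}} object.
#' @param trait_genes character vector of trait-relevant genes (must exist in
#'   the gene registry).
#' @param n_bins number of average-expression bins, default 25.
#' @param n_ctrl control genes drawn per trait gene, default 100.
#' @param seed RNG seed (required).
#' @return named numeric vector of per-cell rvTRS.
#' @export
rvtrs_score <- function(expr, trait_genes, n_bins = 25, n_ctrl = 100, seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  expr <- normalize_expression(expr)
  norm <- expr$normalized
  missing_genes <- setdiff(trait_genes, rownames(norm))
  if (length(missing_genes)) {
    stop("trait gene(s) absent from registry: ",
         paste(utils::head(missing_genes, 3), collapse = ", "), call. = FALSE)
  }
  avg <- Matrix::rowMeans(norm)
  # equal-frequency bins via ranks (deterministic ties)
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(rk / (length(avg) / n_bins))
  names(bin) <- rownames(norm)

  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  ctrl_pool <- character(0)
  warned <- FALSE
  for (g in trait_genes) {
    candidates <- names(bin)[bin == bin[[g]]]
    if (length(candidates) < n_ctrl) {
      if (!warned) {
        warning("expression bin smaller than n_ctrl; sampling with replacement")
        warned <- TRUE
      }
      draw <- sample(candidates, n_ctrl, replace = TRUE)
    } else {
      draw <- sample(candidates, n_ctrl)
    }
    ctrl_pool <- c(ctrl_pool, draw)
  }
  trait_mean <- Matrix::colMeans(norm[trait_genes, , drop = FALSE])
  ctrl_mean <- colMeans(as.matrix(norm[ctrl_pool, , drop = FALSE]))
  stats::setNames(trait_mean - ctrl_mean, colnames(norm))
}

#' Run the scPBS pipeline end to end
#'
#' Orchestrates the five scPBS stages: expression specificity, per-cell
#' specific gene sets, per-cell Firth burden coefficients (scPBS),
#' PCC-ranked trait-relevant genes, and the rvTRS with bin-matched control
#' subtraction. Returns the per-cell table together with a per-type summary.
#'
#' @param gene_carriers gene x sample carrier matrix of qualifying PTVs.
#' @param design cohort design data frame.
#' @param expr an \code{\link{expression_data}} object.
#' @param fraction top fraction for per-cell gene sets and trait genes,
#'   default 0.10.
#' @param n_bins,n_ctrl rvTRS control-scheme parameters, defaults 25 and 100.
#' @param covariates covariate columns for the per-cell Firth model.
#' @param seed RNG seed (required; the only stochastic stage is the control
#'   draw of \code{\link{rvtrs_score}}).
#' @return object of class \code{scpbs_result}: list with \code{cells}
#'   (per-cell data frame: cell, type, embedding, scpbs, rvtrs, null_flag),
#'   \code{pcc}, \code{trait_genes}, \code{type_summary} (per-type median and
#'   IQR of rvTRS, sorted decreasing by median).
#' @export
run_scpbs <- function(gene_carriers, design, expr, fraction = 0.10,
                      n_bins = 25, n_ctrl = 100,
                      covariates = c("sex", "pcs", "total_exome_count"),
                      seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  expr <- normalize_expression(expr)
  spec <- tpm_and_specificity(expr)
  sets <- per_cell_gene_sets(expr, spec, fraction = fraction)
  scores <- per_cell_burden_score(sets, gene_carriers, design,
                                  covariates = covariates)
  ranking <- trait_relevant_genes(scores, expr, fraction = fraction)
  rvtrs <- rvtrs_score(expr, ranking$trait_genes, n_bins = n_bins,
                       n_ctrl = n_ctrl, seed = seed)

  meta <- expr$cell_meta
  cells <- data.frame(cell = meta$cell, type = meta$type,
                      stringsAsFactors = FALSE)
  if (all(c("x", "y") %in% names(meta))) {
    cells$x <- meta$x
    cells$y <- meta$y
  }
  cells$scpbs <- scores$scpbs[match(cells$cell, scores$cell)]
  cells$null_flag <- scores$null_flag[match(cells$cell, scores$cell)]
  cells$rvtrs <- rvtrs[cells$cell]

  agg <- split(cells$rvtrs, cells$type)
  type_summary <- data.frame(
    type = names(agg),
    n_cells = vapply(agg, length, integer(1)),
    median_rvtrs = vapply(agg, stats::median, numeric(1)),
    iqr_rvtrs = vapply(agg, stats::IQR, numeric(1)),
    median_scpbs = vapply(split(cells$scpbs, cells$type), stats::median,
                          numeric(1)),
    stringsAsFactors = FALSE
  )
  type_summary <- type_summary[order(-type_summary$median_rvtrs), ,
                               drop = FALSE]
  rownames(type_summary) <- NULL
  structure(list(cells = cells, pcc = ranking$pcc,
                 trait_genes = ranking$trait_genes,
                 type_summary = type_summary),
            class = "scpbs_result")
}

#' @export
print.scpbs_result <- function(x, ...) {
  cat(sprintf("scPBS result: %d cells, %d trait-relevant genes\n",
              nrow(x$cells), length(x$trait_genes)))
  print(x$type_summary)
  invisible(x)
}
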