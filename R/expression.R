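# Single-cell expression container, library-size log-normalization,
# TPM-based expression specificity, one-vs-rest marker ranking and per-type
# relative-expression profiles.

#' Construct an expression-data object
#'
#' Bundles a sparse gene x cell count matrix with cell metadata (cell id,
#' cell-type label, optional 2-D embedding coordinates). Log-normalized
#' values are computed lazily by \code{\link{normalize_expression}}.
#'
#' @param counts gene x cell matrix of non-negative integer counts (dense or
#'   \code{Matrix} sparse); row names are gene ids, column names cell ids.
#' @param cell_meta data frame with columns \code{cell}, \code{type} and
#'   optionally \code{x}, \code{y} (embedding coordinates); one row per cell,
#'   in matrix column order.
#' @return object of class \code{expression_data}.
#' @export
expression_data <- function(counts, cell_meta) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  stopifnot(is.data.frame(cell_meta),
            all(c("cell", "type") %in% names(cell_meta)))
  if (nrow(cell_meta) != ncol(counts)) {
    stop("cell_meta rows must match count-matrix columns", call. = FALSE)
  }
  if (is.null(rownames(counts))) stop("counts needs gene-id row names",
                                      call. = FALSE)
  if (is.null(colnames(counts))) colnames(counts) <- cell_meta$cell
  if (!identical(colnames(counts), as.character(cell_meta$cell))) {
    stop("cell ids in metadata do not match count-matrix columns",
         call. = FALSE)
  }
  if (any(counts@x < 0)) stop("negative counts", call. = FALSE)
  structure(list(counts = counts, cell_meta = cell_meta, normalized = NULL),
            class = "expression_data")
}

#' @export
print.expression_data <- function(x, ...) {
  cat(sprintf("expression_data: %d genes x %d cells, %d cell type(s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$type))))
  invisible(x)
}

#' Library-size log-normalization
#'
#' Scales each cell's counts to a common library size (default 1e4) and
#' applies \code{log1p}; the standard log-normalization used before
#' correlation- and module-score computations. The result is cached on the
#' object.
#'
#' @param expr an \code{\link{expression_data}} object.
#' @param scale_factor target library size, default 1e4.
#' @return \code{expr} with the \code{normalized} slot filled (sparse gene x
#'   cell matrix).
#' @export
normalize_expression <- function(expr, scale_factor = 1e4) {
  stopifnot(inherits(expr, "expression_data"))
  if (!is.null(expr$normalized)) return(expr)
  lib <- Matrix::colSums(expr$counts)
  if (any(lib == 0)) warning(sum(lib == 0), " cell(s) with zero counts")
  lib[lib == 0] <- 1
  norm <- expr$counts %*% Matrix::Diagonal(x = scale_factor / lib)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(expr$counts)
  expr$normalized <- norm
  expr
}

#' Expression specificity per gene and cell type
#'
#' Mean counts per cell type are scaled to a total of one million (TPM per
#' type); the specificity of gene g in type c is its TPM divided by the gene's
#' maximum TPM across types, so every expressed gene attains 1 in its argmax
#' type and specificity lies in [0, 1]. Genes with zero expression everywhere
#' get specificity 0 in all types.
#'
#' @param expr an \code{\link{expression_data}} object.
#' @return list of class \code{specificity_matrix}: \code{s} (gene x type
#'   specificity), \code{tpm} (gene x type mean TPM).
#' @export
tpm_and_specificity <- function(expr) {
  stopifnot(inherits(expr, "expression_data"))
  types <- sort(unique(as.character(expr$cell_meta$type)))
  if (length(types) < 2) stop("need at least 2 cell types", call. = FALSE)
  mean_counts <- sapply(types, function(tp) {
    Matrix::rowMeans(expr$counts[, expr$cell_meta$type == tp, drop = FALSE])
  })
  totals <- colSums(mean_counts)
  if (any(totals == 0)) {
    stop("cell type(s) with zero total counts: ",
         paste(types[totals == 0], collapse = ", "), call. = FALSE)
  }
  tpm <- sweep(mean_counts, 2, totals, "/") * 1e6
  mx <- apply(tpm, 1, max)
  s <- tpm / ifelse(mx > 0, mx, 1)
  s[mx == 0, ] <- 0
  dimnames(s) <- dimnames(tpm) <- list(rownames(expr$counts), types)
  structure(list(s = s, tpm = tpm), class = "specificity_matrix")
}

# Wilcoxon rank-sum z statistics, one gene at a time, for cells in `in_idx`
# versus the rest. Normal approximation with tie correction.
ranksum_z <- function(mat, in_idx) {
  n <- ncol(mat)
  n1 <- sum(in_idx)
  n2 <- n - n1
  apply(mat, 1, function(v) {
    r <- rank(v)
    u <- sum(r[in_idx]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sig2 <= 0) return(0)
    (u - n1 * n2 / 2) / sqrt(sig2)
  })
}

#' One-vs-rest marker genes per cell type
#'
#' Ranks genes per cell type by a one-vs-rest Wilcoxon rank-sum z statistic on
#' log-normalized expression, keeping only positively enriched genes with
#' natural-log fold change at least \code{logfc_threshold} (computed, as in
#' standard single-cell practice, on expm1-averaged normalized values with a
#' pseudocount of 1) and detection fraction at least \code{min_pct} in the
#' type. Each type's markers are the top \code{fraction} (default 10\%) of
#' the dataset's genes by rank statistic, truncated to the genes passing the
#' filters.
#'
#' @param expr an \code{\link{expression_data}} object.
#' @param fraction fraction of the gene registry kept per type, default 0.10.
#' @param min_pct minimum within-type detection fraction, default 0.1.
#' @param logfc_threshold minimum natural-log fold change, default 0.25.
#' @return named list (one element per type) of data frames with columns
#'   \code{gene}, \code{z}, \code{logfc}, \code{pct_in}, ordered by
#'   decreasing z; attribute \code{markers} gives the top-fraction gene lists.
#' @export
celltype_marker_genes <- function(expr, fraction = 0.10, min_pct = 0.1,
                                  logfc_threshold = 0.25) {
  expr <- normalize_expression(expr)
  types <- sort(unique(as.character(expr$cell_meta$type)))
  norm <- as.matrix(expr$normalized)
  detected <- as.matrix(expr$counts > 0)
  out <- list()
  for (tp in types) {
    in_idx <- expr$cell_meta$type == tp
    if (sum(in_idx) < 3) {
      warning(sprintf("type '%s' has fewer than 3 cells; skipped", tp))
      out[[tp]] <- data.frame(gene = character(0), z = numeric(0),
                              logfc = numeric(0), pct_in = numeric(0))
      next
    }
    pct_in <- rowMeans(detected[, in_idx, drop = FALSE])
    mean_in <- rowMeans(expm1(norm[, in_idx, drop = FALSE]))
    mean_out <- rowMeans(expm1(norm[, !in_idx, drop = FALSE]))
    logfc <- log(mean_in + 1) - log(mean_out + 1)
    pass <- pct_in >= min_pct & logfc >= logfc_threshold
    if (!any(pass)) {
      warning(sprintf("type '%s' has no passing marker genes", tp))
      out[[tp]] <- data.frame(gene = character(0), z = numeric(0),
                              logfc = numeric(0), pct_in = numeric(0))
      next
    }
    z <- ranksum_z(norm[pass, , drop = FALSE], in_idx)
    df <- data.frame(gene = rownames(norm)[pass], z = z,
                     logfc = logfc[pass], pct_in = pct_in[pass],
                     stringsAsFactors = FALSE)
    df <- df[order(-df$z, df$gene), , drop = FALSE]
    rownames(df) <- NULL
    out[[tp]] <- df
  }
  markers <- lapply(out, function(df) {
    if (!nrow(df)) return(character(0))
    utils::head(df$gene, ceiling(fraction * nrow(expr$counts)))
  })
  structure(out, markers = markers)
}

#' Per-type relative expression profile of a candidate gene
#'
#' Mean log-normalized expression of the gene per cell type, z-scaled across
#' types (mean 0, SD 1 when at least two types differ), mirroring the usual
#' relative-expression heatmap computation.
#'
#' @param expr an \code{\link{expression_data}} object.
#' @param gene gene id; must be present in the count matrix.
#' @return named numeric vector of z-scaled per-type means.
#' @export
candidate_gene_celltype_profile <- function(expr, gene) {
  expr <- normalize_expression(expr)
  if (!gene %in% rownames(expr$counts)) {
    stop("gene not found: ", gene, call. = FALSE)
  }
  v <- expr$normalized[gene, ]
  types <- sort(unique(as.character(expr$cell_meta$type)))
  m <- vapply(types, function(tp) mean(v[expr$cell_meta$type == tp]),
              numeric(1))
  s <- stats::sd(m)
  if (!is.finite(s) || s == 0) return(stats::setNames(rep(0, length(m)), types))
  stats::setNames((m - mean(m)) / s, types)
}
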