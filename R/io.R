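# Interchange formats: VCF genotypes (via vcfR), the annotation-table TSV
# dialect, MatrixMarket expression trios, GMT gene sets, and deterministic
# result writing with a run manifest.

ANNOTATION_COLUMNS <- c("variant_id", "consequence", "polyphen", "sift",
                        "cadd_phred", "loftee", "af_gnomad", "af_1kg",
                        "af_esp", "low_complexity", "vqsr_pass")

#' Read genotypes from a VCF file
#'
#' Light-weight VCF (v4.2, plain or gzipped) reader built on \pkg{vcfR}.
#' Dosages are coded 0/1/2 with \code{NA} for missing; multi-allelic records
#' are split into one biallelic variant per alternate allele; variant ids are
#' normalised to \code{chrom-pos-ref-alt}. FORMAT fields DP and GQ are
#' returned when present, and the alternate-allele balance is derived from AD
#' (alt depth over total depth) for heterozygous calls.
#'
#' @param path VCF file path.
#' @return a \code{\link{genotype_matrix}} whose dosage rows are named by
#'   normalised variant id; attribute \code{variants} carries the variant
#'   registry (chrom, pos, ref, alt).
#' @export
read_vcf_lite <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_lite requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  grab <- function(element, numeric = TRUE) {
    m <- tryCatch(vcfR::extract.gt(v, element = element,
                                   as.numeric = numeric),
                  error = function(e) NULL)
    if (is.null(m) || all(is.na(m))) NULL else m   # absent FORMAT field
  }
  dp_raw <- grab("DP")
  gq_raw <- grab("GQ")
  ad_raw <- grab("AD", numeric = FALSE)
  samples <- colnames(gt_raw)
  n_rec <- nrow(fix)

  rows <- list()
  reg <- list()
  for (r in seq_len(n_rec)) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    gt <- gsub("|", "/", gt_raw[r, ], fixed = TRUE)
    alleles <- strsplit(gt, "/", fixed = TRUE)
    ad <- if (!is.null(ad_raw)) {
      lapply(strsplit(ad_raw[r, ], ",", fixed = TRUE),
             function(x) suppressWarnings(as.numeric(x)))
    } else NULL
    for (k in seq_along(alts)) {
      vid <- paste(fix[r, "CHROM"], fix[r, "POS"], fix[r, "REF"], alts[k],
                   sep = "-")
      dos <- vapply(alleles, function(al) {
        if (length(al) == 0 || any(al == ".") || any(is.na(al))) {
          return(NA_integer_)
        }
        sum(al == as.character(k))
      }, integer(1))
      ab <- rep(NA_real_, length(dos))
      if (!is.null(ad)) {
        for (s in which(!is.na(dos) & dos == 1L)) {
          depths <- ad[[s]]
          if (length(depths) > k && sum(depths, na.rm = TRUE) > 0) {
            ab[s] <- depths[k + 1] / sum(depths, na.rm = TRUE)
          }
        }
      }
      rows[[vid]] <- list(
        dosage = dos,
        dp = if (!is.null(dp_raw)) dp_raw[r, ] else rep(NA_real_, length(dos)),
        gq = if (!is.null(gq_raw)) gq_raw[r, ] else rep(NA_real_, length(dos)),
        ab = ab)
      reg[[vid]] <- data.frame(variant_id = vid, chrom = fix[r, "CHROM"],
                               pos = as.integer(fix[r, "POS"]),
                               ref = fix[r, "REF"], alt = alts[k],
                               stringsAsFactors = FALSE)
    }
  }
  pull <- function(field) {
    m <- do.call(rbind, lapply(rows, `[[`, field))
    dimnames(m) <- list(names(rows), samples)
    m
  }
  # FORMAT fields absent from the file stay NULL: "not collected" rather
  # than "collected and missing", so downstream filters skip them
  g <- genotype_matrix(pull("dosage"),
                       dp = if (!is.null(dp_raw)) pull("dp"),
                       gq = if (!is.null(gq_raw)) pull("gq"),
                       ab = if (!is.null(ad_raw)) pull("ab"))
  attr(g, "variants") <- do.call(rbind, c(reg, list(make.row.names = FALSE)))
  g
}

#' Read a variant annotation table
#'
#' Tab-separated with named columns: \code{variant_id}, \code{consequence},
#' \code{polyphen}, \code{sift}, \code{cadd_phred}, \code{loftee},
#' \code{af_gnomad}, \code{af_1kg}, \code{af_esp}, \code{low_complexity},
#' \code{vqsr_pass}; a \code{gene} column is kept when present. Empty
#' numeric fields become \code{NA}; unknown categories are preserved as
#' strings; duplicated variant ids are an error.
#'
#' @param path TSV file path.
#' @return annotation data frame.
#' @export
read_annotation_table <- function(path) {
  ann <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(ann))
  if (length(missing_cols)) {
    stop("annotation table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ann$variant_id)) {
    stop("duplicated variant_id in annotation table", call. = FALSE)
  }
  for (col in c("cadd_phred", "af_gnomad", "af_1kg", "af_esp")) {
    ann[[col]] <- suppressWarnings(as.numeric(ann[[col]]))
  }
  for (col in c("low_complexity", "vqsr_pass")) {
    ann[[col]] <- as.logical(ann[[col]])
  }
  ann
}

#' Read a sparse expression matrix with registries
#'
#' MatrixMarket coordinate counts plus a gene registry (TSV, first column =
#' gene id) and cell metadata (TSV with columns \code{cell}, \code{type} and
#' optional embedding columns \code{x}, \code{y}).
#'
#' @param mtx_path,genes_path,cells_path file paths.
#' @return an \code{\link{expression_data}} object.
#' @export
read_expression <- function(mtx_path, genes_path, cells_path) {
  counts <- Matrix::readMM(mtx_path)
  genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  if (length(genes) != nrow(counts)) {
    stop("gene registry does not match matrix rows", call. = FALSE)
  }
  if (nrow(cells) != ncol(counts)) {
    stop("cell metadata does not match matrix columns", call. = FALSE)
  }
  rownames(counts) <- genes
  colnames(counts) <- cells$cell
  empty <- Matrix::colSums(counts) == 0
  if (any(empty)) {
    warning(sum(empty), " all-zero cell column(s) retained")
  }
  expression_data(counts, cells)
}

#' Write an expression fixture as a MatrixMarket trio
#'
#' @param expr an \code{\link{expression_data}} object.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths written.
#' @export
write_expression <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "counts.mtx")
  genes <- file.path(dir, "genes.tsv")
  cells <- file.path(dir, "cells.tsv")
  Matrix::writeMM(expr$counts, mtx)
  utils::write.table(data.frame(gene = rownames(expr$counts)), genes,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$cell_meta, cells, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(mtx, genes, cells))
}

#' Read a GMT gene-set collection
#'
#' Tab-delimited: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character gene vectors; descriptions kept as the
#'   \code{description} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    stop("malformed GMT line(s): ", paste(utils::head(bad, 3), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character gene vectors.
#' @param path output file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a sparse dosage matrix as a minimal VCF
#'
#' Emits a VCF v4.2 with GT only, one biallelic record per variant id of the
#' form \code{chrom-pos-ref-alt}; used to materialise synthetic cohorts.
#'
#' @param dosage variant x sample dosage matrix with \code{chrom-pos-ref-alt}
#'   row names.
#' @param path output file path.
#' @export
write_vcf_lite <- function(dosage, path) {
  dosage <- as.matrix(dosage)
  ids <- strsplit(rownames(dosage), "-", fixed = TRUE)
  bad <- which(lengths(ids) != 4)
  if (length(bad)) stop("variant id(s) not chrom-pos-ref-alt", call. = FALSE)
  gt <- matrix(c("0/0", "0/1", "1/1")[dosage + 1], nrow(dosage))
  gt[is.na(dosage)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(dosage)), collapse = "\t"))
  body <- vapply(seq_len(nrow(dosage)), function(i) {
    p <- ids[[i]]
    paste(c(p[1], p[2], rownames(dosage)[i], p[3], p[4], ".", "PASS", ".",
            "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

file_md5 <- function(paths) {
  out <- tools::md5sum(paths[file.exists(paths)])
  as.list(out)
}

#' Write result tables with a run manifest
#'
#' Writes each table as TSV with deterministic row order (sorted over all
#' columns) and fixed column order, plus a \code{manifest.json} recording the
#' configuration, its hash, every seed used, package and R versions, and
#' checksums of inputs and outputs. Refuses to write into a non-empty
#' directory unless \code{force = TRUE}.
#'
#' @param tables named list of data frames.
#' @param outdir output directory.
#' @param config list of run parameters recorded in the manifest.
#' @param seeds named list/vector of seeds used.
#' @param inputs character vector of input file paths to checksum.
#' @param force overwrite into a non-empty directory, default \code{FALSE}.
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, outdir, config = list(), seeds = list(),
                          inputs = character(0), force = FALSE) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force) {
    stop("output directory not empty (use force = TRUE): ", outdir,
         call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tb <- as.data.frame(tables[[nm]])
    if (nrow(tb) > 1) tb <- tb[do.call(order, tb), , drop = FALSE]
    p <- file.path(outdir, paste0(nm, ".tsv"))
    utils::write.table(tb, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  cfg_file <- tempfile()
  writeLines(deparse(config), cfg_file)
  manifest <- list(
    config = config,
    config_hash = unname(tools::md5sum(cfg_file)),
    seeds = seeds,
    versions = list(rvburden = as.character(utils::packageVersion("rvburden")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    input_checksums = file_md5(inputs),
    output_checksums = file_md5(paths)
  )
  unlink(cfg_file)
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(paths, manifest_path))
}
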