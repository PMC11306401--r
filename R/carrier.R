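# Carrier (collapsing) matrices: per-unit indicator or allele-count coding of
# qualifying-variant carriage, plus the per-sample total exome count covariate.

#' Build a carrier matrix from qualifying variants
#'
#' Collapses a variant x sample dosage matrix to a unit x sample matrix,
#' where a unit is a gene or a gene set. In \code{"indicator"} mode (the
#' default, matching presence/absence collapsing) an entry is 1 iff the sample
#' carries at least one qualifying allele in the unit; \code{"count"} mode
#' sums alleles. Missing genotypes are treated as non-carrier (site-level call
#' rate is enforced upstream); the number of affected calls is reported as a
#' message.
#'
#' @param dosage variant x sample dosage matrix (0/1/2/NA); row names are
#'   variant ids.
#' @param gene_map data frame with columns \code{variant_id} and \code{gene}
#'   mapping each variant to one or more genes.
#' @param units named list of character vectors of genes (gene sets), or
#'   \code{NULL} to use one unit per gene.
#' @param mode \code{"indicator"} or \code{"count"}.
#' @return object of class \code{carrier_matrix}: unit x sample numeric
#'   matrix with attributes \code{mode} and \code{total_exome_count} (named
#'   per-sample allele sum over all supplied variants).
#' @export
build_carrier_matrix <- function(dosage, gene_map, units = NULL,
                                 mode = c("indicator", "count")) {
  mode <- match.arg(mode)
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) stop("dosage needs variant-id row names",
                                      call. = FALSE)
  unmapped <- setdiff(rownames(dosage), gene_map$variant_id)
  if (length(unmapped)) {
    stop("variant(s) missing from gene map: ",
         paste(utils::head(unmapped, 3), collapse = ", "), call. = FALSE)
  }
  n_missing <- sum(is.na(dosage))
  if (n_missing > 0) {
    message(sprintf(
      "build_carrier_matrix: %d missing call(s) treated as non-carrier",
      n_missing))
    dosage[is.na(dosage)] <- 0
  }
  texc <- colSums(dosage)

  genes <- sort(unique(gene_map$gene))
  per_gene <- matrix(0, length(genes), ncol(dosage),
                     dimnames = list(genes, colnames(dosage)))
  idx <- split(gene_map$variant_id, gene_map$gene)
  for (g in genes) {
    v <- intersect(idx[[g]], rownames(dosage))
    if (length(v)) {
      per_gene[g, ] <- colSums(dosage[v, , drop = FALSE])
    }
  }

  if (is.null(units)) {
    out <- per_gene
  } else {
    if (is.null(names(units))) stop("units must be named", call. = FALSE)
    out <- matrix(0, length(units), ncol(dosage),
                  dimnames = list(names(units), colnames(dosage)))
    for (u in names(units)) {
      members <- intersect(units[[u]], genes)
      if (!length(members)) {
        warning(sprintf("unit '%s' has no variants; row of zeros", u))
        next
      }
      out[u, ] <- colSums(per_gene[members, , drop = FALSE])
    }
  }
  if (mode == "indicator") out <- (out > 0) + 0
  structure(out, mode = mode, total_exome_count = texc,
            class = c("carrier_matrix", class(out)))
}

#' Per-sample total exome count
#'
#' Sum of a sample's qualifying alleles over all four variant classes
#' (synonymous, benign missense, damaging missense, PTV); used as a covariate
#' in the Firth burden models.
#'
#' @param dosage variant x sample dosage matrix for all qualifying variants
#'   (all classes).
#' @return named numeric vector of allele sums per sample.
#' @export
total_exome_count <- function(dosage) {
  dosage <- as.matrix(dosage)
  dosage[is.na(dosage)] <- 0
  colSums(dosage)
}
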