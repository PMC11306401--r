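# Diagnostic-yield summary over an externally curated table of
# pathogenic/likely-pathogenic findings.

#' Summarise diagnostic yield from a curated carrier table
#'
#' Given a table of per-case pathogenic/likely-pathogenic findings (one row
#' per detected allele), reports the carrier yield as a percentage of the
#' cohort, the share of carriers with a single (monoallelic) finding, the
#' class composition of the findings and per-gene allele counts.
#'
#' @param findings data frame with columns \code{case_id}, \code{gene} and
#'   optionally \code{class} (e.g. PTV / D_MIS) and \code{variant_id}; one row
#'   per detected allele.
#' @param n_cases cohort size (number of cases screened); must be positive.
#' @return list with elements \code{n_carriers}, \code{yield_pct} (2 decimal
#'   places), \code{monoallelic_pct}, \code{class_props} (named proportions)
#'   and \code{gene_allele_counts} (named integer vector, decreasing).
#' @examples
#' f <- data.frame(case_id = c("a", "b", "b"), gene = c("G1", "G1", "G2"))
#' diagnostic_yield_summary(f, n_cases = 10)
#' @export
diagnostic_yield_summary <- function(findings, n_cases) {
  if (length(n_cases) != 1 || is.na(n_cases) || n_cases <= 0) {
    stop("n_cases must be a positive count", call. = FALSE)
  }
  if (nrow(findings) == 0) {
    return(list(n_carriers = 0L, yield_pct = 0, monoallelic_pct = NA_real_,
                class_props = numeric(0),
                gene_allele_counts = integer(0)))
  }
  stopifnot(all(c("case_id", "gene") %in% names(findings)))
  alleles_per_case <- table(findings$case_id)
  n_carriers <- length(alleles_per_case)
  yield_pct <- round(100 * n_carriers / n_cases, 2)
  monoallelic_pct <- round(100 * sum(alleles_per_case == 1) / n_carriers, 2)
  class_props <- if ("class" %in% names(findings)) {
    round(100 * prop.table(table(findings$class)), 2)
  } else numeric(0)
  gene_counts <- sort(table(findings$gene), decreasing = TRUE)
  list(n_carriers = n_carriers,
       yield_pct = yield_pct,
       monoallelic_pct = monoallelic_pct,
       class_props = c(class_props),
       gene_allele_counts = c(gene_counts))
}
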