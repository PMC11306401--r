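# Genotype- and variant-level quality control: per-call filters, site filters
# and the exact Hardy-Weinberg equilibrium test.

#' Construct a genotype matrix object
#'
#' Bundles a variant x sample dosage matrix with the per-call metrics used by
#' the call-level filters. All four matrices share dimensions and dimnames;
#' allele balance is defined only for heterozygous calls.
#'
#' @param dosage integer matrix (variants x samples) with values 0/1/2 or
#'   \code{NA} for missing.
#' @param dp,gq per-call depth and genotype-quality matrices (or \code{NULL}).
#' @param ab per-call alternate-allele balance in \code{[0, 1]} for
#'   heterozygous calls, \code{NA} elsewhere (or \code{NULL}).
#' @return object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosage, dp = NULL, gq = NULL, ab = NULL) {
  dosage <- as.matrix(dosage)
  chk <- function(m, what) {
    if (!is.null(m) && !identical(dim(m), dim(dosage))) {
      stop(what, " dimensions do not match dosage matrix", call. = FALSE)
    }
    m
  }
  structure(list(dosage = dosage, dp = chk(dp, "DP"), gq = chk(gq, "GQ"),
                 ab = chk(ab, "AB")),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variants x %d samples (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Per-call genotype filtering
#'
#' Sets individual genotype calls to missing when they fail any of:
#' depth DP >= 10, genotype quality GQ >= 20, or (for heterozygous calls)
#' allele balance within \code{[0.2, 0.8]}. Calls whose required metric is
#' itself missing are set to missing; the count of affected calls is reported
#' as a message.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param min_dp,min_gq,ab_range filter bounds; defaults 10, 20 and
#'   \code{c(0.2, 0.8)}.
#' @return the filtered \code{genotype_matrix}.
#' @export
filter_genotype_calls <- function(g, min_dp = 10, min_gq = 20,
                                  ab_range = c(0.2, 0.8)) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  present <- !is.na(d)
  bad <- matrix(FALSE, nrow(d), ncol(d))
  if (!is.null(g$dp)) bad <- bad | (present & (is.na(g$dp) | g$dp < min_dp))
  if (!is.null(g$gq)) bad <- bad | (present & (is.na(g$gq) | g$gq < min_gq))
  het <- present & d == 1L
  if (!is.null(g$ab)) {
    bad <- bad | (het & (is.na(g$ab) | g$ab < ab_range[1] | g$ab > ab_range[2]))
  }
  n_bad <- sum(bad, na.rm = TRUE)
  if (n_bad > 0) {
    message(sprintf("filter_genotype_calls: %d call(s) set to missing", n_bad))
    g$dosage[bad] <- NA_integer_
    if (!is.null(g$ab)) g$ab[bad] <- NA_real_
  }
  g
}

#' Variant-site filtering
#'
#' Applies the site-level exclusions in fixed priority order and reports the
#' first matching drop reason: low-complexity region, VQSR failure, call rate
#' below 90\%, Hardy-Weinberg exact test P below 1e-6.
#'
#' @param ann annotation data frame with logical columns \code{low_complexity}
#'   and \code{vqsr_pass} (one row per variant).
#' @param call_rate numeric vector of per-variant call rates in \code{[0, 1]}.
#' @param hwe_p numeric vector of per-variant HWE exact-test P values.
#' @param min_call_rate,hwe_threshold cutoffs; defaults 0.90 and 1e-6.
#' @return data frame with columns \code{variant_id}, \code{keep} and
#'   \code{reason} (\code{NA} for kept sites).
#' @export
filter_variant_sites <- function(ann, call_rate, hwe_p,
                                 min_call_rate = 0.90, hwe_threshold = 1e-6) {
  stopifnot(is.data.frame(ann),
            length(call_rate) == nrow(ann), length(hwe_p) == nrow(ann))
  if (any(call_rate < 0 | call_rate > 1, na.rm = TRUE)) {
    stop("call_rate must be in [0, 1]", call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(ann))
  reason[is.na(reason) & !is.na(hwe_p) & hwe_p < hwe_threshold] <- "hwe"
  reason[!is.na(call_rate) & call_rate < min_call_rate] <- "call_rate"
  reason[!is.na(ann$vqsr_pass) & !ann$vqsr_pass] <- "vqsr_fail"
  reason[!is.na(ann$low_complexity) & ann$low_complexity] <- "low_complexity"
  data.frame(variant_id = ann$variant_id, keep = is.na(reason),
             reason = reason, stringsAsFactors = FALSE)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on genotype counts at a biallelic site: given the
#' observed allele counts, the P value sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed configuration (no mid-P adjustment). Monomorphic sites return
#' P = 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative genotype counts.
#' @return exact two-sided P value in \code{[0, 1]}.
#' @examples
#' hwe_exact_test(25, 50, 25)
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("no genotypes supplied", call. = FALSE)
  n_alt <- n_het + 2 * n_hom_alt
  n_minor <- min(n_alt, 2 * n - n_alt)
  if (n_minor == 0) return(1)

  # possible heterozygote counts share the parity of the minor-allele count
  h <- seq(n_minor %% 2, n_minor, by = 2)
  hom_minor <- (n_minor - h) / 2
  hom_major <- n - h - hom_minor
  # log conditional probability up to a shared constant
  logp <- h * log(2) + lgamma(n + 1) -
    (lgamma(hom_major + 1) + lgamma(h + 1) + lgamma(hom_minor + 1))
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[match(n_het, h)]
  if (is.na(obs)) stop("observed heterozygote count impossible for allele count",
                       call. = FALSE)
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Per-variant HWE P values from a dosage matrix
#'
#' @param dosage variant x sample dosage matrix (0/1/2/NA).
#' @return numeric vector of exact HWE P values, one per variant.
#' @export
hwe_test_matrix <- function(dosage) {
  apply(as.matrix(dosage), 1L, function(d) {
    d <- d[!is.na(d)]
    if (length(d) == 0) return(NA_real_)
    hwe_exact_test(sum(d == 0L), sum(d == 1L), sum(d == 2L))
  })
}

#' Folded minor-allele frequency per variant
#'
#' Computed on non-missing alleles; "minor" is the folded frequency
#' \code{min(p, 1 - p)}.
#'
#' @param dosage variant x sample dosage matrix (0/1/2/NA).
#' @param fold return folded MAF (default) or raw alternate-allele frequency.
#' @return numeric vector of frequencies.
#' @export
allele_frequency <- function(dosage, fold = TRUE) {
  dosage <- as.matrix(dosage)
  n_called <- rowSums(!is.na(dosage))
  af <- rowSums(dosage, na.rm = TRUE) / (2 * n_called)
  af[n_called == 0] <- NA_real_
  if (fold) pmin(af, 1 - af) else af
}
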