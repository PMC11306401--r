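# Sample-level quality control and sex inference from X-chromosome
# heterozygosity.

#' Sample-level QC
#'
#' Applies hard thresholds first -- average call rate >= 0.9, mean sequencing
#' depth >= 10, mean genotype quality >= 65 -- then a single-pass 4-SD outlier
#' exclusion on the transition/transversion, heterozygous/homozygous and
#' insertion/deletion ratios. Outlier means and SDs are computed within the
#' cohort over samples passing the hard thresholds.
#'
#' @param stats data frame with one row per sample and columns
#'   \code{sample_id}, \code{call_rate}, \code{mean_depth}, \code{mean_gq},
#'   \code{titv}, \code{het_hom}, \code{ins_del} (ratio columns may be
#'   \code{NA} when undefined for a sample).
#' @param sd_limit outlier cutoff in SD units, default 4.
#' @return data frame with columns \code{sample_id}, \code{keep},
#'   \code{reasons} (comma-separated, \code{NA} when kept).
#' @export
sample_qc <- function(stats, sd_limit = 4) {
  need <- c("sample_id", "call_rate", "mean_depth", "mean_gq",
            "titv", "het_hom", "ins_del")
  missing_cols <- setdiff(need, names(stats))
  if (length(missing_cols)) {
    stop("sample stats missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  reasons <- vector("list", nrow(stats))
  add <- function(idx, tag) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], tag)
  }
  add(!is.na(stats$call_rate) & stats$call_rate < 0.9, "call_rate")
  add(!is.na(stats$mean_depth) & stats$mean_depth < 10, "mean_depth")
  add(!is.na(stats$mean_gq) & stats$mean_gq < 65, "mean_gq")
  hard_pass <- lengths(reasons) == 0

  if (sum(hard_pass) < 3) {
    warning("fewer than 3 samples pass hard thresholds; ",
            "ratio-outlier step skipped")
  } else {
    for (ratio in c("titv", "het_hom", "ins_del")) {
      x <- stats[[ratio]]
      m <- mean(x[hard_pass], na.rm = TRUE)
      s <- stats::sd(x[hard_pass], na.rm = TRUE)
      if (!is.finite(s) || s == 0) next
      add(hard_pass & !is.na(x) & abs(x - m) > sd_limit * s,
          paste0(ratio, "_outlier"))
    }
  }
  data.frame(
    sample_id = stats$sample_id,
    keep = lengths(reasons) == 0,
    reasons = vapply(reasons, function(r) {
      if (length(r)) paste(r, collapse = ",") else NA_character_
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Infer genetic sex from X-chromosome heterozygosity
#'
#' Computes, per sample, the X-chromosome inbreeding coefficient
#' F = 1 - observed_het / expected_het, where the expected heterozygosity sums
#' 2p(1-p) over the sample's non-missing X variants (allele frequencies
#' estimated from the full cohort). Classification follows strict cutoffs:
#' F > 0.8 male, F < 0.4 female, otherwise excluded (ambiguous). The boundary
#' values 0.8 and 0.4 therefore fall in "excluded".
#'
#' @param x_dosage variant x sample dosage matrix (0/1/2/NA) restricted to
#'   X-chromosome sites.
#' @return data frame with columns \code{sample_id}, \code{f} and
#'   \code{sex} in \code{c("male", "female", "excluded")}.
#' @export
infer_sex <- function(x_dosage) {
  x_dosage <- as.matrix(x_dosage)
  if (nrow(x_dosage) == 0) stop("no X-chromosome variants", call. = FALSE)
  p <- allele_frequency(x_dosage, fold = FALSE)
  exp_het_site <- 2 * p * (1 - p)
  poly <- !is.na(p) & exp_het_site > 0
  samples <- colnames(x_dosage)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(x_dosage)))
  f <- rep(NA_real_, ncol(x_dosage))
  if (!any(poly)) {
    warning("no polymorphic X variants; all samples excluded")
  } else {
    d <- x_dosage[poly, , drop = FALSE]
    eh <- exp_het_site[poly]
    called <- !is.na(d)
    obs_het <- colSums(d == 1L, na.rm = TRUE)
    exp_het <- colSums(called * eh)
    ok <- exp_het > 0
    f[ok] <- 1 - obs_het[ok] / exp_het[ok]
    if (any(!ok)) warning("sample(s) with no usable X calls excluded")
  }
  sex <- rep("excluded", length(f))
  sex[!is.na(f) & f > 0.8] <- "male"
  sex[!is.na(f) & f < 0.4] <- "female"
  data.frame(sample_id = samples, f = f, sex = sex, stringsAsFactors = FALSE)
}
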