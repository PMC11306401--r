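# Qualifying-variant classification: four mutually exclusive coding classes
# (PTV, damaging missense, benign missense, synonymous) plus OTHER.

#' Consequence terms counted as protein-truncating
#'
#' Sequence-Ontology terms treated as protein-truncating variants (PTVs):
#' frameshift, splice acceptor/donor, stop-gained and start-lost.
#' @export
PTV_CONSEQUENCES <- c(
  "frameshift_variant", "splice_acceptor_variant", "splice_donor_variant",
  "stop_gained", "start_lost"
)

#' Consequence terms treated as missense-family
#'
#' Terms eligible for the damaging/benign missense split: in-frame indels,
#' missense and stop-lost variants.
#' @export
MISSENSE_CONSEQUENCES <- c(
  "inframe_deletion", "inframe_insertion", "missense_variant", "stop_lost"
)

#' Classify variant consequences into qualifying-variant classes
#'
#' Assigns each variant exactly one of five labels:
#' \describe{
#'   \item{PTV}{one of the five protein-truncating consequence terms
#'     (\code{\link{PTV_CONSEQUENCES}}).}
#'   \item{D_MIS}{missense-family consequence predicted \emph{probably
#'     damaging} by PolyPhen-2 \strong{and} \emph{deleterious} by SIFT
#'     \strong{and} CADD > 20. All three conditions are required; a missing
#'     predictor disqualifies the variant from D_MIS.}
#'   \item{B_MIS}{missense-family consequence that is either (\emph{tolerated}
#'     by SIFT \strong{and} \emph{benign} by PolyPhen-2) \strong{or} has
#'     CADD < 15. The CADD route alone suffices when the categorical
#'     predictors are missing.}
#'   \item{SYNONYMOUS}{\code{synonymous_variant}.}
#'   \item{OTHER}{anything else, including missense-family variants that meet
#'     neither rule set.}
#' }
#'
#' @param consequence character vector of Sequence-Ontology consequence terms.
#' @param polyphen PolyPhen-2 category: \code{"probably_damaging"},
#'   \code{"possibly_damaging"}, \code{"benign"} or \code{NA}.
#' @param sift SIFT category: \code{"deleterious"}, \code{"tolerated"} or
#'   \code{NA}.
#' @param cadd_phred PHRED-scaled CADD score, \code{NA} when unavailable.
#' @return character vector of labels in
#'   \code{c("PTV","D_MIS","B_MIS","SYNONYMOUS","OTHER")}.
#' @examples
#' classify_consequence("stop_gained")
#' classify_consequence("missense_variant", "probably_damaging",
#'                      "deleterious", 25)
#' @export
classify_consequence <- function(consequence, polyphen = NA_character_,
                                 sift = NA_character_,
                                 cadd_phred = NA_real_) {
  if (length(consequence) == 0L) return(character(0))
  if (anyNA(consequence) || any(!nzchar(consequence))) {
    stop("missing or empty consequence term", call. = FALSE)
  }
  n <- length(consequence)
  polyphen <- rep_len(as.character(polyphen), n)
  sift <- rep_len(as.character(sift), n)
  cadd_phred <- rep_len(as.numeric(cadd_phred), n)

  out <- rep("OTHER", n)
  out[consequence %in% PTV_CONSEQUENCES] <- "PTV"
  out[consequence == "synonymous_variant"] <- "SYNONYMOUS"

  mis <- consequence %in% MISSENSE_CONSEQUENCES
  dmis <- mis &
    !is.na(polyphen) & polyphen == "probably_damaging" &
    !is.na(sift) & sift == "deleterious" &
    !is.na(cadd_phred) & cadd_phred > 20
  bmis_cat <- mis &
    !is.na(polyphen) & polyphen == "benign" &
    !is.na(sift) & sift == "tolerated"
  bmis_cadd <- mis & !is.na(cadd_phred) & cadd_phred < 15
  out[bmis_cat | bmis_cadd] <- "B_MIS"
  out[dmis] <- "D_MIS"
  out
}

#' Test whether a variant is rare in the cohort and all reference panels
#'
#' A qualifying variant must have folded minor-allele frequency below
#' \code{threshold} (default 0.5\%) in the study cohort \emph{and} in every
#' supplied reference panel. A missing panel frequency is treated as 0
#' (absent from the panel).
#'
#' @param cohort_af cohort alternate-allele frequency in \code{[0, 1]}.
#' @param ref_afs numeric vector (possibly named) of reference-panel allele
#'   frequencies; \code{NA} entries count as 0.
#' @param threshold MAF cutoff, default 0.005.
#' @return logical scalar.
#' @export
is_rare <- function(cohort_af, ref_afs = numeric(0), threshold = 0.005) {
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  if (is.na(cohort_af) || cohort_af < 0 || cohort_af > 1) {
    stop("cohort_af must be in [0, 1]", call. = FALSE)
  }
  fold <- function(p) pmin(p, 1 - p)
  refs <- as.numeric(ref_afs)
  refs[is.na(refs)] <- 0
  fold(cohort_af) < threshold && all(fold(refs) < threshold)
}

#' Classify an annotation table into qualifying-variant classes
#'
#' Convenience wrapper applying \code{\link{classify_consequence}} and
#' \code{\link{is_rare}} to an annotation table in the package's TSV dialect
#' (see \code{\link{read_annotation_table}}).
#'
#' @param ann annotation data frame with columns \code{variant_id},
#'   \code{consequence}, \code{polyphen}, \code{sift}, \code{cadd_phred} and
#'   reference-frequency columns \code{af_gnomad}, \code{af_1kg}, \code{af_esp}.
#' @param cohort_af numeric vector of cohort allele frequencies, parallel to
#'   \code{ann}; \code{NULL} skips the rarity call.
#' @param maf_threshold MAF cutoff for \code{\link{is_rare}}.
#' @return \code{ann} with added columns \code{class} and (when
#'   \code{cohort_af} is given) \code{rare}.
#' @export
classify_variants <- function(ann, cohort_af = NULL, maf_threshold = 0.005) {
  stopifnot(is.data.frame(ann))
  ann$class <- classify_consequence(ann$consequence, ann$polyphen, ann$sift,
                                    ann$cadd_phred)
  if (!is.null(cohort_af)) {
    refs <- cbind(af_gnomad = ann$af_gnomad, af_1kg = ann$af_1kg,
                  af_esp = ann$af_esp)
    ann$rare <- vapply(seq_len(nrow(ann)), function(i) {
      if (is.na(cohort_af[i])) return(NA)   # no called genotypes
      is_rare(cohort_af[i], refs[i, ], maf_threshold)
    }, logical(1))
  }
  ann
}
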