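# Ancestry principal components on common variants and nearest-neighbour
# control matching in PC space.

#' Ancestry principal components from common genotypes
#'
#' Restricts to variants with folded MAF above \code{maf_min} (default 1\%),
#' centres each variant at its expected dosage 2p and standardises by
#' \code{sqrt(2p(1-p))} (missing dosages imputed at the variant mean), then
#' extracts sample scores by singular-value decomposition. PCs are ordered by
#' decreasing eigenvalue and each PC's sign is fixed so its largest-magnitude
#' variant loading is positive.
#'
#' @param dosage variant x sample dosage matrix (0/1/2/NA).
#' @param n_pcs number of components requested, default 10.
#' @param maf_min folded-MAF lower bound for inclusion, default 0.01.
#' @return sample x PC numeric matrix (columns \code{PC1..}); attribute
#'   \code{eigenvalues} carries the corresponding eigenvalues.
#' @export
compute_ancestry_pcs <- function(dosage, n_pcs = 10, maf_min = 0.01) {
  dosage <- as.matrix(dosage)
  maf <- allele_frequency(dosage, fold = TRUE)
  keep <- !is.na(maf) & maf > maf_min
  if (sum(keep) < n_pcs) {
    warning(sprintf("only %d common variants available for %d requested PCs",
                    sum(keep), n_pcs))
  }
  d <- dosage[keep, , drop = FALSE]
  p <- allele_frequency(d, fold = FALSE)
  mu <- 2 * p
  sdv <- sqrt(2 * p * (1 - p))
  x <- (d - mu) / sdv
  x[is.na(x)] <- 0            # mean imputation after standardisation
  x <- x[sdv > 0, , drop = FALSE]

  sv <- svd(t(x))             # samples x variants
  pos <- sv$d > max(sv$d) * 1e-8
  k <- min(n_pcs, sum(pos), ncol(sv$u))
  if (k < n_pcs) warning(sprintf("degenerate matrix: returning %d PC(s)", k))
  if (k == 0) {
    scores <- matrix(0, ncol(dosage), min(n_pcs, ncol(dosage) - 1L))
    if (ncol(scores) == 0) scores <- matrix(0, ncol(dosage), 1L)
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
    rownames(scores) <- colnames(dosage)
    attr(scores, "eigenvalues") <- rep(0, ncol(scores))
    return(scores)
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  load <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- colnames(dosage)
  attr(scores, "eigenvalues") <- sv$d[seq_len(k)]^2 / (ncol(dosage) - 1L)
  scores
}

#' Greedy nearest-neighbour control matching in PC space
#'
#' For each case, in input order, selects the unused control with smallest
#' Euclidean distance in the top \code{k_pcs} principal components (without
#' replacement). Distance ties are broken by the lexicographically smallest
#' control id, so matching is deterministic given the case ordering.
#'
#' @param case_pcs,control_pcs numeric matrices of PC scores with sample ids
#'   as row names.
#' @param k_pcs number of leading PCs used, default 3.
#' @return character vector of matched control ids, one per case, named by
#'   case id.
#' @export
match_controls <- function(case_pcs, control_pcs, k_pcs = 3) {
  case_pcs <- as.matrix(case_pcs)
  control_pcs <- as.matrix(control_pcs)
  if (k_pcs > ncol(case_pcs) || k_pcs > ncol(control_pcs)) {
    stop("k_pcs exceeds available PCs", call. = FALSE)
  }
  if (nrow(control_pcs) < nrow(case_pcs)) {
    stop("fewer controls than cases", call. = FALSE)
  }
  ids <- rownames(control_pcs)
  if (is.null(ids)) ids <- paste0("C", seq_len(nrow(control_pcs)))
  cs <- case_pcs[, seq_len(k_pcs), drop = FALSE]
  ct <- control_pcs[, seq_len(k_pcs), drop = FALSE]
  ord <- order(ids)            # tie-break: lowest control id wins
  ct <- ct[ord, , drop = FALSE]
  ids <- ids[ord]
  used <- rep(FALSE, length(ids))
  out <- character(nrow(cs))
  for (i in seq_len(nrow(cs))) {
    d2 <- colSums((t(ct) - cs[i, ])^2)
    d2[used] <- Inf
    j <- which.min(d2)         # which.min returns the first (lowest id) tie
    out[i] <- ids[j]
    used[j] <- TRUE
  }
  names(out) <- rownames(case_pcs)
  out
}
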