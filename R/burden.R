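# Burden association tests: per-unit Fisher / Firth dispatch, gene-set scan
# with BH FDR, length-matched resampling null, exome-wide collapsing scan
# with permutation-based expected P distribution, and genomic control.

covariate_matrix <- function(design, covariates) {
  cols <- unlist(lapply(covariates, function(cv) {
    if (cv == "pcs") grep("^PC[0-9]+$", names(design), value = TRUE) else cv
  }))
  missing_cols <- setdiff(cols, names(design))
  if (length(missing_cols)) {
    stop("design lacks covariate column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!length(cols)) return(NULL)
  m <- as.matrix(as.data.frame(lapply(design[cols], function(x) {
    if (is.numeric(x)) x else as.numeric(factor(x)) - 1
  })))
  colnames(m) <- cols
  m
}

design_status <- function(design) {
  s <- design$status
  if (is.numeric(s)) {
    stopifnot(all(s %in% c(0, 1)))
    return(s)
  }
  as.integer(tolower(as.character(s)) == "case")
}

#' Burden test for one unit (gene or gene set)
#'
#' Tests association between carrying at least one qualifying allele in the
#' unit and case status, by either a two-sided Fisher's exact test on the
#' carrier 2x2 table or Firth penalized logistic regression of status on the
#' carrier indicator plus covariates (P by penalized LRT).
#'
#' @param carrier numeric 0/1 carrier vector named by sample id (a row of a
#'   \code{\link{build_carrier_matrix}} result).
#' @param design cohort design data frame with columns \code{sample_id},
#'   \code{status} (case/control or 1/0) and covariate columns.
#' @param test \code{"fet"} or \code{"firth"}.
#' @param covariates character vector of design columns to adjust for in the
#'   Firth model; \code{"pcs"} expands to all \code{PC} columns. Default
#'   \code{c("sex", "pcs", "total_exome_count")}, the most conservative model.
#' @param unit unit label carried into the result.
#' @return one-row data frame with columns \code{unit},
#'   \code{n_case_carriers}, \code{n_control_carriers}, \code{or},
#'   \code{beta}, \code{se}, \code{p}, \code{ci_lo}, \code{ci_hi},
#'   \code{test}, \code{model}, \code{null_flag}.
#' @export
unit_burden_test <- function(carrier, design, test = c("firth", "fet"),
                             covariates = c("sex", "pcs",
                                            "total_exome_count"),
                             unit = "unit") {
  test <- match.arg(test)
  y <- design_status(design)
  if (!is.null(names(carrier)) && !is.null(design$sample_id)) {
    carrier <- carrier[match(design$sample_id, names(carrier))]
  }
  stopifnot(length(carrier) == length(y))
  x <- as.numeric(carrier > 0)
  a <- sum(x == 1 & y == 1); b <- sum(x == 0 & y == 1)
  cc <- sum(x == 1 & y == 0); d <- sum(x == 0 & y == 0)

  res <- data.frame(unit = unit, n_case_carriers = a, n_control_carriers = cc,
                    or = NA_real_, beta = NA_real_, se = NA_real_,
                    p = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                    test = test, model = "", null_flag = FALSE,
                    stringsAsFactors = FALSE)
  if (a + cc == 0) {
    res$null_flag <- TRUE
    res$p <- 1
    return(res)
  }

  if (test == "fet") {
    ft <- fisher_exact_2x2(a, b, cc, d)
    res$or <- ft$or; res$beta <- ft$log_or; res$se <- ft$se_log_or
    res$p <- ft$p; res$ci_lo <- ft$ci[1]; res$ci_hi <- ft$ci[2]
    res$model <- "carrier 2x2"
  } else {
    covm <- covariate_matrix(design, covariates)
    X <- cbind(intercept = 1, carrier = x, covm)
    fit <- firth_logistic_fit(y, X, test = "carrier")
    res$or <- fit$or; res$beta <- fit$beta[["carrier"]]
    res$se <- fit$se[["carrier"]]
    res$p <- fit$p_lrt; res$ci_lo <- fit$ci95[1]; res$ci_hi <- fit$ci95[2]
    res$model <- paste(c("carrier", colnames(covm)), collapse = "+")
  }
  res
}

#' Gene-set burden scan with BH false-discovery control
#'
#' Per-set two-sided Fisher's exact test of qualifying-variant carriage
#' (carrier of any member gene) against case status, followed by
#' Benjamini-Hochberg FDR across the scanned collection. Results are sorted by
#' P value.
#'
#' @param sets named list of character gene vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param gene_carriers gene x sample carrier matrix
#'   (\code{\link{build_carrier_matrix}} with per-gene units) for the variant
#'   class under test (typically PTVs).
#' @param design cohort design data frame.
#' @return data frame of per-set results with an \code{fdr} column.
#' @export
geneset_scan <- function(sets, gene_carriers, design) {
  if (!length(sets)) stop("empty gene-set collection", call. = FALSE)
  keep <- vapply(sets, length, integer(1)) > 0
  if (any(!keep)) warning(sum(!keep), " empty set(s) skipped")
  sets <- sets[keep]
  genes <- rownames(gene_carriers)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], genes)
    carrier <- if (length(members)) {
      as.numeric(colSums(gene_carriers[members, , drop = FALSE]) > 0)
    } else rep(0, ncol(gene_carriers))
    names(carrier) <- colnames(gene_carriers)
    r <- unit_burden_test(carrier, design, test = "fet", unit = nm)
    r$n_genes <- length(members)
    r
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Length-matched resampling null for a gene set
#'
#' Draws \code{B} random gene sets of the same size whose composition matches
#' the target set across deciles of coding length, recomputes the set-level
#' burden statistic (the Fisher log odds ratio) for each draw, and reports the
#' empirical P value \code{(1 + #{resampled >= observed}) / (B + 1)}.
#'
#' @param set_genes character vector: the target gene set.
#' @param gene_lengths named numeric vector of coding lengths for every gene
#'   eligible for resampling.
#' @param gene_carriers gene x sample carrier matrix.
#' @param design cohort design data frame.
#' @param B number of resamples, default 1000.
#' @param seed RNG seed (required; no global state is consumed).
#' @return list of class \code{empirical_null}: \code{observed},
#'   \code{resampled} (length B), \code{empirical_p}, \code{B}.
#' @export
length_matched_empirical_p <- function(set_genes, gene_lengths, gene_carriers,
                                       design, B = 1000, seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  pool <- names(gene_lengths)
  set_genes <- intersect(set_genes, pool)
  if (!length(set_genes)) stop("no target genes with lengths", call. = FALSE)
  y <- design_status(design)

  stat <- function(genes) {
    members <- intersect(genes, rownames(gene_carriers))
    if (!length(members)) return(0)
    x <- colSums(gene_carriers[members, , drop = FALSE]) > 0
    a <- sum(x & y == 1); b <- sum(!x & y == 1)
    cc <- sum(x & y == 0); d <- sum(!x & y == 0)
    log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (cc + 0.5)))
  }

  breaks <- unique(stats::quantile(gene_lengths, probs = seq(0, 1, 0.1)))
  bin <- cut(gene_lengths, breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  names(bin) <- pool
  target_bins <- table(bin[set_genes])

  rng <- local_rng(seed)
  resampled <- vapply(seq_len(B), function(b) {
    draw <- unlist(lapply(names(target_bins), function(bl) {
      candidates <- pool[bin == as.integer(bl)]
      k <- target_bins[[bl]]
      if (length(candidates) < k) {
        warning("length decile smaller than target; sampling with replacement")
        sample(candidates, k, replace = TRUE)
      } else sample(candidates, k)
    }))
    stat(draw)
  }, numeric(1))
  on.exit(rng(), add = TRUE)

  observed <- stat(set_genes)
  structure(list(observed = observed, resampled = resampled, B = B,
                 empirical_p = (1 + sum(resampled >= observed)) / (B + 1)),
            class = "empirical_null")
}

#' Exome-wide gene-based collapsing scan
#'
#' Per-gene two-sided Fisher's exact carrier test, the Bonferroni
#' exome-wide significance threshold (0.05 divided by the number of genes with
#' at least one qualifying variant), and an expected P-value distribution for
#' QQ plotting obtained by permuting case-control labels \code{B_perm} times,
#' ordering each permutation's P values, and averaging across permutations.
#'
#' @param gene_carriers gene x sample carrier matrix restricted to genes with
#'   at least one qualifying variant.
#' @param design cohort design data frame.
#' @param B_perm number of label permutations (default 1000); 0 skips the
#'   expected-distribution step.
#' @param seed RNG seed, required when \code{B_perm > 0}.
#' @return list with \code{results} (per-gene data frame sorted by P),
#'   \code{bonferroni} threshold, \code{n_genes}, and \code{expected_p}
#'   (rank-ordered expected P values, or \code{NULL}).
#' @export
collapsing_scan <- function(gene_carriers, design, B_perm = 1000, seed) {
  y <- design_status(design)
  n_case <- sum(y == 1); n_ctrl <- sum(y == 0)
  x <- gene_carriers > 0
  case_carriers <- as.vector(x %*% (y == 1))
  all_carriers <- rowSums(x)

  fet_cache <- new.env(parent = emptyenv(), hash = TRUE)
  fet_p <- function(a, k) {
    key <- paste0(a, "_", k)
    p <- fet_cache[[key]]
    if (is.null(p)) {
      p <- fisher_exact_2x2(a, n_case - a, k - a, n_ctrl - (k - a))$p
      fet_cache[[key]] <- p
    }
    p
  }

  pv <- mapply(fet_p, case_carriers, all_carriers)
  ors <- mapply(function(a, k) {
    fisher_exact_2x2(a, n_case - a, k - a, n_ctrl - (k - a))$or
  }, case_carriers, all_carriers)
  results <- data.frame(gene = rownames(gene_carriers),
                        n_case_carriers = case_carriers,
                        n_control_carriers = all_carriers - case_carriers,
                        or = ors, p = pv, stringsAsFactors = FALSE)
  results <- results[order(results$p), , drop = FALSE]

  expected <- NULL
  if (B_perm > 0) {
    if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
    rng <- local_rng(seed)
    on.exit(rng(), add = TRUE)
    acc <- numeric(nrow(results))
    for (b in seq_len(B_perm)) {
      yp <- sample(y)
      ap <- as.vector(x %*% (yp == 1))
      pp <- mapply(fet_p, ap, all_carriers)
      acc <- acc + sort(pp)
    }
    expected <- acc / B_perm
  }
  list(results = results,
       bonferroni = 0.05 / nrow(gene_carriers),
       n_genes = nrow(gene_carriers),
       expected_p = expected)
}

#' Genomic-control inflation factor
#'
#' \eqn{\lambda_{GC}} is the median of the observed 1-df chi-square statistics
#' divided by the theoretical null median (\code{qchisq(0.5, 1)}, about
#' 0.456). When \eqn{\lambda > 1}, statistics are deflated by \eqn{\lambda};
#' otherwise they are returned unchanged.
#'
#' @param p numeric vector of P values (converted to 1-df chi-square), or
#'   \code{NULL} if \code{chisq} is given.
#' @param chisq numeric vector of 1-df chi-square statistics.
#' @return list with \code{lambda}, \code{chisq_adj}, \code{p_adj}.
#' @export
genomic_control_lambda <- function(p = NULL, chisq = NULL) {
  if (is.null(chisq)) {
    if (is.null(p) || length(p) == 0) stop("no statistics supplied",
                                           call. = FALSE)
    chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  }
  if (length(chisq) < 10) stop("need at least 10 statistics", call. = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  adj <- if (lambda > 1) chisq / lambda else chisq
  list(lambda = lambda, chisq_adj = adj,
       p_adj = stats::pchisq(adj, df = 1, lower.tail = FALSE))
}

# Seeded RNG scoped to a function: returns a restore function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
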