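# Two-sided Fisher's exact test on a 2x2 table with sample odds ratio and
# log-OR normal-approximation confidence interval.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The table is
#' \preformatted{
#'            exposed  unexposed
#'   cases       a         b
#'   controls    c         d
#' }
#' The two-sided P value follows the minimum-likelihood convention: it sums
#' the conditional hypergeometric probabilities of all tables (with the
#' observed margins) whose probability does not exceed that of the observed
#' table. The odds ratio reported is the sample OR \code{(a*d)/(b*c)}; when
#' any cell is zero a Haldane-Anscombe correction of 0.5 is added to every
#' cell for the OR and its CI (flagged in the result). The 95\% CI uses the
#' normal approximation on the log-OR scale.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param conf_level confidence level for the CI, default 0.95.
#' @return list with elements \code{or}, \code{p}, \code{ci} (length-2),
#'   \code{log_or}, \code{se_log_or}, \code{haldane} (logical).
#' @examples
#' fisher_exact_2x2(8, 441, 11, 9595)
#' @export
fisher_exact_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  r1 <- a + b; r2 <- c + d; k <- a + c
  if (r1 + r2 == 0 || (r1 * r2 == 0) || (k == 0 && b + d == 0)) {
    stop("degenerate table: a margin is zero", call. = FALSE)
  }

  # conditional distribution of the (1,1) cell given fixed margins
  support <- max(0L, k - r2):min(k, r1)
  probs <- stats::dhyper(support, r1, r2, k)
  p_obs <- probs[match(a, support)]
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))

  haldane <- any(cells == 0)
  cc <- if (haldane) cells + 0.5 else cells
  log_or <- log(cc[1]) + log(cc[4]) - log(cc[2]) - log(cc[3])
  se <- sqrt(sum(1 / cc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  or <- if (haldane) exp(log_or) else (a * d) / (b * c)
  list(or = or, p = p,
       ci = exp(log_or + c(-1, 1) * z * se),
       log_or = log_or, se_log_or = se, haldane = haldane)
}
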