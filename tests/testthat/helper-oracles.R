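# Independent brute-force oracles used to validate the analytic routines.
# Each oracle takes a different arithmetic route than the implementation.

# Two-sided Fisher exact P by explicit enumeration over the (1,1) cell using
# choose() ratios (implementation uses dhyper).
fet_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  support <- max(0, k - r2):min(k, r1)
  probs <- vapply(support, function(x) {
    choose(r1, x) * choose(r2, k - x) / choose(n, k)
  }, numeric(1))
  obs <- probs[support == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact HWE P by the Wigginton-style recurrence on heterozygote counts
# (implementation uses lgamma directly).
hwe_enum_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_alt <- n_ab + 2 * n_bb
  n_minor <- min(n_alt, 2 * n - n_alt)
  if (n_minor == 0) return(1)
  hs <- seq(n_minor %% 2, n_minor, by = 2)
  probs <- numeric(length(hs))
  probs[1] <- 1
  if (length(hs) > 1) {
    for (i in seq_len(length(hs) - 1)) {
      h <- hs[i]
      hom_minor <- (n_minor - h) / 2
      hom_major <- n - h - hom_minor
      # ratio P(h+2)/P(h) from the conditional distribution
      probs[i + 1] <- probs[i] *
        (4 * hom_minor * hom_major) / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[hs == n_ab]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# Grid maximization of the Jeffreys-penalized log-likelihood for a
# 2-parameter (intercept + slope) logistic model; coarse-to-fine refinement.
firth_grid_oracle <- function(y, x, half_width = 8, levels = 12) {
  pll <- function(b0, b1) {
    eta <- b0 + b1 * x
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    X <- cbind(1, x)
    info <- crossprod(X * sqrt(w))
    dt <- det(info)
    if (dt <= 0) return(-Inf)
    sum(y * eta - log1p(exp(eta))) + 0.5 * log(dt)
  }
  centre <- c(0, 0)
  width <- half_width
  for (lv in seq_len(levels)) {
    b0s <- seq(centre[1] - width, centre[1] + width, length.out = 21)
    b1s <- seq(centre[2] - width, centre[2] + width, length.out = 21)
    vals <- outer(b0s, b1s, Vectorize(pll))
    ij <- arrayInd(which.max(vals), dim(vals))
    centre <- c(b0s[ij[1]], b1s[ij[2]])
    width <- width / 5
  }
  centre
}
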