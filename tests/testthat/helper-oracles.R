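# Independent oracles, written against the defining formulas with different
# machinery than the implementations they check.

# Weighted least squares through the origin via stats::lm (QR path).
oracle_wls_origin <- function(gx, gy, sy) {
  w <- 1 / sy^2
  fit <- stats::lm(gy ~ gx - 1, weights = w)
  s <- summary(fit)
  list(
    beta = unname(stats::coef(fit)[1]),
    se_fixed = unname(s$coefficients[1, 2] / s$sigma),
    q = sum(w * stats::residuals(fit)^2)
  )
}

# Weighted least squares with intercept via stats::lm.
oracle_wls_intercept <- function(gx, gy, sy) {
  fit <- stats::lm(gy ~ gx, weights = 1 / sy^2)
  stats::coef(fit)
}

# Brute-force greedy clump: recompute everything from first principles at
# each step, no precomputed ordering or submatrix bookkeeping.
oracle_clump <- function(pval, pos, ids, r, r2_max, p_max = NULL) {
  stopifnot(identical(rownames(r), ids))
  alive <- rep(TRUE, length(ids))
  if (!is.null(p_max)) alive <- alive & pval <= p_max
  retained <- character(0)
  repeat {
    if (!any(alive)) break
    cand <- which(alive)
    best <- cand[order(pval[cand], pos[cand], ids[cand])][1]
    retained <- c(retained, ids[best])
    for (k in which(alive)) {
      if (r[best, k]^2 >= r2_max) alive[k] <- FALSE
    }
    alive[best] <- FALSE
  }
  retained
}

# Random instrument frame for estimator tests.
random_instruments <- function(j, beta = 0.5, sd_gx = 1, sd_noise = 0.2) {
  gx <- rnorm(j, 0, sd_gx)
  sy <- abs(rnorm(j, 0, 0.5)) + 0.1
  sx <- abs(rnorm(j, 0, 0.1)) + 0.05
  gy <- beta * gx + rnorm(j, 0, sd_noise)
  tibble::tibble(
    exposure_beta = gx, exposure_se = sx,
    outcome_beta = gy, outcome_se = sy
  )
}

# Random positive-definite correlation matrix of dimension n.
random_corr <- function(n) {
  a <- matrix(rnorm(n * n), n)
  s <- crossprod(a) + diag(n) * 0.5
  d <- 1 / sqrt(diag(s))
  r <- s * tcrossprod(d)
  diag(r) <- 1
  r
}
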