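# Two-sample MR estimators.
#
# Notation: for instrument j, gamma_j / sigma_Xj are the exposure
# association and SE, Gamma_j / sigma_Yj the outcome association and SE,
# theta_j = Gamma_j / gamma_j the per-variant ratio estimate, and
# w_j = gamma_j^2 / sigma_Yj^2 the inverse-variance weight. All estimators
# are written out from the defining formulas; weighted least squares via
# stats::lm appears only as an independent oracle in the test-suite.

instrument_frame <- function(x, min_variants = 1L, what = "estimator") {
  x <- as_tibble(x)
  needed <- c("exposure_beta", "exposure_se", "outcome_beta", "outcome_se")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort_usage(paste0(
      "instrument set lacks column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(x) < min_variants) {
    abort_usage(sprintf(
      "%s needs at least %d instrument(s), got %d", what, min_variants, nrow(x)
    ))
  }
  x
}

new_mr_estimate <- function(method, beta, se, n_variants, q_stat = NA_real_,
                            q_df = NA_integer_, q_pval = NA_real_,
                            egger_intercept = NA_real_,
                            egger_intercept_se = NA_real_,
                            egger_intercept_p = NA_real_) {
  z <- qnorm(0.975)
  structure(
    list(
      method = method,
      beta = beta,
      se = se,
      ci_low = beta - z * se,
      ci_high = beta + z * se,
      pval = wald_pvalue(beta, se),
      n_variants = as.integer(n_variants),
      q_stat = q_stat,
      q_df = q_df,
      q_pval = q_pval,
      egger_intercept = egger_intercept,
      egger_intercept_se = egger_intercept_se,
      egger_intercept_p = egger_intercept_p
    ),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "<mr_estimate> %s: beta = %.4g (se %.4g, 95%% CI %.4g to %.4g, p = %.3g), %d variant(s)\n",
    x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_variants
  ))
  if (!is.na(x$q_stat)) {
    cat(sprintf("  heterogeneity: Q = %.4g on %d df (p = %.3g)\n",
                x$q_stat, x$q_df, x$q_pval))
  }
  if (x$method == "egger") {
    cat(sprintf("  intercept: %.4g (se %.4g, p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  }
  invisible(x)
}

#' Ratio (Wald) estimate from a single instrument
#'
#' `beta = Gamma / gamma` with first-order delta-method standard error
#' `se = sigma_Y / |gamma|`. Second-order terms are not included.
#'
#' @param x A one-row `harmonized_set` (or data frame with `exposure_beta`,
#'   `exposure_se`, `outcome_beta`, `outcome_se`).
#' @return An `mr_estimate` with method `"ratio"`.
#' @export
mr_ratio <- function(x) {
  x <- instrument_frame(x, 1L, "ratio estimate")
  if (nrow(x) != 1L) {
    abort_usage("ratio estimate takes exactly one instrument")
  }
  if (x$exposure_beta == 0) {
    abort_domain("exposure beta is zero: ratio estimate undefined")
  }
  new_mr_estimate(
    "ratio",
    beta = x$outcome_beta / x$exposure_beta,
    se = x$outcome_se / abs(x$exposure_beta),
    n_variants = 1L
  )
}

#' Inverse-variance weighted estimate
#'
#' Weighted least squares of the outcome associations on the exposure
#' associations through the origin with weights `1/sigma_Yj^2`:
#' `beta = sum(gamma_j Gamma_j / sigma_Yj^2) / sum(gamma_j^2 / sigma_Yj^2)`.
#' The fixed-effect standard error is `(sum w_j)^(-1/2)`; the multiplicative
#' random-effects model (`"mre"`, the default) scales it by
#' `max(1, sqrt(Q / (J - 1)))` where Q is Cochran's statistic. With a single
#' instrument the result reduces to [mr_ratio()].
#'
#' @param x A `harmonized_set` (or compatible data frame) with at least one
#'   instrument.
#' @param model `"mre"` (multiplicative random effects, default) or `"fe"`
#'   (fixed effect).
#' @return An `mr_estimate` with method `"ivw_mre"`, `"ivw_fixed"`, or
#'   `"ratio"` for a single instrument.
#' @export
mr_ivw <- function(x, model = c("mre", "fe")) {
  model <- match.arg(model)
  x <- instrument_frame(x, 1L, "IVW")
  if (nrow(x) == 1L) {
    return(mr_ratio(x))
  }
  gx <- x$exposure_beta
  gy <- x$outcome_beta
  sy <- x$outcome_se
  sw <- sum(gx^2 / sy^2)
  if (sw == 0) {
    abort_domain("all exposure betas are zero: IVW undefined")
  }
  beta <- sum(gx * gy / sy^2) / sw
  se_fixed <- 1 / sqrt(sw)
  j <- nrow(x)
  q <- sum((gy - beta * gx)^2 / sy^2)
  q_df <- j - 1L
  scale <- if (model == "mre") max(1, sqrt(q / q_df)) else 1
  new_mr_estimate(
    if (model == "mre") "ivw_mre" else "ivw_fixed",
    beta = beta,
    se = se_fixed * scale,
    n_variants = j,
    q_stat = q,
    q_df = q_df,
    q_pval = pchisq(q, q_df, lower.tail = FALSE)
  )
}

#' MR-Egger regression
#'
#' Each instrument is first oriented so its exposure association is
#' positive (both betas flipped where needed); without a fixed orientation
#' the intercept is not identified consistently. Then weighted least
#' squares of Gamma on gamma with an intercept and weights `1/sigma_Yj^2`.
#' Standard errors use a multiplicative residual scale floored at 1; the
#' intercept p-value (the directional-pleiotropy test) is two-sided normal.
#'
#' @param x A `harmonized_set` with at least three instruments.
#' @return An `mr_estimate` with method `"egger"` and the intercept block
#'   filled.
#' @export
mr_egger <- function(x) {
  x <- instrument_frame(x, 3L, "MR-Egger")
  o <- ifelse(x$exposure_beta < 0, -1, 1)
  gx <- x$exposure_beta * o
  gy <- x$outcome_beta * o
  w <- 1 / x$outcome_se^2
  j <- nrow(x)
  if (max(gx) - min(gx) < .Machine$double.eps * max(abs(gx), 1)) {
    abort_domain("exposure associations are identical: Egger slope and intercept are not separable")
  }
  xm <- cbind(intercept = 1, slope = gx)
  xtwx <- crossprod(xm, w * xm)
  coefs <- drop(solve(xtwx, crossprod(xm, w * gy)))
  res <- gy - drop(xm %*% coefs)
  rss <- sum(w * res^2)
  phi <- max(1, rss / (j - 2))
  vcov <- phi * solve(xtwx)
  se <- sqrt(diag(vcov))
  new_mr_estimate(
    "egger",
    beta = coefs[["slope"]],
    se = se[["slope"]],
    n_variants = j,
    q_stat = rss,
    q_df = j - 2L,
    q_pval = pchisq(rss, j - 2L, lower.tail = FALSE),
    egger_intercept = coefs[["intercept"]],
    egger_intercept_se = se[["intercept"]],
    egger_intercept_p = wald_pvalue(coefs[["intercept"]], se[["intercept"]])
  )
}

# Weighted median of theta with weights w: sort theta ascending, form
# standardized cumulative midpoints s_j = (cumsum(w)_j - w_j/2) / sum(w),
# and linearly interpolate theta across s at 0.5.
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  approx(s, theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' Consistent when instruments contributing at least half of the weight are
#' valid. Point estimate by interpolating the ratio estimates across
#' standardized cumulative weights at 0.5, with weights
#' `gamma_j^2 / sigma_Yj^2`. The standard error is the SD of the statistic
#' over `n_boot` parametric-bootstrap resamples of the per-variant
#' exposure/outcome estimates (normal, centred at the observed values with
#' their SEs); the seed is required for reproducibility.
#'
#' @param x A `harmonized_set` with at least three instruments.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap (required; the global RNG
#'   state is left untouched).
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(x, n_boot = 1000, seed) {
  if (missing(seed) || is.null(seed)) {
    abort_usage("a bootstrap seed is required")
  }
  x <- instrument_frame(x, 3L, "weighted median")
  gx <- x$exposure_beta
  gy <- x$outcome_beta
  sx <- x$exposure_se
  sy <- x$outcome_se
  j <- nrow(x)
  beta <- weighted_median_point(gy / gx, gx^2 / sy^2)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      gxb <- rnorm(j, gx, sx)
      gyb <- rnorm(j, gy, sy)
      weighted_median_point(gyb / gxb, gxb^2 / sy^2)
    }, numeric(1))
  })
  new_mr_estimate(
    "weighted_median",
    beta = beta,
    se = stats::sd(boots),
    n_variants = j
  )
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (theta_j - beta)^2` with `w_j = gamma_j^2 / sigma_Yj^2`,
#' computed in the numerically equivalent residual form
#' `sum((Gamma_j - beta * gamma_j)^2 / sigma_Yj^2)`; `df = J - 1`; p-value
#' from the upper chi-square tail.
#'
#' @param x A `harmonized_set` with at least two instruments.
#' @param beta The causal estimate to measure dispersion around (typically
#'   the IVW estimate).
#' @return A list with `q_stat`, `q_df`, `pval`.
#' @export
cochran_q <- function(x, beta) {
  x <- instrument_frame(x, 2L, "Cochran's Q")
  q <- sum((x$outcome_beta - beta * x$exposure_beta)^2 / x$outcome_se^2)
  q_df <- nrow(x) - 1L
  list(q_stat = q, q_df = q_df, pval = pchisq(q, q_df, lower.tail = FALSE))
}

#' Run every applicable MR estimator on an instrument set
#'
#' Dispatches by instrument count: one variant gives the ratio estimate;
#' two or more the IVW; three or more additionally MR-Egger and the
#' weighted median.
#'
#' @inheritParams mr_weighted_median
#' @param ivw_model Passed to [mr_ivw()].
#' @return A tibble with one row per estimate, as from [tidy.mr_estimate()]
#'   (slope terms only), plus an `n_variants` column.
#' @export
mr_estimate_all <- function(x, ivw_model = "mre", n_boot = 1000, seed = 1L) {
  x <- instrument_frame(x, 1L, "MR")
  ests <- if (nrow(x) == 1L) {
    list(mr_ratio(x))
  } else if (nrow(x) == 2L) {
    list(mr_ivw(x, model = ivw_model))
  } else {
    list(
      mr_ivw(x, model = ivw_model),
      mr_weighted_median(x, n_boot = n_boot, seed = seed),
      mr_egger(x)
    )
  }
  list_rbind(map(ests, function(e) {
    mutate(filter(tidy(e), .data$term != "intercept"),
           n_variants = e$n_variants)
  }))
}
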