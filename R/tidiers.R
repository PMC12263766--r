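# Broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an MR estimate
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A tibble with columns `method`, `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`; MR-Egger contributes a
#'   `slope` and an `intercept` row, all other methods a single `slope` row.
#' @export
tidy.mr_estimate <- function(x, ...) {
  out <- tibble(
    method = x$method,
    term = "slope",
    estimate = x$beta,
    std.error = x$se,
    statistic = x$beta / x$se,
    p.value = x$pval,
    conf.low = x$ci_low,
    conf.high = x$ci_high
  )
  if (x$method == "egger") {
    z <- qnorm(0.975)
    out <- bind_rows(out, tibble(
      method = x$method,
      term = "intercept",
      estimate = x$egger_intercept,
      std.error = x$egger_intercept_se,
      statistic = x$egger_intercept / x$egger_intercept_se,
      p.value = x$egger_intercept_p,
      conf.low = x$egger_intercept - z * x$egger_intercept_se,
      conf.high = x$egger_intercept + z * x$egger_intercept_se
    ))
  }
  out
}

#' One-row summary of an MR estimate
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with the estimate, its uncertainty, the
#'   instrument count and the heterogeneity block.
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble(
    method = x$method,
    estimate = x$beta,
    std.error = x$se,
    p.value = x$pval,
    n_variants = x$n_variants,
    q_stat = x$q_stat,
    q_df = as.integer(x$q_df),
    q_pval = x$q_pval
  )
}

#' Tidy a premise matrix
#'
#' @param x A `premise_matrix` from [run_biological_pipeline()].
#' @param ... Unused.
#' @return A long tibble with one row per (source, gene region, premise):
#'   `source`, `gene_symbol`, `premise` (1-4), `label`, `status`.
#' @export
tidy.premise_matrix <- function(x, ...) {
  labels <- c(
    biological = "biological relevance",
    consistent = "consistent for three ketone bodies",
    no_pleiotropy = "no horizontal pleiotropy",
    positive_control = "association with at least one positive control"
  )
  long <- pivot_longer(
    select(as_tibble(x), "source", "gene_symbol", "biological", "consistent",
           "no_pleiotropy", "positive_control"),
    cols = all_of(names(labels)),
    names_to = "key", values_to = "status"
  )
  mutate(
    long,
    premise = match(.data$key, names(labels)),
    label = unname(labels[.data$key]),
    key = NULL
  )[, c("source", "gene_symbol", "premise", "label", "status")]
}
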