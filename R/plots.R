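# ggplot2 visualizations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of a harmonized instrument set
#'
#' Exposure versus outcome associations with error bars and the fitted IVW
#' (through the origin) and MR-Egger (three or more instruments) lines.
#'
#' @param object A `harmonized_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.harmonized_set <- function(object, ...) {
  df <- as_tibble(object)
  if (nrow(df) == 0) {
    abort_usage("empty harmonized set")
  }
  # Plot in the exposure-increasing orientation, as the estimators see it.
  o <- ifelse(df$exposure_beta < 0, -1, 1)
  df$gx <- df$exposure_beta * o
  df$gy <- df$outcome_beta * o
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$gx, y = .data$gy)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey60") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$gy - .data$outcome_se,
                   ymax = .data$gy + .data$outcome_se),
      width = 0, colour = "grey50"
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$gx - .data$exposure_se,
                   xmax = .data$gx + .data$exposure_se),
      height = 0, colour = "grey50"
    ) +
    ggplot2::geom_point(size = 2)
  ivw <- mr_ivw(object)
  p <- p + ggplot2::geom_abline(intercept = 0, slope = ivw$beta,
                                colour = "#2166AC")
  if (nrow(df) >= 3) {
    egger <- mr_egger(object)
    p <- p + ggplot2::geom_abline(intercept = egger$egger_intercept,
                                  slope = egger$beta,
                                  colour = "#B2182B", linetype = "dashed")
  }
  p + ggplot2::labs(
    x = paste0("association with ", attr(object, "exposure_trait")),
    y = paste0("association with ", attr(object, "outcome_trait")),
    title = "Instrument associations (IVW solid, MR-Egger dashed)"
  ) + ggplot2::theme_minimal()
}

#' Tile plot of a premise matrix
#'
#' One tile per (source, gene region, premise), coloured by verdict and
#' labelled with the verdict symbol.
#'
#' @param object A `premise_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.premise_matrix <- function(object, ...) {
  long <- tidy(object)
  long$region <- paste0(long$gene_symbol, " (", long$source, ")")
  long$premise_lab <- factor(paste0("P", long$premise),
                             levels = paste0("P", 1:4))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$premise_lab,
                                     y = .data$region,
                                     fill = .data$status)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = status_symbol(.data$status)),
                       size = 5) +
    ggplot2::scale_fill_manual(values = c(
      pass = "#A6DBA0", fail = "#F4A582", not_evaluated = "grey85"
    )) +
    ggplot2::labs(x = "premise", y = NULL, fill = "verdict",
                  title = "Stepwise instrument-validity assessment") +
    ggplot2::theme_minimal()
}

#' Forest-style plot of agnostic MR estimates
#'
#' @param x An `agnostic_result` from [run_agnostic_pipeline()].
#' @return A ggplot with one panel per control outcome, estimates with 95%
#'   CIs per ketone body and method (skipped methods omitted).
#' @export
plot_agnostic_estimates <- function(x) {
  df <- filter(as_tibble(x), .data$status == "ok")
  if (nrow(df) == 0) {
    abort_usage("no computed estimates to plot")
  }
  df$label <- paste0(df$exposure, " (GV#", df$n_variants, ")")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$label,
                                   colour = .data$method)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::facet_wrap(~outcome, scales = "free_x") +
    ggplot2::labs(x = "causal estimate (95% CI)", y = NULL,
                  colour = "method") +
    ggplot2::theme_minimal()
}
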