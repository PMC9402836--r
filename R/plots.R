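#' Forest plot of stratified odds ratios
#'
#' One point and Woolf interval per comparison and endpoint on a log odds
#' scale; undefined estimates (zero cells) are dropped with a message.
#'
#' @param report Tibble from [analyze_outcomes()].
#' @return A ggplot object.
#' @export
plot_forest <- function(report) {
  dropped <- sum(!report$estimate_defined)
  if (dropped) message(dropped, " undefined estimate(s) not drawn")
  d <- dplyr::filter(report, .data$estimate_defined)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio, y = .data$endpoint)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$comparison)) +
    ggplot2::labs(x = "Odds ratio (log scale, Woolf 95% CI)", y = NULL)
}

#' Distribution of MIS-HF totals
#'
#' Histogram of the per-patient totals with the stability threshold marked:
#' totals at or below the threshold are the stable (primary-care eligible)
#' class.
#'
#' @param scores Tibble from [mishf_score()].
#' @param thresholds Threshold record (for the cut line).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, thresholds = mishf_thresholds()) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$total, fill = .data$stability_class)) +
    ggplot2::geom_bar() +
    ggplot2::geom_vline(xintercept = thresholds$stable_max + 0.5, linetype = "dashed") +
    ggplot2::labs(x = "MIS-HF total", y = "Patients", fill = "Class")
}

#' @rdname tidy.mishf_logit
#' @param object A `mishf_logit` fit.
#' @export
autoplot.mishf_logit <- function(object, ...) {
  d <- tidy(object, exponentiate = TRUE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high), height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (Wald 95% CI)", y = NULL)
}
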