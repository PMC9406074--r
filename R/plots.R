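#' Plot an ROC curve
#'
#' @param object A `pv_roc` object.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pv_roc <- function(object, ...) {
  d <- object$curve
  ggplot2::ggplot(d, ggplot2::aes(x = 1 - .data$specificity,
                                  y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc),
                  subtitle = sprintf("Youden-optimal cutoff: %g",
                                     object$optimal_cutoff)) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `pv_km` object.
#' @param ... Ignored.
#' @return A ggplot of the per-group survival step functions.
#' @export
autoplot.pv_km <- function(object, ...) {
  d <- object$curves |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0L,
                     survival = 1), .x)) |>
    dplyr::ungroup()
  lab <- if (is.na(object$logrank_p)) "log-rank p: NA" else
    sprintf("log-rank p = %.3g", object$logrank_p)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival,
                                  colour = .data$group)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL, subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Plot longitudinal cfDNA and mutation dynamics
#'
#' Two aligned panels for one patient's serial samples: cfDNA concentration
#' and total mutation count over follow-up time.
#'
#' @param object A `pv_dynamics` object.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pv_dynamics <- function(object, ...) {
  tp <- object$timepoints
  d <- tidyr::pivot_longer(
    dplyr::select(tp, "months", "cfdna_conc", "n_mutations"),
    cols = c("cfdna_conc", "n_mutations"),
    names_to = "metric", values_to = "value")
  d$metric <- factor(d$metric, levels = c("cfdna_conc", "n_mutations"),
                     labels = c("cfDNA (ng/uL)", "Mutations (n)"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$months, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Months from baseline", y = NULL) +
    ggplot2::theme_minimal()
}
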