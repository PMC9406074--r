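#' Tidy / glance methods for plasmavar result objects
#'
#' broom-style accessors: `tidy()` returns the per-element table of a result
#' (ROC curve points, Kaplan-Meier curve steps, Cox coefficient rows) and
#' `glance()` a one-row model summary.
#'
#' @param x A `pv_roc`, `pv_km` or `pv_cox` object.
#' @param ... Ignored.
#' @return A tibble.
#' @name plasmavar-tidiers
NULL

#' @rdname plasmavar-tidiers
#' @export
tidy.pv_roc <- function(x, ...) x$curve

#' @rdname plasmavar-tidiers
#' @export
glance.pv_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, optimal_cutoff = x$optimal_cutoff,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname plasmavar-tidiers
#' @export
tidy.pv_km <- function(x, ...) x$curves

#' @rdname plasmavar-tidiers
#' @export
glance.pv_km <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$mean_survival, names_from = "group",
                             values_from = c("rmean", "rmean_se"))
  dplyr::bind_cols(tibble::tibble(logrank_chisq = x$logrank_chisq,
                                  logrank_p = x$logrank_p,
                                  rmean_horizon = x$rmean_horizon),
                   wide)
}

#' @rdname plasmavar-tidiers
#' @export
tidy.pv_cox <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname plasmavar-tidiers
#' @export
glance.pv_cox <- function(x, ...) {
  tibble::tibble(n_models = length(attr(x, "fits")),
                 n_terms = nrow(x),
                 n_flagged = sum(!is.na(x$diagnostic) | is.na(x$hr)))
}
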