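#' Mutational-burden metrics for sample profiles
#'
#' Adds the mutations/cfDNA ratio to a table of per-sample burden columns.
#' The ratio is `n_mutations / cfdna_conc` (mutations per ng/uL), defined as
#' 0 when no mutations were detected.
#'
#' @param profiles Tibble with `n_mutations` and `cfdna_conc` columns.
#' @return The input with a `ratio` column.
#' @export
pv_burden <- function(profiles) {
  need <- c("n_mutations", "cfdna_conc")
  miss <- setdiff(need, names(profiles))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  bad <- profiles$n_mutations > 0 & profiles$cfdna_conc <= 0
  if (any(bad)) {
    abort("cfdna_conc must be positive when mutations were detected")
  }
  dplyr::mutate(profiles,
                ratio = ifelse(.data$n_mutations == 0, 0,
                               .data$n_mutations / .data$cfdna_conc))
}

#' Default prognostic dichotomizations
#'
#' The standard biomarker cut-offs for early-HCC cfDNA profiling: cfDNA
#' concentration > 2 ng/uL, > 4 cfDNA mutations, > 2 mutated genes,
#' mutations/cfDNA ratio > 6, and > 6 tissue mutations. All cut-offs are
#' strict: a value exactly at the cut-off is classified low.
#'
#' @return Tibble with `variable`, `cutoff`, `direction`.
#' @export
pv_dichotomies <- function() {
  tibble::tibble(
    variable = c("cfdna_conc", "n_mutations", "n_genes", "ratio",
                 "n_mutations_tissue"),
    cutoff = c(2, 4, 2, 6, 6),
    direction = "greater"
  )
}

#' Dichotomize a variable at a cut-off
#'
#' @param x Numeric vector.
#' @param cutoff Cut-off value; classification is strictly greater.
#' @return Logical vector, `TRUE` = high.
#' @export
pv_classify_high <- function(x, cutoff) x > cutoff

#' Mann-Whitney U comparison of two groups
#'
#' Reports `U = #(a > b) + 0.5 #(a = b)` over all cross-group pairs (so
#' `U + U' = n_a * n_b`) with a two-sided p-value: exact enumeration when
#' both groups have at most 8 untied observations, otherwise the
#' tie-corrected normal approximation (via [stats::wilcox.test()]).
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the measurement and a
#'   two-level grouping; group "a" is the first level.
#' @return One-row tibble: `group_a`, `group_b`, `n_a`, `n_b`, `u`,
#'   `u_prime`, `p_value`, `method`.
#' @export
#' @examples
#' d <- data.frame(v = c(1, 2, 3, 10, 11, 12), g = rep(c("a", "b"), each = 3))
#' pv_mann_whitney(d, v, g)
pv_mann_whitney <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- as.factor(if (is.factor(g)) droplevels(g[keep]) else g[keep])
  lev <- levels(g)
  if (length(lev) != 2L) abort("group must have exactly two levels")
  a <- v[g == lev[1]]
  b <- v[g == lev[2]]
  if (!length(a) || !length(b)) abort("both groups must be non-empty")
  ties <- length(unique(c(a, b))) < length(c(a, b))
  exact <- length(a) <= 8L && length(b) <= 8L && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  u <- unname(wt$statistic)  # #(a > b) + 0.5 ties
  tibble::tibble(group_a = lev[1], group_b = lev[2],
                 n_a = length(a), n_b = length(b),
                 u = u, u_prime = length(a) * length(b) - u,
                 p_value = wt$p.value,
                 method = if (exact) "exact" else "normal approximation")
}

#' ROC analysis with Youden-optimal cut-off
#'
#' Builds the ROC curve of a continuous marker against a binary outcome
#' using the rule "predicted positive when value > threshold". The AUC is
#' computed by pair counting, `P(value_pos > value_neg) + 0.5 P(equal)`
#' (identical to the Mann-Whitney probability), and the reported optimal
#' cut-off maximises Youden's J = sensitivity + specificity - 1, with ties
#' resolved to the lower threshold.
#'
#' @param data A data frame.
#' @param value,outcome Columns (tidy-eval): numeric marker and binary
#'   outcome (0/1, logical, or two-level factor; the higher level is the
#'   positive class).
#' @return An object of class `pv_roc`: list with `curve` (tibble of
#'   `threshold`, `sensitivity`, `specificity`, `youden`), `auc`,
#'   `optimal_cutoff`, `n_pos`, `n_neg`.
#' @export
pv_roc <- function(data, value, outcome) {
  v <- dplyr::pull(data, {{ value }})
  y <- dplyr::pull(data, {{ outcome }})
  keep <- !is.na(v) & !is.na(y)
  v <- v[keep]
  y <- y[keep]
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(as.logical(y) | y > 0)
  if (length(unique(y)) != 2L) abort("outcome must contain both classes")
  pos <- v[y == 1L]
  neg <- v[y == 0L]
  n_pos <- length(pos)
  n_neg <- length(neg)
  # rank-based pair counting (handles ties exactly)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(-Inf, sort(unique(v)))
  sens <- vapply(thr, function(t) mean(pos > t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg <= t), numeric(1))
  curve <- tibble::tibble(threshold = thr, sensitivity = sens,
                          specificity = spec, youden = sens + spec - 1)
  best <- which(curve$youden == max(curve$youden))
  optimal <- min(curve$threshold[best])
  structure(list(curve = curve, auc = auc, optimal_cutoff = optimal,
                 n_pos = n_pos, n_neg = n_neg),
            class = "pv_roc")
}

#' @export
print.pv_roc <- function(x, ...) {
  cat(sprintf("<pv_roc> AUC = %.3f, Youden-optimal cutoff = %g (%d pos / %d neg)\n",
              x$auc, x$optimal_cutoff, x$n_pos, x$n_neg))
  invisible(x)
}

#' Kaplan-Meier curves, log-rank test and restricted mean survival
#'
#' Product-limit estimates per group (deaths before censorings at tied
#' times), the two-group log-rank test, and the restricted mean survival
#' time (area under each curve up to the largest observed time). With no
#' events in either group the log-rank statistic is undefined and reported
#' as `NA`.
#'
#' @param data A data frame.
#' @param time,event,group Columns (tidy-eval): follow-up time (>= 0), event
#'   indicator (0/1), and a two-level grouping.
#' @return An object of class `pv_km`: list with `curves` (tibble `group`,
#'   `time`, `n_risk`, `n_event`, `survival`), `logrank_chisq`, `logrank_p`,
#'   `mean_survival` (tibble `group`, `rmean`, `rmean_se`), `rmean_horizon`
#'   and the underlying `survfit` object.
#' @export
pv_km_logrank <- function(data, time, event, group) {
  tt <- dplyr::pull(data, {{ time }})
  ev <- dplyr::pull(data, {{ event }})
  g <- dplyr::pull(data, {{ group }})
  keep <- !is.na(tt) & !is.na(ev) & !is.na(g)
  tt <- tt[keep]; ev <- as.integer(ev[keep])
  g <- as.factor(if (is.factor(g)) droplevels(g[keep]) else g[keep])
  if (any(tt < 0)) abort("times must be >= 0")
  if (nlevels(g) != 2L) abort("group must have exactly two non-empty levels")
  if (any(table(g) == 0L)) abort("both groups must contain subjects")
  df <- data.frame(t = tt, e = ev, g = g)
  fit <- survival::survfit(survival::Surv(t, e) ~ g, data = df)
  sm <- summary(fit)
  curves <- tibble::tibble(
    group = sub("^g=", "", as.character(sm$strata)),
    time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    survival = sm$surv)
  horizon <- max(tt)
  tab <- summary(fit, rmean = horizon)$table
  mean_surv <- tibble::tibble(group = sub("^g=", "", rownames(tab)),
                              rmean = unname(tab[, "rmean"]),
                              rmean_se = unname(tab[, "se(rmean)"]))
  if (sum(ev) == 0L) {
    chisq <- NA_real_
    p <- NA_real_
  } else {
    sd <- survival::survdiff(survival::Surv(t, e) ~ g, data = df)
    chisq <- unname(sd$chisq)
    p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  structure(list(curves = curves, logrank_chisq = chisq, logrank_p = p,
                 mean_survival = mean_surv, rmean_horizon = horizon,
                 fit = fit),
            class = "pv_km")
}

#' @export
print.pv_km <- function(x, ...) {
  cat(sprintf("<pv_km> log-rank chisq = %s, p = %s\n",
              format(x$logrank_chisq, digits = 4),
              format(x$logrank_p, digits = 4)))
  print(x$mean_survival)
  invisible(x)
}

#' Cox proportional-hazards models for burden covariates
#'
#' Fits Cox models (Efron tie handling) for a time-to-event outcome, either
#' one univariate model per covariate or a single multivariate model over
#' all of them. When `dichotomies` is supplied, the matching covariates are
#' first binarized as strictly-greater indicators (value > cutoff), naming
#' the term `<variable>_gt<cutoff>`. Each model uses complete cases for its
#' own covariates and reports its `n_obs`. Non-convergence, complete
#' separation or fits on fewer than 10 complete observations yield a
#' diagnostic note in the result row instead of an error.
#'
#' @param data A data frame.
#' @param time,event Column names (strings) of follow-up time and event
#'   indicator.
#' @param covariates Character vector of covariate column names.
#' @param dichotomies Optional tibble with `variable` and `cutoff` columns
#'   (see [pv_dichotomies()]).
#' @param multivariate Fit one model with all covariates (`TRUE`) or one
#'   univariate model per covariate (default).
#' @param outcome_label Label stored in the result rows.
#' @return An object of class `pv_cox`: a tibble with `term`, `hr`,
#'   `ci_low`, `ci_high`, `p_value`, `n_obs`, `n_event`, `model`, `outcome`,
#'   `diagnostic`; fitted `coxph` objects in attribute `fits`.
#' @export
pv_cox <- function(data, time, event, covariates,
                   dichotomies = NULL, multivariate = FALSE,
                   outcome_label = event) {
  miss <- setdiff(c(time, event, covariates), names(data))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  df <- as.data.frame(data)
  terms <- covariates
  if (!is.null(dichotomies)) {
    for (i in seq_len(nrow(dichotomies))) {
      vn <- dichotomies$variable[i]
      if (!vn %in% covariates) next
      nv <- sprintf("%s_gt%g", vn, dichotomies$cutoff[i])
      df[[nv]] <- as.integer(pv_classify_high(df[[vn]], dichotomies$cutoff[i]))
      terms[terms == vn] <- nv
    }
  }
  if (sum(df[[event]], na.rm = TRUE) < 1)
    abort("at least one event is required")

  fit_one <- function(vars, label) {
    dd <- df[stats::complete.cases(df[, c(time, event, vars)]), ]
    fml <- stats::as.formula(paste0("survival::Surv(", time, ", ", event,
                                    ") ~ ", paste(vars, collapse = " + ")))
    # very small fits are allowed but flagged
    diag_msg <- if (nrow(dd) < 10L)
      "fewer than 10 complete observations" else NA_character_
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(fml, data = dd, ties = "efron"),
        warning = function(w) {
          diag_msg <<- conditionMessage(w)
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(list(rows = tibble::tibble(
        term = vars, hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p_value = NA_real_, n_obs = nrow(dd), n_event = sum(dd[[event]]),
        model = label, outcome = outcome_label,
        diagnostic = conditionMessage(fit)), fit = NULL))
    }
    s <- summary(fit)
    co <- s$coefficients
    ci <- s$conf.int
    rows <- tibble::tibble(
      term = rownames(co),
      hr = unname(co[, "exp(coef)"]),
      ci_low = unname(ci[, "lower .95"]),
      ci_high = unname(ci[, "upper .95"]),
      p_value = unname(co[, "Pr(>|z|)"]),
      n_obs = s$n, n_event = s$nevent,
      model = label, outcome = outcome_label,
      diagnostic = diag_msg)
    list(rows = rows, fit = fit)
  }

  if (multivariate) {
    res <- list(fit_one(terms, "multivariate"))
  } else {
    res <- lapply(terms, function(v) fit_one(v, "univariate"))
  }
  rows <- dplyr::bind_rows(lapply(res, `[[`, "rows"))
  fits <- lapply(res, `[[`, "fit")
  structure(rows, fits = fits, class = c("pv_cox", class(rows)))
}
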