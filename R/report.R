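#' Full prognostic analysis battery for a cohort
#'
#' Runs the standard cfDNA prognostic analyses on a joined clinical/profile
#' table: Mann-Whitney comparisons of cfDNA level and burden metrics by vital
#' status and recurrence, ROC analyses of cfDNA concentration against
#' mortality and against carrying more than two mutations, Kaplan-Meier /
#' log-rank analyses for each default dichotomy, univariate Cox models over
#' the continuous burden covariates, and Cox models over the dichotomized
#' covariates. Burden comparisons against nodule count (single vs multiple)
#' and microvascular invasion are included when those covariates are present.
#' p-values are reported raw, without multiple-testing correction.
#'
#' Analyses whose preconditions fail on the given data (e.g. all-zero burden,
#' a single outcome class, no events) are skipped with a reason rather than
#' erroring.
#'
#' @param cohort Tibble with at least `cfdna_conc`, `n_mutations`, `n_genes`,
#'   `os_time`, `death_event`, `recurrence_time`, `recurrence_event`
#'   (`ratio` is recomputed via [pv_burden()] if absent; `nodule_count` and
#'   `mvi` are optional).
#' @return An object of class `pv_report`: a named list of result objects,
#'   plus `skipped` (tibble of skipped analyses and reasons) and `notes`.
#' @export
pv_prognostic_report <- function(cohort) {
  need <- c("cfdna_conc", "n_mutations", "n_genes", "os_time", "death_event",
            "recurrence_time", "recurrence_event")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    abort(paste("cohort is missing required columns:",
                paste(miss, collapse = ", ")))
  }
  if (!"ratio" %in% names(cohort)) cohort <- pv_burden(cohort)
  res <- list()
  skipped <- list()
  run <- function(label, fn) {
    out <- tryCatch(fn(), error = function(e) e)
    if (inherits(out, "error")) {
      skipped[[length(skipped) + 1L]] <<- tibble::tibble(
        analysis = label, reason = conditionMessage(out))
      NULL
    } else {
      res[[label]] <<- out
      out
    }
  }
  d <- dplyr::mutate(cohort,
                     death_group = factor(ifelse(.data$death_event == 1,
                                                 "dead", "alive"),
                                          levels = c("dead", "alive")),
                     rec_group = factor(ifelse(.data$recurrence_event == 1,
                                               "recurrence", "no_recurrence"),
                                        levels = c("recurrence", "no_recurrence")))

  run("cfdna_by_vital_status",
      function() pv_mann_whitney(d, "cfdna_conc", "death_group"))
  for (v in c("n_mutations", "n_genes", "ratio")) {
    local({
      vv <- v
      run(paste0(vv, "_by_vital_status"),
          function() pv_mann_whitney(d, vv, "death_group"))
      run(paste0(vv, "_by_recurrence"),
          function() pv_mann_whitney(d, vv, "rec_group"))
    })
  }
  run("roc_cfdna_mortality",
      function() pv_roc(d, "cfdna_conc", "death_event"))
  d$gt2_mutations <- d$n_mutations > 2
  run("roc_cfdna_gt2_mutations",
      function() pv_roc(d, "cfdna_conc", "gt2_mutations"))

  dich <- pv_dichotomies()
  km_plan <- list(
    list("km_os_by_cfdna_gt2", "cfdna_conc", "os_time", "death_event"),
    list("km_os_by_mutations_gt4", "n_mutations", "os_time", "death_event"),
    list("km_recurrence_by_mutations_gt4", "n_mutations", "recurrence_time",
         "recurrence_event"),
    list("km_os_by_genes_gt2", "n_genes", "os_time", "death_event"),
    list("km_recurrence_by_genes_gt2", "n_genes", "recurrence_time",
         "recurrence_event"),
    list("km_recurrence_by_ratio_gt6", "ratio", "recurrence_time",
         "recurrence_event"))
  for (p in km_plan) {
    local({
      pp <- p
      cutoff <- dich$cutoff[dich$variable == pp[[2]]]
      dd <- dplyr::mutate(d, grp = factor(
        ifelse(pv_classify_high(.data[[pp[[2]]]], cutoff), "high", "low"),
        levels = c("high", "low")))
      run(pp[[1]],
          function() pv_km_logrank(dd, pp[[3]], pp[[4]], "grp"))
    })
  }

  covars <- c("n_mutations", "n_genes", "ratio", "cfdna_conc")
  run("cox_univariate_death",
      function() pv_cox(d, "os_time", "death_event", covars,
                        outcome_label = "death"))
  run("cox_univariate_recurrence",
      function() pv_cox(d, "recurrence_time", "recurrence_event", covars,
                        outcome_label = "recurrence"))
  run("cox_dichotomized_death",
      function() pv_cox(d, "os_time", "death_event",
                        c("n_mutations", "n_genes", "ratio"),
                        dichotomies = dich, outcome_label = "death"))
  run("cox_dichotomized_recurrence",
      function() pv_cox(d, "recurrence_time", "recurrence_event",
                        c("n_mutations", "n_genes", "ratio"),
                        dichotomies = dich, outcome_label = "recurrence"))

  if ("nodule_count" %in% names(cohort)) {
    dd <- dplyr::mutate(d, foci = factor(ifelse(.data$nodule_count > 1,
                                                "multiple", "single"),
                                         levels = c("multiple", "single")))
    nod <- dd
    run("ratio_by_nodule_count",
        function() pv_mann_whitney(nod, "ratio", "foci"))
    run("n_mutations_by_nodule_count",
        function() pv_mann_whitney(nod, "n_mutations", "foci"))
  }
  if ("mvi" %in% names(cohort)) {
    dd <- dplyr::mutate(d, mvi_grp = factor(ifelse(.data$mvi == 1, "mvi",
                                                   "no_mvi"),
                                            levels = c("mvi", "no_mvi")))
    mv <- dd
    run("n_mutations_by_mvi",
        function() pv_mann_whitney(mv, "n_mutations", "mvi_grp"))
    run("ratio_by_mvi",
        function() pv_mann_whitney(mv, "ratio", "mvi_grp"))
  }

  out <- list(
    results = res,
    skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
      tibble::tibble(analysis = character(0), reason = character(0)),
    notes = paste("p-values are raw (no multiple-testing correction);",
                  "dichotomies use strict '>' cut-offs:",
                  "cfDNA 2 ng/uL, 4 mutations, 2 genes, ratio 6."))
  class(out) <- "pv_report"
  out
}

#' @export
print.pv_report <- function(x, ...) {
  cat("<pv_report>", length(x$results), "analyses,",
      nrow(x$skipped), "skipped\n")
  cat(" ", paste(names(x$results), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a prognostic report to JSON
#'
#' Flattens each result object to plain lists/tables so the full bundle can
#' be written with jsonlite.
#'
#' @param report A `pv_report`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
pv_report_json <- function(report, path = NULL) {
  flat <- lapply(report$results, function(r) {
    if (inherits(r, "pv_roc")) {
      list(auc = r$auc, optimal_cutoff = r$optimal_cutoff,
           n_pos = r$n_pos, n_neg = r$n_neg)
    } else if (inherits(r, "pv_km")) {
      list(logrank_chisq = r$logrank_chisq, logrank_p = r$logrank_p,
           mean_survival = as.data.frame(r$mean_survival))
    } else if (inherits(r, "pv_cox")) {
      as.data.frame(dplyr::select(tibble::as_tibble(r), -"diagnostic"))
    } else {
      as.data.frame(r)
    }
  })
  payload <- list(results = flat, skipped = as.data.frame(report$skipped),
                  notes = report$notes)
  if (is.null(path)) {
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    invisible(path)
  }
}

#' Longitudinal dynamics of one patient's serial samples
#'
#' Summarises serial plasma profiles of a single patient: per timepoint the
#' months from baseline, cfDNA concentration, total and per-gene mutation
#' counts; and per variant its frequency trajectory with `new` / `lost` /
#' `persistent` status transitions between consecutive timepoints.
#'
#' @param samples Tibble with one row per timepoint: `months` (unique,
#'   sorted or sortable), `cfdna_conc`, and a `calls` list-column of variant
#'   call tibbles (columns `gene`, `genomic_label`, `frequency`; empty
#'   tibbles for mutation-free timepoints).
#' @return An object of class `pv_dynamics`: list with `timepoints` (tibble:
#'   `months`, `months_from_baseline`, `cfdna_conc`, `n_mutations`, nested
#'   `gene_counts`) and `trajectories` (tibble: `variant`, `gene`, `months`,
#'   `frequency`, `status`).
#' @export
pv_dynamics <- function(samples) {
  need <- c("months", "cfdna_conc", "calls")
  miss <- setdiff(need, names(samples))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!nrow(samples)) abort("at least one timepoint is required")
  if (anyDuplicated(samples$months)) abort("duplicate timepoints")
  samples <- dplyr::arrange(samples, .data$months)

  tp <- tibble::tibble(
    months = samples$months,
    months_from_baseline = samples$months - samples$months[1],
    cfdna_conc = samples$cfdna_conc,
    n_mutations = vapply(samples$calls, nrow, integer(1)),
    gene_counts = lapply(samples$calls, function(cc) {
      if (!nrow(cc)) return(tibble::tibble(gene = character(0), n = integer(0)))
      dplyr::count(cc, .data$gene, sort = TRUE)
    }))

  traj_rows <- lapply(seq_len(nrow(samples)), function(i) {
    cc <- samples$calls[[i]]
    if (!nrow(cc)) return(NULL)
    tibble::tibble(variant = cc$genomic_label, gene = cc$gene,
                   months = samples$months[i], frequency = cc$frequency)
  })
  traj <- dplyr::bind_rows(traj_rows)
  if (nrow(traj)) {
    status <- character(nrow(traj))
    for (r in seq_len(nrow(traj))) {
      i <- match(traj$months[r], samples$months)
      if (i == 1L) { status[r] <- "baseline"; next }
      prev <- samples$calls[[i - 1L]]
      status[r] <- if (traj$variant[r] %in% prev$genomic_label)
        "persistent" else "new"
    }
    traj$status <- status
    # variants present at one timepoint and absent at the next: lost
    lost_rows <- list()
    for (i in seq_len(nrow(samples) - 1L)) {
      cur <- samples$calls[[i]]
      nxt <- samples$calls[[i + 1L]]
      gone <- cur[!cur$genomic_label %in% nxt$genomic_label, , drop = FALSE]
      if (nrow(gone)) {
        lost_rows[[length(lost_rows) + 1L]] <- tibble::tibble(
          variant = gone$genomic_label, gene = gone$gene,
          months = samples$months[i + 1L], frequency = 0,
          status = "lost")
      }
    }
    traj <- dplyr::bind_rows(c(list(traj), lost_rows)) |>
      dplyr::arrange(.data$variant, .data$months)
  } else {
    traj <- tibble::tibble(variant = character(0), gene = character(0),
                           months = numeric(0), frequency = numeric(0),
                           status = character(0))
  }
  structure(list(timepoints = tp, trajectories = traj),
            class = "pv_dynamics")
}

#' @export
print.pv_dynamics <- function(x, ...) {
  cat("<pv_dynamics>", nrow(x$timepoints), "timepoints\n")
  print(dplyr::select(x$timepoints, -"gene_counts"))
  invisible(x)
}
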