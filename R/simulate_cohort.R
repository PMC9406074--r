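#' Simulate a clinical cohort with cfDNA levels, mutation burdens and outcomes
#'
#' Generates a synthetic cohort of plasma-profiled patients in two latent
#' covariate groups ("low" and "high" risk). Each group has its own
#' log-normal cfDNA concentration distribution and negative-binomial mutation
#' burden; mutated genes are assigned by distributing each patient's
#' mutations uniformly over the panel genes. Overall-survival and recurrence
#' times are then drawn from exponential proportional-hazards models whose
#' linear predictors are taken over the burden covariates, and censored at
#' the follow-up horizon. With all coefficients zero the simulator is a null
#' model (covariates carry no prognostic signal).
#'
#' Default calibration emulates an early-HCC resection cohort: 30 patients of
#' whom ~23% fall in the high-risk group; cfDNA medians 2.90 ng/uL (high)
#' vs 0.98 ng/uL (low) with log-normal spreads matched to the corresponding
#' interquartile ranges; burdens with medians near 4.5 vs 1.5 mutations; and
#' hazard coefficients of log(1.11) (death) and log(1.16) (recurrence) per
#' additional cfDNA mutation.
#'
#' @param n_patients Number of patients.
#' @param frac_high Fraction of patients in the high-risk covariate group.
#' @param cfdna_meanlog,cfdna_sdlog Named numeric vectors (`low`, `high`)
#'   with the per-group log-normal parameters of cfDNA concentration
#'   (ng/uL).
#' @param burden_mu,burden_size Per-group negative-binomial mean and size for
#'   the number of cfDNA mutations (named `low`, `high`).
#' @param genes Gene labels over which mutations are spread.
#' @param base_hazard_death,base_hazard_recurrence Baseline hazards per
#'   month (> 0).
#' @param coef_death,coef_recurrence Named log-hazard coefficients over any
#'   of `n_mutations`, `n_genes`, `cfdna_conc`, `ratio`.
#' @param group_log_hr Named vector (`death`, `recurrence`): extra log-hazard
#'   carried by the high-risk group, a shared frailty standing in for the
#'   unmeasured tumour aggressiveness that links high cfDNA / high burden to
#'   poor outcome. Set both to 0 (with `coef_* = NULL`) for a null cohort.
#' @param horizon_months Administrative censoring time; a horizon of 0
#'   censors everyone at 0 with no events.
#' @param panel Optional amplicon panel; when given, each patient also gets a
#'   `variant_specs` list-column of spiked variants (positions inside the
#'   primer-free insert) usable with [pv_simulate_reads()].
#' @param seed Master seed (per-patient child streams).
#' @return A tibble with one row per patient: `patient_id`, `risk_group`,
#'   `cfdna_conc`, `n_mutations`, `n_genes`, `ratio`, `os_time`,
#'   `death_event`, `recurrence_time`, `recurrence_event`, clinical
#'   covariates (`nodule_count`, `mvi`, `nodule_size_cm`, `afp`), and
#'   optionally `variant_specs`.
#' @export
#' @examples
#' cohort <- pv_simulate_cohort(n_patients = 30, seed = 1)
#' table(cohort$death_event)
pv_simulate_cohort <- function(n_patients = 30L,
                               frac_high = 7 / 30,
                               cfdna_meanlog = c(low = log(0.98), high = log(2.90)),
                               cfdna_sdlog = c(low = 0.925, high = 0.282),
                               burden_mu = c(low = 1.5, high = 4.5),
                               burden_size = 2,
                               genes = c("TERT", "TP53", "CTNNB1", "AXIN1", "ARID1A"),
                               base_hazard_death = 0.0025,
                               base_hazard_recurrence = 0.006,
                               coef_death = c(n_mutations = log(1.11)),
                               coef_recurrence = c(n_mutations = log(1.16)),
                               group_log_hr = c(death = log(4),
                                                recurrence = log(3)),
                               horizon_months = 50,
                               panel = NULL,
                               seed = 1L) {
  if (n_patients < 1L) abort("n_patients must be >= 1")
  if (frac_high < 0 || frac_high > 1) abort("frac_high must be in [0, 1]")
  if (base_hazard_death <= 0 || base_hazard_recurrence <= 0)
    abort("baseline hazards must be positive")
  if (horizon_months < 0) abort("horizon_months must be >= 0")
  set.seed(as.integer(seed))

  group <- ifelse(runif(n_patients) < frac_high, "high", "low")
  cfdna <- rlnorm(n_patients, cfdna_meanlog[group], cfdna_sdlog[group])
  n_mut <- rnbinom(n_patients, size = burden_size, mu = burden_mu[group])
  gene_draws <- lapply(n_mut, function(m) {
    if (m == 0L) character(0) else sample(genes, m, replace = TRUE)
  })
  n_genes <- vapply(gene_draws, dplyr::n_distinct, integer(1))
  ratio <- ifelse(n_mut == 0L, 0, n_mut / cfdna)

  covars <- cbind(n_mutations = n_mut, n_genes = n_genes,
                  cfdna_conc = cfdna, ratio = ratio)
  lin_pred <- function(coefs) {
    if (is.null(coefs) || !length(coefs)) return(rep(0, n_patients))
    bad <- setdiff(names(coefs), colnames(covars))
    if (length(bad)) abort(paste("unknown hazard covariates:",
                                 paste(bad, collapse = ", ")))
    drop(covars[, names(coefs), drop = FALSE] %*% coefs)
  }
  frail <- function(which) {
    g <- if (!is.null(group_log_hr) && which %in% names(group_log_hr))
      group_log_hr[[which]] else 0
    (group == "high") * g
  }
  t_death <- rexp(n_patients,
                  base_hazard_death * exp(lin_pred(coef_death) + frail("death")))
  t_rec <- rexp(n_patients,
                base_hazard_recurrence *
                  exp(lin_pred(coef_recurrence) + frail("recurrence")))

  cohort <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n_patients)),
    risk_group = group,
    cfdna_conc = cfdna,
    n_mutations = as.integer(n_mut),
    n_genes = n_genes,
    ratio = ratio,
    os_time = pmin(t_death, horizon_months),
    death_event = as.integer(t_death <= horizon_months),
    recurrence_time = pmin(t_rec, horizon_months),
    recurrence_event = as.integer(t_rec <= horizon_months),
    nodule_count = 1L + stats::rpois(n_patients, ifelse(group == "high", 0.8, 0.3)),
    mvi = as.integer(runif(n_patients) < ifelse(group == "high", 0.4, 0.15)),
    nodule_size_cm = round(rlnorm(n_patients, log(3.5), 0.45), 1),
    afp = round(rlnorm(n_patients, log(15), 1.2), 1)
  )
  if (horizon_months == 0) {
    cohort$death_event <- 0L
    cohort$recurrence_event <- 0L
  }

  if (!is.null(panel)) {
    pv_validate_panel(panel)
    cohort$variant_specs <- lapply(seq_len(n_patients), function(i) {
      set.seed(pv_child_seed(seed, 1000L + i))
      pv_draw_variant_specs(panel, n_mut[i], gene_draws[[i]])
    })
  }
  cohort
}

# Draw spiked-variant specs for one patient: each mutation goes to an
# amplicon of its assigned gene, at a random primer-free insert position,
# with a frequency log-uniform in [0.015, 0.4] (comfortably above the 1%
# call threshold).
pv_draw_variant_specs <- function(panel, n, gene_draw) {
  if (n == 0L) {
    return(tibble::tibble(amplicon_id = character(0), position = integer(0),
                          ref_base = character(0), alt_base = character(0),
                          true_frequency = numeric(0), strands = character(0)))
  }
  rows <- vector("list", n)
  taken <- character(0)
  for (i in seq_len(n)) {
    cand <- panel[panel$gene == gene_draw[i], ]
    if (!nrow(cand)) cand <- panel
    a <- cand[sample(nrow(cand), 1L), ]
    lo <- nchar(a$forward_primer) + 1L
    hi <- nchar(a$reference_seq) - nchar(a$reverse_primer)
    repeat {
      pos <- sample(lo:hi, 1L)
      key <- paste(a$amplicon_id, pos)
      if (!key %in% taken) { taken <- c(taken, key); break }
    }
    ref <- substr(a$reference_seq, pos, pos)
    alt <- sample(setdiff(DNA_BASES, ref), 1L)
    rows[[i]] <- tibble::tibble(amplicon_id = a$amplicon_id,
                                position = pos, ref_base = ref,
                                alt_base = alt,
                                true_frequency = exp(runif(1, log(0.015), log(0.4))),
                                strands = "both")
  }
  dplyr::bind_rows(rows)
}
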