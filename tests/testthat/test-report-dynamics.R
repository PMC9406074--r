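test_that("the prognostic report runs the full battery and tags each analysis", {
  co <- pv_simulate_cohort(n_patients = 120, seed = 21)
  rep <- pv_prognostic_report(co)
  expect_s3_class(rep, "pv_report")
  expect_true(all(c("cfdna_by_vital_status", "roc_cfdna_mortality",
                    "roc_cfdna_gt2_mutations", "km_os_by_cfdna_gt2",
                    "km_recurrence_by_ratio_gt6", "cox_univariate_death",
                    "cox_dichotomized_recurrence", "ratio_by_mvi")
                  %in% names(rep$results)))
  expect_equal(nrow(rep$skipped), 0L)
  # JSON serialization round-trips
  path <- withr::local_tempfile(fileext = ".json")
  pv_report_json(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$results$roc_cfdna_mortality$auc,
               rep$results$roc_cfdna_mortality$auc)
})

test_that("degenerate cohorts degrade gracefully with reasons", {
  co <- pv_simulate_cohort(n_patients = 40, seed = 22)
  co$n_mutations <- 0L
  co$n_genes <- 0L
  co$ratio <- NULL
  rep <- pv_prognostic_report(co)
  # burden-based groupings collapse to one level -> skipped, not crashed
  expect_gt(nrow(rep$skipped), 0)
  expect_true(all(nzchar(rep$skipped$reason)))
  expect_error(pv_prognostic_report(co[, c("cfdna_conc", "os_time")]),
               "missing required columns")
})

test_that("dichotomized log-rank p-values are near-uniform under the null", {
  set.seed(61)
  pvals <- replicate(120, {
    co <- pv_simulate_cohort(n_patients = 80, coef_death = NULL,
                             coef_recurrence = NULL,
                             group_log_hr = c(death = 0, recurrence = 0),
                             seed = sample.int(1e6, 1))
    co$grp <- factor(ifelse(co$cfdna_conc > 2, "high", "low"),
                     levels = c("high", "low"))
    if (length(unique(co$grp)) < 2 || sum(co$death_event) == 0) NA_real_
    else pv_km_logrank(co, "os_time", "death_event", "grp")$logrank_p
  })
  pvals <- pvals[!is.na(pvals)]
  ks <- suppressWarnings(stats::ks.test(pvals, "punif")$statistic)
  expect_lt(unname(ks), 0.15)
})

test_that("longitudinal tables track per-gene totals and variant turnover", {
  mk_calls <- function(labels, genes, freqs) {
    tibble::tibble(gene = genes, genomic_label = labels, frequency = freqs)
  }
  # baseline: one TERT promoter variant; relapse visit: 37 variants over
  # the five genes (16/9/6/4/2); post-ablation: 4 TERT variants
  sizes <- c(TERT = 16, TP53 = 9, AXIN1 = 6, ARID1A = 4, CTNNB1 = 2)
  big <- mk_calls(
    labels = unlist(lapply(names(sizes), function(g)
      paste0(g, ":", seq_len(sizes[[g]])))),
    genes = rep(names(sizes), sizes),
    freqs = rep(0.05, sum(sizes)))
  visits <- tibble::tibble(
    months = c(0, 31, 40),
    cfdna_conc = c(1.03, 1.99, 1.27),
    calls = list(
      mk_calls("TERT:1", "TERT", 0.12),
      big,
      big[big$genomic_label %in% paste0("TERT:", 1:4), ]))
  dyn <- pv_dynamics(visits)
  expect_equal(dyn$timepoints$n_mutations, c(1L, 37L, 4L))
  expect_equal(dyn$timepoints$months_from_baseline, c(0, 31, 40))
  gc31 <- dyn$timepoints$gene_counts[[2]]
  expect_equal(setNames(gc31$n, gc31$gene),
               c(TERT = 16L, TP53 = 9L, AXIN1 = 6L, ARID1A = 4L, CTNNB1 = 2L))

  tr <- dyn$trajectories
  expect_equal(tr$status[tr$variant == "TERT:1" & tr$months == 0], "baseline")
  expect_equal(tr$status[tr$variant == "TERT:1" & tr$months == 31],
               "persistent")
  expect_equal(tr$status[tr$variant == "TP53:1" & tr$months == 31], "new")
  # TP53:1 vanishes at the third visit
  expect_equal(tr$status[tr$variant == "TP53:1" & tr$months == 40], "lost")

  single <- pv_dynamics(visits[1, ])
  expect_equal(nrow(single$timepoints), 1L)
  expect_error(pv_dynamics(dplyr::bind_rows(visits, visits[1, ])),
               "duplicate")
})

test_that("tidiers and autoplot methods return the documented shapes", {
  co <- pv_simulate_cohort(n_patients = 150, seed = 71)
  r <- pv_roc(co, "cfdna_conc", "death_event")
  expect_s3_class(tidy(r), "tbl_df")
  expect_named(glance(r), c("auc", "optimal_cutoff", "n_pos", "n_neg"))
  expect_s3_class(autoplot(r), "ggplot")

  co$grp <- ifelse(co$cfdna_conc > 2, "high", "low")
  km <- pv_km_logrank(co, "os_time", "death_event", "grp")
  expect_s3_class(tidy(km), "tbl_df")
  expect_true(all(c("logrank_p", "rmean_high", "rmean_low") %in%
                    names(glance(km))))
  expect_s3_class(autoplot(km), "ggplot")

  cx <- pv_cox(co, "os_time", "death_event", c("n_mutations", "n_genes"))
  expect_s3_class(tidy(cx), "tbl_df")
  expect_equal(glance(cx)$n_terms, 2L)
})
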