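test_that("burden metrics and dichotomies follow strict cut-off semantics", {
  prof <- tibble::tibble(n_mutations = c(12L, 0L, 5L),
                         cfdna_conc = c(2, 3, 1))
  b <- pv_burden(prof)
  expect_equal(b$ratio, c(6, 0, 5))
  # ratio exactly 6 is NOT high under the strict '>' rule
  expect_false(pv_classify_high(b$ratio[1], 6))
  # 5 mutations exceed the '>4' cut-off
  expect_true(pv_classify_high(b$n_mutations[3], 4))

  d <- pv_dichotomies()
  at_cutoff <- setNames(d$cutoff, d$variable)
  for (v in c("cfdna_conc", "n_mutations", "n_genes", "ratio")) {
    expect_false(pv_classify_high(at_cutoff[[v]], at_cutoff[[v]]))
    expect_true(pv_classify_high(at_cutoff[[v]] + 1e-9, at_cutoff[[v]]))
  }

  expect_error(pv_burden(tibble::tibble(n_mutations = 3L, cfdna_conc = 0)),
               "positive")
})

test_that("Mann-Whitney matches exact enumeration and pair counting", {
  d <- tibble::tibble(v = c(1, 2, 3, 10, 11, 12),
                      g = rep(c("a", "b"), each = 3))
  res <- pv_mann_whitney(d, v, g)
  expect_equal(res$u, 0)
  expect_equal(res$u_prime, 9)
  expect_equal(res$p_value, 0.1)  # 2 / choose(6,3) extreme orderings
  expect_equal(res$method, "exact")

  same <- tibble::tibble(v = rep(c(1, 2, 3), 2),
                         g = rep(c("a", "b"), each = 3))
  expect_equal(pv_mann_whitney(same, v, g)$p_value, 1)

  set.seed(7)
  for (i in 1:20) {
    a <- sample(1:10, sample(3:12, 1), replace = TRUE)
    b <- sample(1:10, sample(3:12, 1), replace = TRUE)
    dd <- tibble::tibble(v = c(a, b),
                         g = rep(c("a", "b"), c(length(a), length(b))))
    r <- pv_mann_whitney(dd, v, g)
    expect_equal(r$u, oracle_u(a, b))
    expect_equal(r$u + r$u_prime, length(a) * length(b))
  }

  expect_error(pv_mann_whitney(tibble::tibble(v = 1, g = "a"), v, g),
               "two levels")
})

test_that("ROC analysis equals pair counting and finds the Youden cut-off", {
  sep <- tibble::tibble(v = c(1, 2, 3, 10, 11, 12),
                        y = c(0, 0, 0, 1, 1, 1))
  r <- pv_roc(sep, v, y)
  expect_equal(r$auc, 1)
  # any threshold in [3, 10) is optimal; ties resolve to the lower one
  expect_equal(r$optimal_cutoff, 3)

  set.seed(17)
  null <- tibble::tibble(v = rnorm(4000), y = rbinom(4000, 1, 0.5))
  expect_lt(abs(pv_roc(null, v, y)$auc - 0.5), 0.03)

  for (i in 1:15) {
    v <- sample(1:8, 30, replace = TRUE)
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    d <- tibble::tibble(v = v, y = y)
    expect_equal(pv_roc(d, v, y)$auc, oracle_auc(v[y == 1], v[y == 0]),
                 tolerance = 1e-12)
    # AUC equals the Mann-Whitney probability (shared pair-count oracle)
    mw <- pv_mann_whitney(dplyr::mutate(d, g = factor(ifelse(y == 1, "pos", "neg"),
                                                      levels = c("pos", "neg"))),
                          v, g)
    expect_equal(pv_roc(d, v, y)$auc, mw$u / (mw$n_a * mw$n_b),
                 tolerance = 1e-12)
  }

  expect_error(pv_roc(tibble::tibble(v = 1:3, y = c(1, 1, 1)), v, y),
               "both classes")
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  d <- tibble::tibble(v = rnorm(200), y = rbinom(200, 1, 0.4))
  ours <- pv_roc(d, v, y)$auc
  theirs <- suppressMessages(as.numeric(pROC::auc(pROC::roc(d$y, d$v,
                                                            direction = "<"))))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("Kaplan-Meier estimates match closed forms and the log-rank oracle", {
  # 3 subjects, events at 1, 2, 3: S = 2/3, 1/3, 0
  d3 <- tibble::tibble(t = c(1, 2, 3), e = 1, g = "all")
  d3b <- dplyr::bind_rows(d3, tibble::tibble(t = c(1, 2, 3), e = 1, g = "b"))
  km <- pv_km_logrank(d3b, t, e, g)
  s_all <- km$curves[km$curves$group == "all", ]
  expect_equal(s_all$survival, c(2/3, 1/3, 0))

  # without censoring KM equals the empirical survival fraction
  set.seed(31)
  tt <- rexp(60, 0.1)
  dd <- tibble::tibble(t = tt, e = 1, g = rep(c("x", "y"), 30))
  km2 <- pv_km_logrank(dd, t, e, g)
  for (grp in c("x", "y")) {
    cc <- km2$curves[km2$curves$group == grp, ]
    emp <- vapply(cc$time, function(u) mean(tt[dd$g == grp] > u), numeric(1))
    expect_equal(cc$survival, emp, tolerance = 1e-12)
    expect_true(all(diff(cc$survival) <= 1e-12))
  }

  # toy two-group set: log-rank chi-square equals the hypergeometric sum
  toy <- tibble::tibble(t = c(1, 3, 5, 2, 4, 6), e = c(1, 1, 0, 1, 1, 1),
                        g = rep(c("a", "b"), each = 3))
  km3 <- pv_km_logrank(toy, t, e, g)
  expect_equal(km3$logrank_chisq, oracle_logrank(toy$t, toy$e, toy$g),
               tolerance = 1e-9)

  # no events: undefined log-rank reported as NA, rmean = horizon
  none <- tibble::tibble(t = rep(5, 6), e = 0, g = rep(c("a", "b"), 3))
  km4 <- pv_km_logrank(none, t, e, g)
  expect_true(is.na(km4$logrank_p))
  expect_equal(km4$mean_survival$rmean, c(5, 5))

  expect_error(pv_km_logrank(dplyr::mutate(toy, g = "one"), t, e, g),
               "two")
})

test_that("Cox fits are null-stable and agree with a direct partial likelihood", {
  # duplicated groups: HR approximately 1
  set.seed(41)
  base <- tibble::tibble(t = rexp(100, 0.1), e = rbinom(100, 1, 0.8))
  dup <- dplyr::bind_rows(dplyr::mutate(base, x = 0), dplyr::mutate(base, x = 1))
  cx <- pv_cox(dup, "t", "e", "x")
  expect_equal(cx$hr[1], 1, tolerance = 1e-8)

  # tiny binary example: coefficient equals the brute-force maximiser of
  # the Efron partial likelihood
  toy <- tibble::tibble(t = c(1, 4, 2, 3), e = c(1, 0, 1, 1),
                        x = c(0, 0, 1, 1))
  cxt <- pv_cox(toy, "t", "e", "x")
  # distinct event times at 1 (x=0), 2, 3 (x=1): partial log-likelihood
  pll <- function(b) {
    log(1 / (2 * exp(b) + 2)) +            # event at t=1, risk {all}
      log(exp(b) / (2 * exp(b) + 1)) +     # event at t=2, risk {4,2,3}
      log(exp(b) / (exp(b) + 1))           # event at t=3, risk {4,3}
  }
  bhat <- stats::optimize(pll, c(-10, 10), maximum = TRUE)$maximum
  expect_equal(log(cxt$hr[1]), bhat, tolerance = 1e-4)

  # parameter recovery on simulated exponential survival, true HR 2
  set.seed(51)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.05 * exp(log(2) * x))
  d <- tibble::tibble(t = pmin(tt, 30), e = as.integer(tt <= 30), x = x)
  cr <- pv_cox(d, "t", "e", "x")
  expect_true(cr$ci_low[1] <= 2 && 2 <= cr$ci_high[1])
  expect_equal(cr$hr[1], 2, tolerance = 0.15)

  # dichotomized covariates are binarized before fitting
  d$burden <- stats::rpois(n, 3) + 3 * x
  dich <- tibble::tibble(variable = "burden", cutoff = 4)
  cd <- pv_cox(d, "t", "e", "burden", dichotomies = dich)
  expect_equal(cd$term[1], "burden_gt4")

  # very small fits still return an estimate but carry a diagnostic flag
  small <- d[1:8, ]
  cs <- pv_cox(small, "t", "e", "x")
  expect_match(cs$diagnostic[1], "fewer than 10|converge|infinite")
})

test_that("cohort simulation honours its hazard model and seed contract", {
  # null coefficients: mean log-HR between burden groups is ~0 across
  # replicates (averaging removes single-draw sampling noise)
  null_hr <- c(death = 0, recurrence = 0)
  loghr <- vapply(1:20, function(s) {
    co <- pv_simulate_cohort(n_patients = 2000, coef_death = NULL,
                             coef_recurrence = NULL,
                             group_log_hr = null_hr, seed = s)
    co$high <- as.integer(co$n_genes > 2)
    log(pv_cox(co, "os_time", "death_event", "high")$hr[1])
  }, numeric(1))
  expect_lt(abs(mean(loghr)), 0.08)

  # ln(2) per mutated gene: univariate fit recovers HR 2 within its CI
  co2 <- pv_simulate_cohort(n_patients = 2000,
                            coef_death = c(n_genes = log(2)),
                            group_log_hr = null_hr,
                            seed = 4)
  cx2 <- pv_cox(co2, "os_time", "death_event", "n_genes")
  expect_true(cx2$ci_low[1] <= 2 && 2 <= cx2$ci_high[1])

  # horizon 0: everything censored at 0
  co3 <- pv_simulate_cohort(n_patients = 50, horizon_months = 0, seed = 5)
  expect_true(all(co3$os_time == 0))
  expect_equal(sum(co3$death_event), 0L)
  expect_equal(sum(co3$recurrence_event), 0L)

  # reproducibility
  expect_identical(pv_simulate_cohort(n_patients = 40, seed = 9),
                   pv_simulate_cohort(n_patients = 40, seed = 9))

  # calibration: group cfDNA medians sit near their configured targets
  big <- pv_simulate_cohort(n_patients = 6000, seed = 10)
  med <- tapply(big$cfdna_conc, big$risk_group, median)
  expect_equal(unname(med["high"]), 2.90, tolerance = 0.1)
  expect_equal(unname(med["low"]), 0.98, tolerance = 0.1)
})
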