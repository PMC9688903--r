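test_that("Kaplan-Meier estimate matches hand product-limit computations", {
  # no events: no steps at all
  rec <- data.frame(patient_id = paste0("p", 1:5), time = 1:5, event = 0)
  km <- km_estimate(rec)
  expect_length(km$event_times, 0)
  expect_equal(km$n, 5)

  # all events at 1, 2, 3
  rec <- data.frame(patient_id = paste0("p", 1:3), time = 1:3, event = 1)
  km <- km_estimate(rec)
  expect_equal(km$event_times, c(1, 2, 3))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$at_risk, c(3, 2, 1))

  # censoring at 1.5 reduces the risk set without a step
  rec <- data.frame(patient_id = paste0("p", 1:3), time = c(1, 1.5, 3), event = c(1, 0, 1))
  km <- km_estimate(rec)
  expect_equal(km$event_times, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0))

  expect_error(
    km_estimate(data.frame(patient_id = "p1", time = 0, event = 1)),
    class = "sulfscan_validation_error"
  )
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(5)
  t <- sort(sample(1:100, 20))
  rec <- data.frame(patient_id = paste0("p", 1:20), time = t, event = 1)
  km <- km_estimate(rec)
  emp <- vapply(km$event_times, function(x) mean(t > x), numeric(1))
  expect_equal(km$survival, emp)
})

test_that("log-rank test is label-symmetric and matches the O-E/V oracle", {
  rec <- data.frame(
    patient_id = paste0("p", 1:4), time = c(1, 2, 3, 4), event = 1
  )
  g <- c("A", "A", "B", "B")
  res <- logrank_test(rec, g)
  ora <- oracle_logrank(rec$time, rec$event, g)
  expect_equal(res$chi2, ora$chi2, tolerance = 1e-12)
  expect_equal(res$p_value, ora$p_value, tolerance = 1e-12)

  flipped <- logrank_test(rec, rev(g))
  expect_equal(flipped$chi2, res$chi2)

  set.seed(6)
  rec <- make_survival_fixture(30)
  g <- rep(c("lo", "hi"), 15)
  res <- logrank_test(rec, g)
  ora <- oracle_logrank(rec$time, rec$event, g)
  expect_equal(res$chi2, ora$chi2, tolerance = 1e-9)

  # two identical copies of a group, labels alternating: chi2 ~ 0
  rec2 <- data.frame(
    patient_id = paste0("q", 1:20),
    time = rep(rec$time[1:10], 2), event = rep(rec$event[1:10], 2)
  )
  res2 <- logrank_test(rec2, rep(c("a", "b"), each = 10))
  expect_lt(res2$chi2, 1e-10)

  expect_error(logrank_test(rec, rep("A", 30)), class = "sulfscan_validation_error")
})

test_that("cutpoint search enforces the 25% constraint and degenerate input", {
  set.seed(7)
  rec <- make_survival_fixture(8)
  x <- rnorm(8)
  res <- minp_cutpoint(x, rec, min_frac = 0.25)
  expect_gte(min(res$n_high, res$n_low), 2)
  expect_equal(res$n_high + res$n_low, 8)
  expect_true(res$cutoff %in% x)

  expect_error(minp_cutpoint(rep(1, 10), make_survival_fixture(10)),
               class = "sulfscan_no_valid_cutpoint")
  expect_error(minp_cutpoint(rnorm(5), make_survival_fixture(5)),
               class = "sulfscan_insufficient_data")
})

test_that("returned p is minimal over every admissible threshold", {
  set.seed(8)
  rec <- make_survival_fixture(30)
  x <- rlnorm(30)
  res <- minp_cutpoint(x, rec)
  need <- ceiling(0.25 * 30)
  for (c in sort(unique(x))) {
    g <- x > c
    if (min(sum(g), 30 - sum(g)) < need) next
    p <- oracle_logrank(rec$time, rec$event, g)$p_value
    expect_gte(p + 1e-12, res$p_value)
  }
})

test_that("permutation adjustment for the search is reproducible and valid", {
  set.seed(9)
  rec <- make_survival_fixture(40)
  x <- rnorm(40) # no real association
  r1 <- minp_cutpoint(x, rec, adjust_b = 50, seed = 3)
  r2 <- minp_cutpoint(x, rec, adjust_b = 50, seed = 3)
  expect_equal(r1$p_adjusted, r2$p_adjusted)
  expect_gt(r1$p_adjusted, 0)
  # adjusted p accounts for the optimization: never smaller than nominal min p
  expect_gte(r1$p_adjusted, r1$p_value)
})

test_that("Cox fit is symmetric for exchangeable groups and flags issues", {
  # identical event patterns in both arms: beta = 0, HR = 1
  rec <- data.frame(
    patient_id = paste0("p", 1:12),
    time = rep(c(50, 120, 200, 310, 420, 500), 2),
    event = rep(c(1, 1, 0, 1, 0, 1), 2)
  )
  cov <- data.frame(group = rep(c(0, 1), each = 6))
  fit <- cox_fit(rec, cov)
  expect_equal(fit$coefficients$beta, 0, tolerance = 1e-8)
  expect_equal(fit$coefficients$hazard_ratio, 1, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_true(fit$coefficients$ci_low <= 1 && 1 <= fit$coefficients$ci_high)

  expect_error(cox_fit(rec, data.frame(group = rep("a", 12))),
               class = "sulfscan_validation_error")
  norec <- rec
  norec$event <- 0
  expect_error(cox_fit(norec, cov), class = "sulfscan_insufficient_data")

  # missing covariates dropped casewise with a message
  cov2 <- cov
  cov2$group[1] <- NA
  expect_message(fit2 <- cox_fit(rec, cov2), "dropped")
  expect_equal(fit2$n, 11)
})

test_that("Cox beta estimates are consistent as n grows", {
  beta_true <- log(2)
  bias <- vapply(c(100, 400, 1600), function(n) {
    coh <- gen_survival_cohort(n, beta_true, beta_age = 0, seed = 1000 + n)
    cov <- data.frame(high = as.numeric(coh$expression > coh$cutoff))
    fit <- cox_fit(coh$records, cov)
    abs(fit$coefficients$beta - beta_true)
  }, numeric(1))
  expect_lt(bias[3], 0.15)
  expect_lt(bias[3], bias[1] + 0.05) # shrinking with n, allowing noise
})

test_that("stage-stratified analysis handles pure and missing strata", {
  coh <- gen_survival_cohort(60, log(2), seed = 12)
  ann <- data.frame(
    sample_id = coh$records$patient_id, condition = "tumor",
    stage = rep(c("I", "II"), 30),
    age = coh$covariates$age
  )
  expect_warning(
    res <- stage_stratified_survival(coh$expression, coh$records,
                                     validate_annotations(ann)),
    "late"
  )
  expect_null(res$late)
  unstrat <- minp_cutpoint(unname(coh$expression[coh$records$patient_id]), coh$records)
  expect_equal(res$early$cutpoint$cutoff, unstrat$cutoff)
  expect_equal(res$early$cutpoint$p_value, unstrat$p_value)

  ann$stage <- NA_character_
  expect_error(
    stage_stratified_survival(coh$expression, coh$records, ann),
    class = "sulfscan_insufficient_data"
  )
})

test_that("a stage-restricted effect shows up in the matching stratum", {
  hits_early <- 0
  early_beats_late <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    early <- gen_survival_cohort(200, log(2.3), beta_age = 0, seed = 7000 + i)
    late <- gen_survival_cohort(200, 0, beta_age = 0, seed = 8000 + i)
    late$records$patient_id <- sub("PT", "LT", late$records$patient_id)
    names(late$expression) <- late$records$patient_id
    records <- rbind(early$records, late$records)
    expr <- c(early$expression, late$expression)
    ann <- validate_annotations(data.frame(
      sample_id = records$patient_id, condition = "tumor",
      stage = rep(c("II", "III"), each = 200)
    ))
    res <- stage_stratified_survival(expr, records, ann, use_covariates = FALSE)
    p_early <- res$early$cutpoint$p_value
    p_late <- res$late$cutpoint$p_value
    if (p_early < 0.05) hits_early <- hits_early + 1
    if (p_early < p_late) early_beats_late <- early_beats_late + 1
  }
  expect_gte(hits_early, 15)
  expect_gte(early_beats_late, 15)
})
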