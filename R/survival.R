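# Kaplan-Meier / log-rank / Cox modeling and the constrained minimal-p-value
# expression cutpoint search used to dichotomize a continuous biomarker.

#' Kaplan-Meier product-limit estimate
#'
#' @param records Validated survival data.frame (`patient_id`, `time`,
#'   `event`); see [validate_survival()].
#' @return An object of class `km_estimate` with `event_times` (times at
#'   which at least one event occurred), `survival` (the estimate just after
#'   each event time), `at_risk` (numbers at risk at each event time) and
#'   `n`. Censored times reduce the risk set without producing steps.
#' @export
km_estimate <- function(records) {
  records <- validate_survival(records)
  if (!nrow(records)) insufficient_data_error("no survival records")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  has_event <- fit$n.event > 0
  structure(
    list(
      event_times = fit$time[has_event],
      survival = fit$surv[has_event],
      at_risk = fit$n.risk[has_event],
      n = nrow(records)
    ),
    class = "km_estimate"
  )
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf(
    "Kaplan-Meier estimate: n = %d, %d event times, final S(t) = %.3f\n",
    x$n, length(x$event_times),
    if (length(x$survival)) x$survival[length(x$survival)] else 1
  ))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected events summed over distinct event times with the
#' hypergeometric variance; 1-df chi-square statistic and two-sided p.
#'
#' @inheritParams km_estimate
#' @param group_labels Two-level grouping vector aligned with `records` rows.
#' @return List with `chi2` and `p_value`.
#' @export
logrank_test <- function(records, group_labels) {
  records <- validate_survival(records)
  g <- as.factor(group_labels)
  if (length(g) != nrow(records)) {
    validation_error("group labels must align with survival records")
  }
  if (nlevels(droplevels(g)) != 2) {
    validation_error("log-rank test requires exactly 2 non-empty groups")
  }
  sd <- survival::survdiff(
    survival::Surv(records$time, records$event) ~ g
  )
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Log-rank chi-square for many thresholds at once. Z is an n x K 0/1 matrix
# of "high" indicators (one column per candidate cutoff); returns a K-vector
# of chi-square statistics. Works on the distinct-event-time table so the
# whole scan costs two matrix products.
logrank_chi2_scan <- function(time, event, Z) {
  tt <- sort(unique(time[event == 1]))
  if (!length(tt)) return(rep(NA_real_, ncol(Z)))
  at_risk <- outer(tt, time, "<=") * 1 # at_risk[j, i]: subject i still at risk at tt[j]
  at_event <- outer(tt, time, "==") *
    matrix(event, nrow = length(tt), ncol = length(time), byrow = TRUE)
  n_j <- rowSums(at_risk)
  d_j <- rowSums(at_event)
  n1 <- at_risk %*% Z # J x K subjects at risk in high arm
  d1 <- at_event %*% Z # J x K events in high arm
  frac <- n1 / n_j
  O <- colSums(d1)
  E <- colSums(d_j * frac)
  vmult <- ifelse(n_j > 1, (n_j - d_j) / (n_j - 1), 0)
  V <- colSums(d_j * frac * (1 - frac) * vmult)
  chi2 <- ifelse(V > 0, (O - E)^2 / V, 0)
  as.numeric(chi2)
}

#' Constrained minimal-p-value expression cutpoint
#'
#' Scans every distinct observed expression value as a threshold (high
#' defined as value strictly greater than the cutoff), keeps only thresholds
#' where both arms retain at least `ceiling(min_frac * n)` patients, and
#' returns the admissible threshold minimizing the log-rank p-value. Ties on
#' p are broken toward the cutoff closest to the median expression, then the
#' smaller value. The returned p is the minimal log-rank p, unadjusted for
#' the search; see `adjust_b` for a permutation-adjusted alternative.
#'
#' @param expression_values Numeric expression vector, one value per patient,
#'   aligned with `records` (by position, or by `patient_id` when named).
#' @param records Validated survival data.frame.
#' @param min_frac Minimum fraction of patients required in each arm
#'   (default 0.25).
#' @param adjust_b If > 0, additionally report `p_adjusted`: the fraction of
#'   `adjust_b` label permutations whose full constrained search attains a
#'   minimal p at most the observed one (add-one rule).
#' @param seed Seed for the permutation adjustment.
#' @return An object of class `cutpoint_result` with `cutoff`, `p_value`,
#'   `chi2`, `n_high`, `n_low`, `candidates_scanned` and optionally
#'   `p_adjusted`.
#' @export
minp_cutpoint <- function(expression_values, records, min_frac = 0.25,
                          adjust_b = 0, seed = NULL) {
  records <- validate_survival(records)
  x <- expression_values
  if (!is.null(names(x))) {
    if (!all(records$patient_id %in% names(x))) {
      validation_error("expression values missing for some patients")
    }
    x <- unname(x[records$patient_id])
  }
  n <- nrow(records)
  if (length(x) != n) validation_error("expression and records must align")
  if (any(is.na(x))) validation_error("missing expression values not allowed in cutpoint search")
  if (n < 8) insufficient_data_error("cutpoint search requires n >= 8, got ", n)
  need <- ceiling(min_frac * n)

  cand <- sort(unique(x))
  n_high_all <- vapply(cand, function(c) sum(x > c), integer(1))
  admissible <- pmin(n_high_all, n - n_high_all) >= need
  if (!any(admissible)) {
    sulf_error(
      paste0("no threshold leaves >= ", need, " patients in both arms"),
      "sulfscan_no_valid_cutpoint"
    )
  }
  cand <- cand[admissible]
  Z <- outer(x, cand, ">") * 1
  chi2 <- logrank_chi2_scan(records$time, records$event, Z)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)

  med <- stats::median(x)
  best <- which(p == min(p))
  if (length(best) > 1) {
    dist <- abs(cand[best] - med)
    best <- best[dist == min(dist)]
    best <- best[which.min(cand[best])]
  }
  cut <- cand[best]
  res <- structure(
    list(
      cutoff = cut,
      p_value = p[best],
      chi2 = chi2[best],
      n_high = sum(x > cut),
      n_low = sum(x <= cut),
      candidates_scanned = length(cand)
    ),
    class = "cutpoint_result"
  )
  if (adjust_b > 0) {
    if (!is.null(seed)) {
      res$p_adjusted <- with_seed(seed, minp_adjust(x, records, min_frac, adjust_b, res$p_value))
    } else {
      res$p_adjusted <- minp_adjust(x, records, min_frac, adjust_b, res$p_value)
    }
  }
  res
}

# Permutation adjustment for the cutoff optimization: re-run the full
# constrained search on label-permuted expression and compare minimal p's.
minp_adjust <- function(x, records, min_frac, b, observed_p) {
  hits <- 0L
  for (i in seq_len(b)) {
    xp <- sample(x)
    res <- tryCatch(
      minp_cutpoint(xp, records, min_frac = min_frac),
      sulfscan_error = function(e) NULL
    )
    if (!is.null(res) && res$p_value <= observed_p) hits <- hits + 1L
  }
  (1 + hits) / (1 + b)
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(
    "Minimal-p cutpoint: cutoff = %.4g (high n = %d, low n = %d)\n  log-rank chi2 = %.3f, p = %.3g (%d admissible thresholds scanned%s)\n",
    x$cutoff, x$n_high, x$n_low, x$chi2, x$p_value, x$candidates_scanned,
    if (!is.null(x$p_adjusted)) sprintf("; search-adjusted p = %.3g", x$p_adjusted) else ""
  ))
  invisible(x)
}

#' Multivariable Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood with Efron tie handling and reports, per
#' covariate, the coefficient, hazard ratio, Wald 95% confidence interval and
#' p-value. Rows with missing covariates are dropped casewise with a logged
#' count. Non-convergence and likely monotone-likelihood (separation)
#' situations are flagged rather than silently accepted.
#'
#' @inheritParams km_estimate
#' @param covariate_table Data.frame of numeric covariates (binary factors
#'   encoded 0/1), one row per record.
#' @return An object of class `cox_result`: `coefficients` data.frame
#'   (`term`, `beta`, `hazard_ratio`, `ci_low`, `ci_high`, `p_value`),
#'   `loglik`, `n`, `n_events`, `converged`, `separation`.
#' @export
cox_fit <- function(records, covariate_table) {
  records <- validate_survival(records)
  stopifnot(is.data.frame(covariate_table))
  if (nrow(covariate_table) != nrow(records)) {
    validation_error("covariate table must have one row per survival record")
  }
  if (!all(vapply(covariate_table, is.numeric, logical(1)))) {
    validation_error("covariates must be numeric (encode binary groups as 0/1)")
  }
  keep <- stats::complete.cases(covariate_table)
  if (any(!keep)) {
    message(sum(!keep), " record(s) dropped for missing covariates")
  }
  records <- records[keep, , drop = FALSE]
  covariate_table <- covariate_table[keep, , drop = FALSE]
  if (sum(records$event) < 1) insufficient_data_error("no events in the data")
  dat <- cbind(records[c("time", "event")], covariate_table)
  converged <- TRUE
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(time, event) ~ ., data = dat, ties = "efron",
      control = survival::coxph.control(eps = 1e-9, iter.max = 100)
    ),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("Ran out of iterations", msg)) converged <<- FALSE
      if (grepl("infinite|converged before", msg)) separation <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(0.975)
  coefs <- data.frame(
    term = names(beta),
    beta = unname(beta),
    hazard_ratio = unname(exp(beta)),
    ci_low = unname(exp(beta - z * se)),
    ci_high = unname(exp(beta + z * se)),
    p_value = unname(2 * stats::pnorm(-abs(beta / se))),
    stringsAsFactors = FALSE
  )
  if (separation) {
    warning("monotone likelihood suspected; coefficient estimates unreliable")
  }
  if (!converged) warning("Cox fit did not converge in 100 iterations")
  structure(
    list(
      coefficients = coefs,
      loglik = fit$loglik[length(fit$loglik)],
      n = nrow(dat),
      n_events = sum(dat$event),
      converged = converged,
      separation = separation
    ),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf(
    "Cox proportional-hazards fit: n = %d, events = %d%s\n",
    x$n, x$n_events, if (!x$converged) " [NOT CONVERGED]" else ""
  ))
  df <- x$coefficients
  for (i in seq_len(nrow(df))) {
    cat(sprintf(
      "  %s: HR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
      df$term[i], df$hazard_ratio[i], df$ci_low[i], df$ci_high[i], df$p_value[i]
    ))
  }
  invisible(x)
}

#' Stage-stratified cutpoint and Cox analysis
#'
#' Runs [minp_cutpoint()] and a [cox_fit()] of the resulting high/low split
#' (plus optional age/gender covariates) separately within the early
#' (stage I/II) and late (stage III/IV) strata. Patients with missing stage
#' are excluded with a logged count; a stratum with fewer than 8 patients is
#' skipped with a warning.
#'
#' @param expression_values Named numeric vector of expression, names are
#'   patient ids.
#' @param records Validated survival data.frame.
#' @param annotations Annotation data.frame whose `sample_id` matches
#'   `patient_id` and carries `stage` (and optionally `age`, `gender`).
#' @param min_frac Passed to [minp_cutpoint()].
#' @param use_covariates Include `age` and 0/1-encoded `gender` in the Cox
#'   model when available (default TRUE).
#' @return List with elements `early` and `late` (each either NULL or a list
#'   `cutpoint`, `cox`, `n`) and `n_missing_stage`.
#' @export
stage_stratified_survival <- function(expression_values, records, annotations,
                                      min_frac = 0.25, use_covariates = TRUE) {
  records <- validate_survival(records)
  stage <- annotations$stage[match(records$patient_id, annotations$sample_id)]
  n_missing <- sum(is.na(stage))
  if (n_missing) message(n_missing, " patient(s) excluded for missing stage")
  if (all(is.na(stage))) {
    insufficient_data_error("stage is missing for every patient")
  }
  run_stratum <- function(keep, label) {
    idx <- which(keep)
    if (length(idx) < 8) {
      warning("stratum '", label, "' has ", length(idx), " patients; skipped")
      return(NULL)
    }
    rec <- records[idx, , drop = FALSE]
    x <- expression_values[rec$patient_id]
    cp <- minp_cutpoint(unname(x), rec, min_frac = min_frac)
    cov <- data.frame(high = as.numeric(x > cp$cutoff))
    if (use_covariates) {
      ann_idx <- match(rec$patient_id, annotations$sample_id)
      age <- annotations$age[ann_idx]
      gender <- annotations$gender[ann_idx]
      if (!all(is.na(age))) cov$age <- age
      if (!all(is.na(gender))) {
        cov$gender <- as.numeric(factor(gender)) - 1
      }
    }
    list(cutpoint = cp, cox = cox_fit(rec, cov), n = length(idx))
  }
  list(
    early = run_stratum(!is.na(stage) & stage %in% c("I", "II"), "early"),
    late = run_stratum(!is.na(stage) & stage %in% c("III", "IV"), "late"),
    n_missing_stage = n_missing
  )
}
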