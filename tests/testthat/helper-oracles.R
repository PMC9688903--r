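# Independent brute-force oracles. These deliberately re-derive each
# statistic from first principles (full enumeration, closed forms, direct
# tabulation) so they share no code path with the package implementation.

# Exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign
# assignments of the ranks of |d| (requires no zero and no tied |d|).
oracle_signed_rank_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  n <- length(d)
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(p, 1)
}

# Exact two-sided rank-sum p by enumerating all C(n1+n2, n1) assignments of
# the joint ranks to group A (requires no ties).
oracle_rank_sum_p <- function(a, b) {
  stopifnot(!anyDuplicated(c(a, b)))
  n1 <- length(a)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(r), n1)
  w_all <- colSums(matrix(r[combos], nrow = n1))
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(p, 1)
}

# Log-rank chi-square from a direct tabulation over distinct event times.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) - 1L # 0/1
  tt <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in tt) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & g == 1)
    d_j <- sum(time == t & event == 1)
    d1_j <- sum(time == t & event == 1 & g == 1)
    O <- O + d1_j
    E <- E + d_j * n1_j / n_j
    if (n_j > 1) {
      V <- V + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  chi2 <- if (V > 0) (O - E)^2 / V else 0
  list(chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Exhaustive constrained minimal-p scan built on survival::survdiff, with
# the same admissibility and tie-break rules as the documented contract.
oracle_minp_scan <- function(x, records, min_frac = 0.25) {
  n <- length(x)
  need <- ceiling(min_frac * n)
  srv <- survival::Surv(records$time, records$event)
  best <- NULL
  scanned <- 0L
  for (c in sort(unique(x))) {
    g <- x > c
    if (min(sum(g), n - sum(g)) < need) next
    scanned <- scanned + 1L
    sd <- survival::survdiff(srv ~ g)
    p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    cand <- list(cutoff = c, p = p, dist = abs(c - median(x)))
    if (is.null(best) ||
      p < best$p ||
      (p == best$p && cand$dist < best$dist) ||
      (p == best$p && cand$dist == best$dist && c < best$cutoff)) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  list(cutoff = best$cutoff, p_value = best$p, candidates_scanned = scanned)
}

# Cox log partial likelihood for a single covariate without ties, written
# out directly; maximized on a bounded interval.
oracle_cox_beta <- function(time, event, x) {
  stopifnot(!anyDuplicated(time[event == 1]))
  loglik <- function(beta) {
    s <- 0
    for (i in which(event == 1)) {
      at_risk <- time >= time[i]
      s <- s + beta * x[i] - log(sum(exp(beta * x[at_risk])))
    }
    s
  }
  stats::optimize(loglik, c(-20, 20), maximum = TRUE, tol = 1e-9)$maximum
}

# BH step-up by hand: p_(i) * m / i, cumulative minimum from the largest,
# capped at 1, reported in the original order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Welch two-sample t-test p-value from the closed form.
oracle_welch_p <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}

# Mean and SD of a Normal(mu, sigma) truncated to (0, Inf).
truncnorm_moments <- function(mu, sigma) {
  alpha <- -mu / sigma
  lambda <- dnorm(alpha) / (1 - pnorm(alpha))
  m <- mu + sigma * lambda
  s <- sigma * sqrt(1 + alpha * lambda - lambda^2)
  c(mean = m, sd = s)
}
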