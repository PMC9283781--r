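# Independent oracles and small fixture builders used across the suite.
# The oracles are deliberately naive re-implementations (loops, enumeration,
# grid search) kept separate from the package's computation paths.

# Tiny expression + clinical pair with the given per-stage sample counts and
# per-gene stage means on the log2 scale (exact, no noise).
make_fixture <- function(stage_means, n_per_stage = c(normal = 4, AIS = 4, MIA = 4, LUAD = 4)) {
  stages <- rep(names(n_per_stage), times = n_per_stage)
  samples <- sprintf("S%03d", seq_along(stages))
  tpm <- t(vapply(seq_len(nrow(stage_means)), function(i) {
    2^stage_means[i, stages]
  }, numeric(length(stages))))
  colnames(tpm) <- samples
  expr <- dplyr::bind_cols(
    tibble::tibble(gene = rownames(stage_means)),
    tibble::as_tibble(tpm)
  )
  clinical <- tibble::tibble(
    patient_id = paste0("P", seq_along(samples)),
    sample_id = samples,
    stage = stages
  )
  list(expr = expr, clinical = clinical)
}

# Hand-coded product-limit estimator.
km_oracle <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ev_times, survival = NA_real_)
  for (k in seq_along(ev_times)) {
    t_k <- ev_times[k]
    n_k <- sum(time >= t_k)
    d_k <- sum(time == t_k & event == 1)
    s <- s * (1 - d_k / n_k)
    out$survival[k] <- s
  }
  out
}

# Hand-coded two-group log-rank statistic (hypergeometric variance).
logrank_oracle <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(1, 0), c(length(time_a), length(time_b)))
  ev_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t_k in ev_times) {
    at_risk <- time >= t_k
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1)
    d <- sum(time == t_k & event == 1)
    d1 <- sum(time == t_k & event == 1 & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chi_square = chisq, p_value = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Breslow partial log-likelihood for a binary covariate.
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Coarse-to-fine 1-D grid search of the Breslow partial likelihood.
cox_grid_oracle <- function(time, event, x, lo = -5, hi = 5) {
  for (step in c(0.01, 1e-4)) {
    grid <- seq(lo, hi, by = step)
    ll <- vapply(grid, breslow_loglik, numeric(1), time = time, event = event, x = x)
    best <- grid[which.max(ll)]
    lo <- best - 2 * step
    hi <- best + 2 * step
  }
  best
}

# Two-sided Fisher p by full hypergeometric enumeration on a 2x2 table.
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
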