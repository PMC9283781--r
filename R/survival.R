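#' Split patients at the median TP index
#'
#' Labels patients `"high"` (TP index strictly above the cohort median) or
#' `"low"` (at or below it; ties at the median go low, deterministically).
#'
#' @param index Result of [compute_indices()], or any tibble with
#'   `sample_id` and `tp_index`.
#' @return The input with a `group` column (`"high"`/`"low"`).
#' @export
#' @examples
#' idx <- tibble::tibble(sample_id = letters[1:4], tumor_index = 0,
#'                       immune_index = 0, tp_index = c(1, 2, 3, 4))
#' dichotomize_by_median(idx)$group  # low low high high
dichotomize_by_median <- function(index) {
  if (nrow(index) < 2) abort("Need >= 2 patients to split at the median.")
  v <- index$tp_index
  if (length(unique(v)) == 1) {
    abort("All TP index values are identical; no median split is possible.")
  }
  med <- stats::median(v)
  dplyr::mutate(index, group = ifelse(v > med, "high", "low"))
}

check_survival_records <- function(records) {
  stopifnot(all(c("time", "event") %in% names(records)))
  if (any(records$time < 0)) abort("Survival times must be >= 0.")
  if (!all(records$event %in% c(0, 1))) abort("`event` must be 0 or 1.")
  invisible(records)
}

#' Kaplan-Meier product-limit estimate
#'
#' The product-limit estimator: at each distinct event time `t`,
#' `S <- S * (1 - d_t / n_t)` with `d_t` events among `n_t` at risk;
#' censored times only shrink the risk set. Computed with
#' [survival::survfit()].
#'
#' @param records Tibble with `time` (>= 0) and `event` (1 = event,
#'   0 = censored) columns.
#' @return A tibble with one row per distinct event time: `time`, `n_risk`,
#'   `n_event`, `survival`. `S(0) = 1` is implicit.
#' @export
#' @examples
#' km_estimate(tibble::tibble(time = 1:3, event = 1))$survival  # 2/3 1/3 0
km_estimate <- function(records) {
  if (nrow(records) == 0) abort("Need >= 1 survival record.")
  check_survival_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  keep <- fit$n.event > 0
  tibble(
    time = fit$time[keep],
    n_risk = fit$n.risk[keep],
    n_event = fit$n.event[keep],
    survival = fit$surv[keep]
  )
}

#' Two-group log-rank test
#'
#' The standard log-rank statistic: summed observed-minus-expected events in
#' one group over the pooled event times, with the hypergeometric variance,
#' referred to chi-square with 1 df. Computed with [survival::survdiff()].
#'
#' @param group_a,group_b Tibbles of survival records (`time`, `event`).
#' @return A list: `chi_square`, `p_value`, `n_events`. With zero events the
#'   test is not applicable and both statistics are `NA`.
#' @export
logrank_test <- function(group_a, group_b) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0) {
    abort("Both groups must be non-empty.")
  }
  check_survival_records(group_a)
  check_survival_records(group_b)
  df <- dplyr::bind_rows(
    dplyr::mutate(group_a[, c("time", "event")], group = "A"),
    dplyr::mutate(group_b[, c("time", "event")], group = "B")
  )
  n_events <- sum(df$event)
  if (n_events == 0) {
    return(list(chi_square = NA_real_, p_value = NA_real_, n_events = 0L))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(
    chi_square = unname(sd$chisq),
    p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
    n_events = as.integer(n_events)
  )
}

#' Cox hazard ratio for a binary group label
#'
#' Maximum partial-likelihood estimate (Breslow ties) of the hazard ratio of
#' `"high"` relative to `"low"`, with a Wald 95% confidence interval.
#' Monotone-likelihood fits — all events in one group, so the partial
#' likelihood has no interior maximum — are flagged `estimable = FALSE` and
#' return `NA` numbers rather than a runaway estimate.
#'
#' @param records Tibble with `time`, `event` and a two-level `group` column
#'   (`"high"`/`"low"`).
#' @return A list of class `hr_estimate`: `hr`, `ci_low`, `ci_high`,
#'   `log_hr`, `se_log_hr`, `estimable`, `n_events`.
#' @export
cox_hazard_ratio <- function(records) {
  check_survival_records(records)
  stopifnot("group" %in% names(records))
  groups <- unique(records$group)
  if (length(groups) != 2) abort("`group` must have exactly two levels.")
  if (sum(records$event) == 0) {
    return(structure(list(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          log_hr = NA_real_, se_log_hr = NA_real_,
                          estimable = FALSE, n_events = 0L),
                     class = "hr_estimate"))
  }
  df <- records
  df$group <- factor(df$group, levels = c("low", "high"))
  # no events in one group => monotone partial likelihood, no interior MPLE
  ev_by_group <- tapply(df$event, df$group, sum)
  if (any(ev_by_group == 0)) {
    return(structure(list(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          log_hr = NA_real_, se_log_hr = NA_real_,
                          estimable = FALSE,
                          n_events = as.integer(sum(df$event))),
                     class = "hr_estimate"))
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ group, data = df,
                         ties = "breslow")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  z <- stats::qnorm(0.975)
  structure(list(
    hr = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    log_hr = beta,
    se_log_hr = se,
    estimable = TRUE,
    n_events = as.integer(sum(df$event))
  ), class = "hr_estimate")
}

#' @export
print.hr_estimate <- function(x, ...) {
  if (!x$estimable) {
    cat("Hazard ratio: not estimable (monotone partial likelihood or no events)\n")
  } else {
    cat(sprintf("Hazard ratio %.3f (95%% CI %.3f-%.3f), %d events\n",
                x$hr, x$ci_low, x$ci_high, x$n_events))
  }
  invisible(x)
}

#' Median-split survival stratification
#'
#' The full prognostic workflow: joins per-sample TP indices to per-patient
#' survival, dichotomizes at the median index, and computes the per-group
#' Kaplan-Meier curves, the log-rank test, and the Cox hazard ratio of high
#' versus low.
#'
#' @param index Result of [compute_indices()] on tumor samples.
#' @param clinical Tibble with `sample_id`, `patient_id`, `time`, `event`;
#'   rows with missing follow-up are dropped.
#' @return An object of class `tp_survfit`: a list with `records` (the
#'   labelled survival records), `km` (per-group KM tibble), `logrank`, and
#'   `hr`. Use [generics::tidy()], [generics::glance()] or
#'   [ggplot2::autoplot()] on it.
#' @export
stratify_survival <- function(index, clinical) {
  need <- c("sample_id", "patient_id", "time", "event")
  stopifnot(all(need %in% names(clinical)))
  df <- dplyr::inner_join(index, clinical[, need], by = "sample_id")
  df <- df[!is.na(df$time) & !is.na(df$event), ]
  if (nrow(df) < 2) abort("Need >= 2 patients with follow-up.")
  df <- dichotomize_by_median(df)
  records <- df[, c("patient_id", "time", "event", "group", "tp_index")]
  km <- records |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ km_estimate(.x)) |>
    dplyr::ungroup()
  lr <- logrank_test(records[records$group == "high", ],
                     records[records$group == "low", ])
  hr <- cox_hazard_ratio(records)
  structure(list(records = records, km = km, logrank = lr, hr = hr),
            class = "tp_survfit")
}

#' @export
print.tp_survfit <- function(x, ...) {
  n <- table(x$records$group)
  cat("TP-index median-split survival stratification\n")
  cat("  groups: high n=", n[["high"]], ", low n=", n[["low"]], "\n", sep = "")
  cat(sprintf("  log-rank chi-square %.3f, p = %.4g\n",
              x$logrank$chi_square, x$logrank$p_value))
  print(x$hr)
  invisible(x)
}

#' @method tidy tp_survfit
#' @export
tidy.tp_survfit <- function(x, ...) {
  x$km
}

#' @method glance tp_survfit
#' @export
glance.tp_survfit <- function(x, ...) {
  tibble(
    n = nrow(x$records),
    n_events = x$logrank$n_events,
    logrank_chisq = x$logrank$chi_square,
    logrank_p = x$logrank$p_value,
    hr = x$hr$hr,
    hr_ci_low = x$hr$ci_low,
    hr_ci_high = x$hr$ci_high,
    hr_estimable = x$hr$estimable
  )
}

#' @method autoplot tp_survfit
#' @export
autoplot.tp_survfit <- function(object, ...) {
  # step curves from the per-group KM tables, anchored at S(0) = 1
  km <- object$km |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble(time = 0, n_risk = NA_integer_, n_event = NA_integer_, survival = 1),
      .x
    )) |>
    dplyr::ungroup()
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = "TP index",
                  title = "Survival by median-split TP index") +
    ggplot2::theme_minimal()
}
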