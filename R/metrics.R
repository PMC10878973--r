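# Survival-model evaluation: Harrell concordance on interval-censored
# records, IPCW Brier / integrated Brier score, cumulative/dynamic
# time-dependent AUC, Kaplan-Meier, one-sided log-rank, and clustered
# percentile bootstrap.
#
# Event-time convention throughout: an event is timed at t_prime (the exam
# where progression was observed), a censoring at t. Records are
# administratively censored at the evaluation horizon tau before computing
# rank-based metrics.

#' Evaluation horizon
#'
#' @param tau Horizon in years (default 5, the study follow-up).
#' @param yearly_marks Landmark times for time-dependent AUC (default 1..5).
#' @return An `evaluation_horizon` object.
#' @export
evaluation_horizon <- function(tau = 5, yearly_marks = 1:5) {
  abort_if(tau <= 0, "`tau` must be > 0")
  abort_if(any(yearly_marks > tau), "`yearly_marks` must not exceed `tau`")
  structure(list(tau = tau, yearly_marks = yearly_marks),
            class = "evaluation_horizon")
}

# (time, event) under the convention above, with optional administrative
# censoring at tau.
observed_times <- function(records, tau = NULL) {
  time <- ifelse(records$event == 1L, records$t_prime, records$t)
  event <- as.integer(records$event)
  if (!is.null(tau)) {
    event[time > tau] <- 0L
    time <- pmin(time, tau)
  }
  list(time = time, event = event)
}

#' Harrell concordance index
#'
#' Fraction of comparable pairs ordered concordantly by the predicted times.
#' A pair (i, j) is comparable when subject i has an observed event and its
#' event time precedes subject j's observed time (after administrative
#' censoring at `tau`); it is concordant when the predicted time for i is
#' smaller (earlier predicted event = higher risk); score ties count 0.5.
#'
#' @param predicted_times Numeric vector, one predicted time per record.
#' @param records Survival-records data.frame (`t`, `t_prime`, `event`).
#' @param tau Administrative-censoring horizon in years; `NULL` disables.
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(predicted_times, records, tau = 5) {
  abort_if(length(predicted_times) != nrow(records),
           "`predicted_times` length must match records")
  ot <- observed_times(records, tau)
  conc <- 0
  n_pairs <- 0
  for (i in which(ot$event == 1L)) {
    later <- ot$time > ot$time[i]
    m <- sum(later)
    if (m == 0) next
    n_pairs <- n_pairs + m
    conc <- conc + sum(predicted_times[i] < predicted_times[later]) +
      0.5 * sum(predicted_times[i] == predicted_times[later])
  }
  abort_if(n_pairs == 0, "no comparable pairs: concordance is undefined")
  conc / n_pairs
}

# ---- Kaplan-Meier and IPCW helpers -----------------------------------------

#' Kaplan-Meier curve of progression
#'
#' Product-limit estimator with events timed at `t_prime` and censorings at
#' `t`. Backed by [survival::survfit()].
#'
#' @param records Survival-records data.frame.
#' @return A `km_curve`: data.frame with `time`, `survival`, `n_risk`,
#'   `n_event` plus an evaluator `s(t)` (right-continuous step function with
#'   `S(0) = 1`).
#' @export
kaplan_meier <- function(records) {
  ot <- observed_times(records)
  fit <- survival::survfit(survival::Surv(ot$time, ot$event) ~ 1)
  tab <- data.frame(time = fit$time, survival = fit$surv,
                    n_risk = fit$n.risk, n_event = fit$n.event)
  structure(list(table = tab, s = km_step_fun(tab$time, tab$survival)),
            class = "km_curve")
}

km_step_fun <- function(times, surv) {
  function(t) {
    vapply(t, function(tt) {
      i <- findInterval(tt, times)
      if (i == 0L) 1 else surv[i]
    }, numeric(1))
  }
}

# Censoring-distribution KM G(t) for IPCW (censoring as the "event").
censoring_km <- function(records, tau = NULL) {
  ot <- observed_times(records, tau)
  fit <- survival::survfit(survival::Surv(ot$time, 1L - ot$event) ~ 1)
  km_step_fun(fit$time, fit$surv)
}

# Left limit G(t-): evaluate just below t on the step function.
km_left <- function(G, t) G(t - 1e-10)

#' IPCW Brier score at a fixed time
#'
#' Inverse-probability-of-censoring-weighted squared error of the predicted
#' survival probabilities at `t`. Subjects with an observed event by `t`
#' contribute `(0 - S_i(t))^2 / G(T_i-)`; subjects still under observation
#' past `t` contribute `(1 - S_i(t))^2 / G(t)`; subjects censored before `t`
#' contribute nothing. Terms whose censoring-KM weight hits zero are dropped
#' with a warning.
#'
#' @param surv_fn Function `f(times)` returning the `n x length(times)`
#'   matrix of model survival probabilities (see [survival_curves()]).
#' @param records Survival-records data.frame.
#' @param t Evaluation time (years), at most `tau`.
#' @param tau Horizon used for administrative censoring.
#' @return Brier score in `[0, 1]`.
#' @export
brier_score <- function(surv_fn, records, t, tau = 5) {
  abort_if(t > tau, "`t` must not exceed `tau`")
  ot <- observed_times(records, tau)
  G <- censoring_km(records, tau)
  S_t <- as.numeric(surv_fn(t))
  abort_if(length(S_t) != nrow(records),
           "`surv_fn` must return one survival value per record")
  had_event <- ot$event == 1L & ot$time <= t
  at_risk <- ot$time > t
  w <- numeric(nrow(records))
  w[had_event] <- 1 / km_left(G, ot$time[had_event])
  w[at_risk] <- 1 / G(t)
  bad <- !is.finite(w)
  if (any(bad)) {
    warning("censoring KM reached 0: dropping affected terms", call. = FALSE)
    w[bad] <- 0
  }
  err <- numeric(nrow(records))
  err[had_event] <- (0 - S_t[had_event])^2
  err[at_risk] <- (1 - S_t[at_risk])^2
  sum(w * err) / nrow(records)
}

#' Integrated Brier score
#'
#' Trapezoid integral of [brier_score()] over `[0, tau]` on `n_points`
#' uniform time points, divided by `tau`.
#'
#' @inheritParams brier_score
#' @param n_points Number of integration points (default 100).
#' @export
integrated_brier_score <- function(surv_fn, records, tau = 5,
                                   n_points = 100L) {
  ts <- seq(0, tau, length.out = n_points)
  bs <- vapply(ts, function(t) brier_score(surv_fn, records, t, tau),
               numeric(1))
  sum(diff(ts) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) / tau
}

#' Time-dependent (cumulative/dynamic) AUC
#'
#' Cases are subjects with an observed event by `t_eval`; controls are
#' subjects still under observation beyond `t_eval`. The rank statistic is
#' IPCW-weighted, with risk taken as the negative predicted time and score
#' ties counting 0.5.
#'
#' @inheritParams concordance_index
#' @param t_eval Landmark time in years.
#' @return AUC in `[0, 1]`.
#' @export
time_dependent_auc <- function(predicted_times, records, t_eval, tau = 5) {
  abort_if(length(predicted_times) != nrow(records),
           "`predicted_times` length must match records")
  ot <- observed_times(records, tau)
  G <- censoring_km(records, tau)
  cases <- which(ot$event == 1L & ot$time <= t_eval)
  controls <- which(ot$time > t_eval)
  abort_if(length(cases) == 0 || length(controls) == 0,
           "time-dependent AUC undefined: need both cases and controls")
  w_case <- 1 / km_left(G, ot$time[cases])
  w_ctrl <- rep(1 / G(t_eval), length(controls))
  risk <- -predicted_times
  num <- 0
  for (k in seq_along(cases)) {
    gt <- risk[cases[k]] > risk[controls]
    eq <- risk[cases[k]] == risk[controls]
    num <- num + w_case[k] * sum(w_ctrl * (gt + 0.5 * eq))
  }
  num / (sum(w_case) * sum(w_ctrl))
}

#' One-sided log-rank test
#'
#' Standard log-rank statistic comparing the low-risk and high-risk groups,
#' with the one-sided alternative that the high-risk group progresses
#' faster. Returns the signed normal deviate `z = (O_high - E_high) /
#' sqrt(V)` and `p = P(Z > z)`; identical groups give z = 0, p = 0.5.
#'
#' @param group_low,group_high Survival-records data.frames.
#' @return List with `statistic` (z) and `p`.
#' @export
log_rank_one_sided <- function(group_low, group_high) {
  abort_if(nrow(group_low) == 0 || nrow(group_high) == 0,
           "both groups must be non-empty")
  lo <- observed_times(group_low)
  hi <- observed_times(group_high)
  abort_if(sum(lo$event) + sum(hi$event) == 0,
           "log-rank undefined: no events in either group")
  time <- c(lo$time, hi$time)
  event <- c(lo$event, hi$event)
  grp <- factor(rep(c("low", "high"), c(length(lo$time), length(hi$time))),
                levels = c("low", "high"))
  fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  v <- if (is.matrix(fit$var)) fit$var[2L, 2L] else fit$var
  z <- if (v <= 0) 0 else (fit$obs[2L] - fit$exp[2L]) / sqrt(v)
  list(statistic = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Participant-clustered percentile bootstrap CI
#'
#' Resamples participants with replacement (both eyes of a participant move
#' together), recomputes the statistic on each resample, and reports the
#' percentile 2.5/97.5 bounds. Resamples on which the statistic errors are
#' redrawn, up to `10 * n_boot` redraws in total.
#'
#' @param statistic Function mapping a records data.frame to a numeric
#'   scalar.
#' @param records Survival-records data.frame with a `participant_id`
#'   column.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @return List with `estimate`, `lower`, `upper`, and `n_redrawn`.
#' @export
bootstrap_ci <- function(statistic, records, n_boot = 1000L, seed = 1L) {
  abort_if(n_boot < 100L, "`n_boot` must be >= 100")
  est <- statistic(records)
  ids <- unique(records$participant_id)
  by_id <- split(seq_len(nrow(records)), records$participant_id)
  set.seed(seed)
  stats_out <- numeric(n_boot)
  redrawn <- 0L
  max_redraw <- 10L * n_boot
  b <- 1L
  while (b <= n_boot) {
    draw <- sample(ids, length(ids), replace = TRUE)
    res <- records[unlist(by_id[draw], use.names = FALSE), , drop = FALSE]
    val <- tryCatch(statistic(res), error = function(e) NULL)
    if (is.null(val) || !is.finite(val)) {
      redrawn <- redrawn + 1L
      abort_if(redrawn > max_redraw,
               "statistic undefined on too many bootstrap resamples")
      next
    }
    stats_out[b] <- val
    b <- b + 1L
  }
  q <- stats::quantile(stats_out, c(0.025, 0.975), names = FALSE, type = 7)
  list(estimate = est, lower = q[1L], upper = q[2L], n_redrawn = redrawn)
}

#' Predicted-vs-actual agreement statistics
#'
#' Coefficient of determination `R^2 = 1 - SSE/SST`, mean absolute error,
#' and Bland-Altman bias with 95% limits of agreement, computed on the event
#' subset (where an actual progression time is observed).
#'
#' @param predicted_times,actual_times Numeric vectors of equal length.
#' @return List with `r_squared`, `mae`, `bias`, `loa_lower`, `loa_upper`.
#' @export
agreement_stats <- function(predicted_times, actual_times) {
  abort_if(length(predicted_times) != length(actual_times) ||
             length(actual_times) == 0,
           "need non-empty vectors of equal length")
  sst <- sum((actual_times - mean(actual_times))^2)
  abort_if(sst == 0, "zero variance in actual times: R^2 is undefined")
  diffs <- predicted_times - actual_times
  sd_d <- stats::sd(diffs)
  if (is.na(sd_d)) sd_d <- 0
  list(r_squared = 1 - sum(diffs^2) / sst,
       mae = mean(abs(diffs)),
       bias = mean(diffs),
       loa_lower = mean(diffs) - 1.96 * sd_d,
       loa_upper = mean(diffs) + 1.96 * sd_d)
}

#' Full evaluation report
#'
#' Assembles the evaluation the study reports for one model on one dataset:
#' concordance with a participant-clustered bootstrap CI, integrated Brier
#' score, time-dependent AUC at the yearly marks, Kaplan-Meier curves for
#' the median-threshold risk groups, and the one-sided log-rank p-value
#' between them.
#'
#' @param predicted_times Predicted times (risk scores) per record.
#' @param records Survival-records data.frame.
#' @param surv_fn Optional survival-curve closure for Brier/IBS (see
#'   [survival_curves()]); when `NULL` the IBS entries are `NA`.
#' @param horizon An [evaluation_horizon()].
#' @param n_boot Bootstrap resamples for the concordance CI.
#' @param seed Bootstrap seed.
#' @return A `metric_report` list.
#' @export
metric_report <- function(predicted_times, records, surv_fn = NULL,
                          horizon = evaluation_horizon(), n_boot = 200L,
                          seed = 1L) {
  tau <- horizon$tau
  pred_by_key <- stats::setNames(
    predicted_times, paste(records$participant_id, records$eye))
  ci <- bootstrap_ci(function(r) {
    concordance_index(pred_by_key[paste(r$participant_id, r$eye)], r, tau)
  }, records, n_boot = max(n_boot, 100L), seed = seed)
  aucs <- sapply(horizon$yearly_marks, function(m) {
    tryCatch(time_dependent_auc(predicted_times, records, m, tau),
             error = function(e) NA_real_)
  })
  names(aucs) <- paste0("year", horizon$yearly_marks)
  thr <- median_threshold(predicted_times)
  grp <- assign_risk(predicted_times, thr)
  low <- records[grp == "low", , drop = FALSE]
  high <- records[grp == "high", , drop = FALSE]
  lr <- tryCatch(log_rank_one_sided(low, high),
                 error = function(e) list(statistic = NA_real_, p = NA_real_))
  structure(list(
    c_index = ci$estimate, c_index_lower = ci$lower, c_index_upper = ci$upper,
    ibs = if (is.null(surv_fn)) NA_real_ else {
      integrated_brier_score(surv_fn, records, tau)
    },
    td_auc = aucs,
    threshold = thr$value,
    km_low = if (nrow(low)) kaplan_meier(low),
    km_high = if (nrow(high)) kaplan_meier(high),
    log_rank_z = lr$statistic, log_rank_p = lr$p
  ), class = "metric_report")
}

#' Serialize a metric report to JSON
#' @param report A `metric_report`.
#' @param path Output path.
#' @export
report_to_json <- function(report, path) {
  obj <- list(c_index = report$c_index,
              c_index_ci = c(report$c_index_lower, report$c_index_upper),
              ibs = report$ibs, td_auc = as.list(report$td_auc),
              risk_threshold_years = report$threshold,
              log_rank_z = report$log_rank_z, log_rank_p = report$log_rank_p)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
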