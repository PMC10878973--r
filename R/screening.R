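# Clinical policy layer: median-threshold risk triage, personalized
# screening-year recommendation, delayed-detection and frequency-reduction
# accounting, and eye-year incidence / adjusted-relative-reduction machinery.

#' Median risk threshold from developmental-set scores
#'
#' @param dev_scores Predicted times from the developmental dataset.
#' @return A `risk_threshold` with the sample median; orientation is
#'   "smaller predicted time = higher risk".
#' @export
median_threshold <- function(dev_scores) {
  abort_if(length(dev_scores) == 0, "`dev_scores` must be non-empty")
  structure(list(value = stats::median(dev_scores)), class = "risk_threshold")
}

#' Triage a predicted time into a risk group
#'
#' High risk when the predicted time falls strictly below the threshold
#' (earlier predicted progression); ties go to low risk.
#'
#' @param score Predicted time(s) in years.
#' @param threshold A [median_threshold()] result (or a number).
#' @return Factor with levels `low`, `high`.
#' @export
assign_risk <- function(score, threshold) {
  thr <- if (inherits(threshold, "risk_threshold")) threshold$value
         else threshold
  abort_if(any(!is.finite(score)), "`score` must be finite")
  factor(ifelse(score < thr, "high", "low"), levels = c("low", "high"))
}

#' Recommended screening year from a predicted progression time
#'
#' The next annual time point strictly after the predicted time, clamped to
#' the 5-year horizon: `min(horizon, floor(pred) + 1)`. With
#' `rule = "ceiling"` the recommendation is `ceiling(pred)` instead (clamped
#' to at least 1); the two coincide except at integer predictions.
#'
#' @param predicted_time Positive predicted time(s) in years.
#' @param horizon Last permissible screening year (default 5).
#' @param rule `"after"` (default) or `"ceiling"`.
#' @return Integer year(s) in `1..horizon`.
#' @export
recommend_screening_year <- function(predicted_time, horizon = 5L,
                                     rule = c("after", "ceiling")) {
  rule <- match.arg(rule)
  abort_if(any(!is.finite(predicted_time)) || any(predicted_time <= 0),
           "`predicted_time` must be strictly positive")
  year <- if (rule == "after") floor(predicted_time) + 1 else {
    pmax(ceiling(predicted_time), 1)
  }
  as.integer(pmin(horizon, year))
}

#' Evaluate a personalized screening regime
#'
#' Cohort-level accounting of a set of recommended screening years against
#' annual screening: mean screening interval in months, the resulting
#' reduction in screening frequency, and the fraction of eyes whose
#' progression would be detected later than under annual screening.
#'
#' @param recommended_years Integer recommended screening year per eye.
#' @param detection_any Integer exam year at which any-DR progression was
#'   observed under annual screening, `NA` for eyes that did not progress.
#' @param detection_vtdr As `detection_any`, for progression to VTDR.
#' @return A `screening_plan` list with `mean_interval_months`,
#'   `reduction_pct`, `delayed_any_pct`, `delayed_vtdr_pct`, `n_eyes`.
#' @export
evaluate_regime <- function(recommended_years, detection_any = NULL,
                            detection_vtdr = NULL) {
  n <- length(recommended_years)
  abort_if(n == 0, "empty cohort")
  mean_interval <- 12 * mean(recommended_years)
  delayed_pct <- function(detect) {
    if (is.null(detect)) return(NA_real_)
    abort_if(length(detect) != n,
             "detection years must match `recommended_years` length")
    delayed <- !is.na(detect) & recommended_years > detect
    100 * sum(delayed) / n
  }
  structure(list(mean_interval_months = mean_interval,
                 reduction_pct = 100 * (1 - 12 / mean_interval),
                 delayed_any_pct = delayed_pct(detection_any),
                 delayed_vtdr_pct = delayed_pct(detection_vtdr),
                 n_eyes = n),
            class = "screening_plan")
}

#' Frequency reduction from a mean screening interval
#'
#' `100 * (1 - 12 / mean_interval_months)` versus fixed annual screening.
#'
#' @param mean_interval_months Mean recommended interval in months.
#' @return Percentage reduction in screening frequency.
#' @export
frequency_reduction <- function(mean_interval_months) {
  abort_if(any(mean_interval_months <= 0), "interval must be positive")
  100 * (1 - 12 / mean_interval_months)
}

#' Progression incidence per 1,000 eye-years
#'
#' @param n_events Number of progressing eyes.
#' @param n_eyes Number of eyes in the group.
#' @param followup_years Follow-up per eye in years (default 5, the study
#'   horizon).
#' @return Events per 1,000 eye-years, rounded to 2 decimals.
#' @export
incidence_rate <- function(n_events, n_eyes, followup_years = 5) {
  abort_if(n_events < 0 || n_eyes <= 0 || followup_years <= 0,
           "counts must be non-negative and denominators positive")
  round(1000 * n_events / (n_eyes * followup_years), 2)
}

#' Adjusted relative reduction in progression rate between two groups
#'
#' Relative difference `100 * (rate_a - rate_b) / rate_b` of the two groups'
#' progression rates. With covariates the rates come from a log-linear
#' (Poisson) event-rate regression with a log eye-years offset, so the
#' contrast is covariate-adjusted; with an empty covariate list this reduces
#' exactly to the crude relative difference of incidence rates. The point
#' estimate and 95% CI are the median and 2.5/97.5 percentiles of the
#' bootstrap distribution over participants.
#'
#' @param group_a,group_b Eye-level data.frames with columns `event`
#'   (0/1), `followup_years`, `participant_id`, plus any adjustment
#'   covariates.
#' @param covariates Character vector of covariate column names (may be
#'   empty for the crude contrast).
#' @param n_boot Bootstrap resamples (default 200).
#' @param seed Integer seed.
#' @return List with `arr` (median bootstrap ARR, %), `lower`, `upper`,
#'   `point` (the full-sample ARR), and `adjusted` flag.
#' @export
adjusted_relative_reduction <- function(group_a, group_b,
                                        covariates = character(0),
                                        n_boot = 200L, seed = 1L) {
  abort_if(nrow(group_a) == 0 || nrow(group_b) == 0,
           "both groups must be non-empty")
  one_arr <- function(a, b) {
    if (length(covariates) == 0) {
      rate_a <- sum(a$event) / sum(a$followup_years)
      rate_b <- sum(b$event) / sum(b$followup_years)
      return(100 * (rate_a - rate_b) / rate_b)
    }
    dat <- rbind(cbind(a[c("event", "followup_years", covariates)],
                       grp = 1),
                 cbind(b[c("event", "followup_years", covariates)],
                       grp = 0))
    fml <- stats::as.formula(paste(
      "event ~ grp +", paste(covariates, collapse = " + ")))
    fit <- tryCatch(
      stats::glm(fml, family = stats::poisson(),
                 offset = log(dat$followup_years), data = dat),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !fit$converged) {
      warning("rate regression degenerate: falling back to crude contrast",
              call. = FALSE)
      rate_a <- sum(a$event) / sum(a$followup_years)
      rate_b <- sum(b$event) / sum(b$followup_years)
      return(100 * (rate_a - rate_b) / rate_b)
    }
    100 * (exp(stats::coef(fit)[["grp"]]) - 1)
  }
  point <- one_arr(group_a, group_b)
  resample <- function(g, ids) {
    by_id <- split(seq_len(nrow(g)), g$participant_id)
    g[unlist(by_id[ids[ids %in% names(by_id)]], use.names = FALSE), ,
      drop = FALSE]
  }
  set.seed(seed)
  boots <- numeric(n_boot)
  ids_a <- unique(group_a$participant_id)
  ids_b <- unique(group_b$participant_id)
  for (i in seq_len(n_boot)) {
    ra <- resample(group_a, sample(ids_a, length(ids_a), replace = TRUE))
    rb <- resample(group_b, sample(ids_b, length(ids_b), replace = TRUE))
    boots[i] <- tryCatch(one_arr(ra, rb), error = function(e) NA_real_)
  }
  boots <- boots[is.finite(boots)]
  abort_if(length(boots) < n_boot / 2,
           "too many degenerate bootstrap resamples")
  q <- stats::quantile(boots, c(0.5, 0.025, 0.975), names = FALSE)
  list(arr = q[1L], lower = q[2L], upper = q[3L], point = point,
       adjusted = length(covariates) > 0)
}

#' Difference-in-differences of triage-model progression rates
#'
#' Computes `[(ai_high + ai_low) - (meta_high + meta_low)]` within the
#' managed (IM) arm minus the same bracket in the non-managed arm, on
#' absolute rates per 1,000 eye-years.
#'
#' @param im_ai_low,im_ai_high,im_meta_low,im_meta_high Rates in the IM arm.
#' @param nonim_ai_low,nonim_ai_high,nonim_meta_low,nonim_meta_high Rates in
#'   the non-IM arm.
#' @return List with `im_bracket`, `nonim_bracket`, `did`.
#' @export
difference_in_differences <- function(im_ai_low, im_ai_high,
                                      im_meta_low, im_meta_high,
                                      nonim_ai_low, nonim_ai_high,
                                      nonim_meta_low, nonim_meta_high) {
  rates <- c(im_ai_low, im_ai_high, im_meta_low, im_meta_high,
             nonim_ai_low, nonim_ai_high, nonim_meta_low, nonim_meta_high)
  abort_if(any(!is.finite(rates)), "all eight rates must be provided")
  im <- (im_ai_high + im_ai_low) - (im_meta_high + im_meta_low)
  nonim <- (nonim_ai_high + nonim_ai_low) - (nonim_meta_high + nonim_meta_low)
  list(im_bracket = im, nonim_bracket = nonim, did = im - nonim)
}

#' Build a per-eye screening plan table
#'
#' @param records Survival-records data.frame for the `"any"` endpoint.
#' @param predicted_times Predicted progression times per record.
#' @param records_vtdr Optional records for the VTDR endpoint (matched by
#'   participant and eye) supplying VTDR detection years.
#' @param threshold Optional [median_threshold()]; defaults to the median of
#'   `predicted_times`.
#' @param horizon Screening horizon in years.
#' @param rule Year rule, see [recommend_screening_year()].
#' @return Data.frame with columns `participant_id`, `eye`,
#'   `predicted_time`, `risk_group`, `recommended_year`, `detection_year`,
#'   `delayed_any`, `delayed_vtdr`.
#' @export
screening_plan <- function(records, predicted_times, records_vtdr = NULL,
                           threshold = NULL, horizon = 5L, rule = "after") {
  abort_if(nrow(records) != length(predicted_times),
           "`predicted_times` length must match records")
  if (is.null(threshold)) threshold <- median_threshold(predicted_times)
  rec_year <- recommend_screening_year(predicted_times, horizon, rule)
  detect_any <- ifelse(records$event == 1L, ceiling(records$t_prime),
                       NA_real_)
  detect_vtdr <- rep(NA_real_, nrow(records))
  if (!is.null(records_vtdr)) {
    key <- paste(records$participant_id, records$eye)
    key_v <- paste(records_vtdr$participant_id, records_vtdr$eye)
    m <- match(key, key_v)
    hit <- !is.na(m) & records_vtdr$event[m] == 1L
    detect_vtdr[hit] <- ceiling(records_vtdr$t_prime[m[hit]])
  }
  data.frame(participant_id = records$participant_id, eye = records$eye,
             predicted_time = predicted_times,
             risk_group = assign_risk(predicted_times, threshold),
             recommended_year = rec_year,
             detection_year = detect_any,
             delayed_any = !is.na(detect_any) & rec_year > detect_any,
             delayed_vtdr = !is.na(detect_vtdr) & rec_year > detect_vtdr,
             stringsAsFactors = FALSE)
}

#' Summarize a screening plan into policy metrics
#'
#' @param plan A data.frame from [screening_plan()].
#' @return A `screening_plan` metrics list (see [evaluate_regime()]).
#' @export
plan_metrics <- function(plan) {
  n <- nrow(plan)
  abort_if(n == 0, "empty plan")
  mean_interval <- 12 * mean(plan$recommended_year)
  structure(list(mean_interval_months = mean_interval,
                 reduction_pct = frequency_reduction(mean_interval),
                 delayed_any_pct = 100 * sum(plan$delayed_any) / n,
                 delayed_vtdr_pct = 100 * sum(plan$delayed_vtdr) / n,
                 n_eyes = n),
            class = "screening_plan")
}
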