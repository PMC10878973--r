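# Shared fixtures, built in code at test time.

# A small cohort with a strong covariate signal; cached per session because
# several test files reuse it.
small_sim <- local({
  cache <- NULL
  function(n = 400, seed = 7) {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_scenario(n_participants = n, seed = seed))
    }
    cache
  }
})

# Records + encoder derived from the small cohort.
small_records <- local({
  cache <- NULL
  function(endpoint = "any") {
    if (is.null(cache)) {
      sim <- small_sim()
      base <- sim$visits[!duplicated(paste(sim$visits$participant_id,
                                           sim$visits$eye)), ]
      enc <- fit_feature_encoder(base)
      cache <<- list(records = derive_records(sim$visits, endpoint, enc),
                     encoder = enc, sim = sim)
    }
    cache
  }
})

# Match a truth-table column onto a records data.frame by (participant, eye).
truth_for_records <- function(records, truth, column) {
  m <- match(paste(records$participant_id, records$eye),
             paste(truth$participant_id, truth$eye))
  truth[[column]][m]
}

# Hand-rolled visit series for unit tests.
make_series <- function(grades, dmes = rep(FALSE, length(grades)),
                        times = seq_along(grades) - 1,
                        id = "P1", eye = "OD") {
  covs <- as.list(stats::setNames(rep(1, 12), covariate_fields()))
  covs$baseline_dr_grade <- grades[1]
  visit_series(id, eye, data.frame(time = times, dr_grade = grades,
                                   dme = dmes), covs)
}

# Random records table (no features) for metric property tests.
random_records <- function(n, p_event = 0.5, max_time = 6) {
  t_prime <- round(stats::runif(n, 0.5, max_time), 2)
  event <- stats::rbinom(n, 1, p_event)
  t <- ifelse(event == 1, pmax(t_prime - stats::runif(n, 0.2, 1), 0), t_prime)
  data.frame(participant_id = sprintf("P%04d", seq_len(n)),
             eye = "OD", t = t, t_prime = t_prime, event = event)
}

# O(n^2) reference concordance: explicit pair enumeration, independent of
# the package's implementation (per-event vector sweep).
brute_force_cindex <- function(pred, records, tau = 5) {
  time <- ifelse(records$event == 1, records$t_prime, records$t)
  event <- records$event
  event[time > tau] <- 0L
  time <- pmin(time, tau)
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1L) next
    for (j in seq_len(n)) {
      if (time[j] <= time[i]) next
      den <- den + 1
      if (pred[i] < pred[j]) num <- num + 1
      else if (pred[i] == pred[j]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}
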