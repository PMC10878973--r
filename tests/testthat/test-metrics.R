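# Evaluation metrics against brute-force, hand-computed, and library oracles.

test_that("concordance follows the earlier-event/smaller-prediction
           convention", {
  # perfect ordering, no censoring
  recs <- data.frame(participant_id = as.character(1:4), eye = "OD",
                     t = c(0.5, 1, 1.5, 2), t_prime = 1:4,
                     event = 1L)
  expect_equal(concordance_index(1:4, recs), 1)
  # printed toy: 3 comparable pairs, one concordant
  toy <- data.frame(participant_id = as.character(1:3), eye = "OD",
                    t = c(0.5, 1.5, 3), t_prime = c(1, 2, 3),
                    event = c(1L, 1L, 0L))
  expect_equal(concordance_index(c(3, 1, 2), toy), 1 / 3)
  # all score ties
  expect_equal(concordance_index(c(2, 2, 2), toy), 0.5)
  # no comparable pairs
  none <- data.frame(t = c(5, 5), t_prime = c(5, 5), event = 0L)
  expect_error(concordance_index(c(1, 2), none), "undefined")
})

test_that("concordance equals an explicit O(n^2) pair enumeration", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(10:120, 1)
    recs <- random_records(n)
    pred <- if (i %% 3 == 0) sample(1:5, n, TRUE) else stats::runif(n, 0, 8)
    bf <- brute_force_cindex(pred, recs, tau = 5)
    if (is.na(bf)) {
      expect_error(concordance_index(pred, recs, tau = 5))
    } else {
      expect_equal(concordance_index(pred, recs, tau = 5), bf)
    }
  }
})

test_that("Kaplan-Meier matches hand product-limit arithmetic", {
  toy <- data.frame(t = c(0.5, 2, 2.5), t_prime = c(1, 2, 3),
                    event = c(1L, 0L, 1L))
  km <- kaplan_meier(toy)
  expect_equal(km$s(0), 1)
  expect_equal(km$s(1), 2 / 3)
  expect_equal(km$s(2.9), 2 / 3)
  expect_equal(km$s(3), 0)
  # no events: S identically 1
  cens <- data.frame(t = 1:4, t_prime = 1:4, event = 0L)
  expect_true(all(kaplan_meier(cens)$s(c(0.5, 2, 4, 9)) == 1))
  # all events, distinct times: empirical survival
  evs <- data.frame(t = c(1, 2, 3) - 0.5, t_prime = c(1, 2, 3), event = 1L)
  km2 <- kaplan_meier(evs)
  for (tt in c(0.5, 1, 1.7, 2, 2.5, 3.5)) {
    expect_equal(km2$s(tt), mean(evs$t_prime > tt))
  }
})

test_that("one-sided log-rank matches hand O-E arithmetic and its
           symmetries", {
  ga <- data.frame(t = c(0.5, 1.5), t_prime = c(1, 2), event = 1L)
  gb <- data.frame(t = c(2.5, 3.5), t_prime = c(3, 4), event = 1L)
  # hand table: O_B = 2, E_B = 1/2 + 2/3 + 1 + 1, V = 1/4 + 2/9
  z_hand <- (2 - (0.5 + 2 / 3 + 1 + 1)) / sqrt(0.25 + 2 / 9)
  res <- log_rank_one_sided(ga, gb)
  expect_equal(res$statistic, z_hand, tolerance = 1e-12)
  expect_equal(res$p, stats::pnorm(z_hand, lower.tail = FALSE))
  # swapping the groups flips the one-sided p
  swapped <- log_rank_one_sided(gb, ga)
  expect_equal(swapped$p, 1 - res$p, tolerance = 1e-12)
  # identical groups: z = 0, p = 0.5
  same <- log_rank_one_sided(ga, ga)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 0.5)
  expect_error(log_rank_one_sided(
    data.frame(t = 1, t_prime = 1, event = 0L),
    data.frame(t = 2, t_prime = 2, event = 0L)), "no events")
})

test_that("Brier score is zero for the sharp oracle and 0.25 for the
           coin-flip model on uncensored data", {
  n <- 40
  set.seed(5)
  tp <- stats::runif(n, 0.5, 4.5)
  recs <- data.frame(participant_id = as.character(1:n), eye = "OD",
                     t = tp - 0.2, t_prime = tp, event = 1L)
  sharp <- function(times) {
    outer(tp, times, function(ti, tt) as.numeric(tt < ti))
  }
  flat <- function(times) matrix(0.5, n, length(times))
  for (tt in c(1, 2.5, 4)) {
    expect_equal(brier_score(sharp, recs, tt), 0)
    expect_equal(brier_score(flat, recs, tt), 0.25)
  }
  expect_equal(integrated_brier_score(sharp, recs), 0)
  expect_equal(integrated_brier_score(flat, recs), 0.25)
  expect_lt(integrated_brier_score(sharp, recs),
            integrated_brier_score(flat, recs) + 1e-12)
})

test_that("censored Brier score equals the hand-computed IPCW sum", {
  # events at 1 and 3, censorings at 2, 4, 5
  recs <- data.frame(participant_id = as.character(1:5), eye = "OD",
                     t = c(0.5, 2, 2.5, 4, 5),
                     t_prime = c(1, 2, 3, 4, 5),
                     event = c(1L, 0L, 1L, 0L, 0L))
  sfn <- function(times) {
    probs <- c(0.9, 0.8, 0.7, 0.6, 0.5)
    outer(probs, exp(-as.numeric(times) / 10))
  }
  t_eval <- 3.5
  S_t <- as.numeric(sfn(t_eval))
  # censoring KM: drops to 3/4 at 2, to 3/8 at 4 (left limits used for events)
  G <- function(tt) ifelse(tt < 2, 1, ifelse(tt < 4, 3 / 4, 3 / 8))
  hand <- (1 / G(1 - 1e-12)) * (0 - S_t[1])^2 +
    (1 / G(3 - 1e-12)) * (0 - S_t[3])^2 +
    (1 / G(t_eval)) * ((1 - S_t[4])^2 + (1 - S_t[5])^2)
  expect_equal(brier_score(sfn, recs, t_eval), hand / 5)
})

test_that("time-dependent AUC reduces to Mann-Whitney without censoring and
           detects perfect separation", {
  recs6 <- data.frame(participant_id = as.character(1:6), eye = "OD",
                      t = c(0.5, 1, 1.5, 4, 4, 4),
                      t_prime = c(1, 1.5, 2, 4, 4, 4),
                      event = c(1L, 1L, 1L, 0L, 0L, 0L))
  pred <- c(2, 5, 1, 4, 6, 3)
  # cases 1:3 (events by t=3), controls 4:6; U statistic by explicit count
  risk <- -pred
  u <- 0
  for (i in 1:3) for (j in 4:6) {
    u <- u + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
  }
  expect_equal(time_dependent_auc(pred, recs6, 3, tau = 4), u / 9)
  # perfect separation
  expect_equal(time_dependent_auc(c(1, 1.2, 1.1, 9, 8, 7), recs6, 3,
                                  tau = 4), 1)
  # scores independent of outcomes: near 0.5 at large n
  set.seed(12)
  n <- 4000
  tp <- stats::runif(n, 0.2, 6)
  big <- data.frame(participant_id = as.character(1:n), eye = "OD",
                    t = tp, t_prime = tp, event = 0L)
  big$event <- stats::rbinom(n, 1, 0.5)
  big$t <- ifelse(big$event == 1, tp - 0.1, tp)
  auc <- time_dependent_auc(stats::runif(n), big, 3)
  expect_lt(abs(auc - 0.5), 3 * sqrt(1 / (12 * min(
    sum(big$event == 1 & big$t_prime <= 3), sum(big$t > 3)))))
  expect_error(time_dependent_auc(pred[4:6], recs6[4:6, ], 3), "cases")
})

test_that("clustered bootstrap is seeded, degenerate on constants, and has
           near-nominal coverage for a simple mean", {
  recs <- random_records(50)
  const <- function(r) 1.23
  ci <- bootstrap_ci(const, recs, n_boot = 100, seed = 3)
  expect_equal(ci$lower, 1.23)
  expect_equal(ci$upper, 1.23)
  m <- function(r) mean(r$t_prime)
  ci1 <- bootstrap_ci(m, recs, n_boot = 150, seed = 9)
  ci2 <- bootstrap_ci(m, recs, n_boot = 150, seed = 9)
  expect_identical(ci1, ci2)
  expect_true(ci1$lower <= ci1$estimate && ci1$estimate <= ci1$upper)

  set.seed(77)
  hits <- 0
  n_sim <- 200
  for (s in 1:n_sim) {
    y <- stats::rnorm(100)
    df <- data.frame(participant_id = as.character(1:100), eye = "OD",
                     t = y, t_prime = y, event = 0L)
    ci <- bootstrap_ci(function(r) mean(r$t), df, n_boot = 150, seed = s)
    if (ci$lower <= 0 && 0 <= ci$upper) hits <- hits + 1
  }
  expect_lt(abs(hits / n_sim - 0.95), 3 * sqrt(0.95 * 0.05 / n_sim))
})

test_that("agreement statistics match their textbook formulas", {
  a <- c(1, 2, 3, 4, 5)
  st <- agreement_stats(a, a)
  expect_equal(st$r_squared, 1)
  expect_equal(st$mae, 0)
  expect_equal(st$bias, 0)
  st2 <- agreement_stats(a + 1, a)
  expect_equal(st2$mae, 1)
  expect_equal(st2$bias, 1)
  expect_equal(st2$loa_upper - st2$loa_lower, 0)
  set.seed(14)
  p <- stats::runif(30, 0, 5); act <- stats::runif(30, 0, 5)
  st3 <- agreement_stats(p, act)
  expect_equal(st3$r_squared, 1 - sum((p - act)^2) /
                 sum((act - mean(act))^2))
  expect_equal(st3$bias, mean(p - act))
  expect_equal(st3$loa_upper, mean(p - act) + 1.96 * stats::sd(p - act))
  expect_error(agreement_stats(c(1, 2), c(3, 3)), "variance")
})

test_that("the assembled metric report is internally consistent", {
  fix <- small_records()
  recs <- fix$records
  truth <- fix$sim$truth
  pred <- truth_for_records(recs, truth, "true_scale")
  rep <- metric_report(pred, recs, n_boot = 100, seed = 2)
  expect_true(rep$c_index > 0.5 && rep$c_index <= 1)
  expect_true(rep$c_index_lower <= rep$c_index &&
                rep$c_index <= rep$c_index_upper)
  expect_true(rep$log_rank_p < 0.05)  # strong signal separates risk groups
  path <- withr::local_tempfile(fileext = ".json")
  report_to_json(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$c_index, rep$c_index)
})
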