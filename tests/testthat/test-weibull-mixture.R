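# Mixture-of-Weibull survival mathematics against arithmetic, closed-form,
# and Monte-Carlo oracles.

test_that("atom sampling is seeded, positive, and matches its log-normal
           prior at scale", {
  pr <- atom_prior(K = 32, seed = 11)
  a1 <- sample_atoms(pr)
  a2 <- sample_atoms(pr)
  expect_identical(a1$alpha, a2$alpha)
  expect_identical(a1$beta, a2$beta)
  expect_true(all(a1$alpha > 0) && all(a1$beta > 0))

  big <- sample_atoms(atom_prior(K = 100000, beta0 = 0, lambda = 1,
                                 seed = 5))
  # CLT bound: sample mean of log beta within 3/sqrt(K) of the prior mean
  expect_lt(abs(mean(log(big$beta))), 3 / sqrt(100000))
  expect_lt(abs(mean(log(big$alpha)) - log(5)), 3 / sqrt(100000))
})

test_that("survival and cdf match scalar arithmetic and are complementary", {
  expect_equal(mixture_survival(atom_set(2, 1), 1, 2), exp(-1))
  a2 <- atom_set(c(1, 2), c(1, 2))
  expect_equal(mixture_survival(a2, c(0.5, 0.5), 1),
               0.5 * exp(-1) + 0.5 * exp(-0.25))
  expect_equal(mixture_cdf(atom_set(1, 1), 1, 2), 1 - exp(-2))
  # S(0) = 1 and F(0) = 0 for arbitrary mixtures
  set.seed(3)
  for (i in 1:20) {
    K <- sample(1:6, 1)
    atoms <- atom_set(stats::rlnorm(K, 1, 0.5), stats::rlnorm(K, 0, 0.4))
    w <- stats::rexp(K); w <- w / sum(w)
    expect_equal(mixture_survival(atoms, w, 0), 1)
    t <- stats::runif(1, 0, 10)
    expect_equal(mixture_cdf(atoms, w, t) + mixture_survival(atoms, w, t), 1)
  }
  expect_error(mixture_survival(atom_set(1, 1), 1, -1), "non-negative")
})

test_that("survival is non-increasing, reaches 0 in the far tail, and the
           weights must form a simplex", {
  atoms <- atom_set(c(2, 7), c(0.8, 2.5))
  ts <- seq(0, 50, length.out = 200)
  s <- mixture_survival(atoms, c(0.3, 0.7), ts)
  expect_true(all(diff(s) <= 1e-12))
  expect_lt(mixture_survival(atoms, c(0.3, 0.7), 10 * max(atoms$alpha)),
            1e-6)
  expect_error(mixture_survival(atoms, c(0.5, 0.6), 1), "sum to 1")
  expect_error(mixture_survival(atoms, c(1.2, -0.2), 1), "non-negative")
})

test_that("density matches arithmetic, integrates to one, and is the
           negative derivative of survival", {
  expect_equal(mixture_density(atom_set(1, 1), 1, 1), exp(-1))
  expect_error(mixture_density(atom_set(1, 1), 1, 0), "positive")
  set.seed(8)
  for (i in 1:10) {
    K <- sample(1:5, 1)
    atoms <- atom_set(stats::rlnorm(K, 1.2, 0.5),
                      pmax(stats::rlnorm(K, 0, 0.4), 0.5))
    w <- stats::rexp(K); w <- w / sum(w)
    total <- stats::integrate(function(u) mixture_density(atoms, w, u),
                              1e-9, 1, subdivisions = 2000L)$value +
      stats::integrate(function(u) mixture_density(atoms, w, u),
                       1, 200, subdivisions = 2000L)$value
    expect_equal(total, 1, tolerance = 1e-3)
    t0 <- stats::runif(1, 0.5, 5)
    h <- 1e-5
    fd <- -(mixture_survival(atoms, w, t0 + h) -
              mixture_survival(atoms, w, t0 - h)) / (2 * h)
    expect_equal(mixture_density(atoms, w, t0), fd, tolerance = 1e-5)
  }
})

test_that("mixture cdf agrees with Monte-Carlo draws from the two-stage
           sampler", {
  set.seed(123)
  atoms <- atom_set(c(1, 2, 6), c(1, 2, 3))
  w <- c(0.2, 0.5, 0.3)
  n <- 1e6
  comp <- sample.int(3, n, replace = TRUE, prob = w)
  draws <- stats::rweibull(n, shape = atoms$beta[comp],
                           scale = atoms$alpha[comp])
  for (t in seq(0.25, 5, length.out = 20)) {
    p <- mixture_cdf(atoms, w, t)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(draws < t) - p), 3 * se + 1e-9)
  }
})

test_that("interval-censored loss reproduces hand-computed values and the
           gamma semantics", {
  a <- atom_set(1, 1)
  censored <- data.frame(t = 3, t_prime = 3, event = 0L)
  expect_equal(mixture_loss(a, matrix(1, 1, 1), censored), 3)
  expect_equal(mixture_loss(a, matrix(1, 1, 1), censored,
                            loss_config(gamma = 7)), 3)
  uncensored <- data.frame(t = 1, t_prime = 2, event = 1L)
  expect_equal(mixture_loss(a, matrix(1, 1, 1), uncensored,
                            loss_config(gamma = 1)),
               1 - log(1 - exp(-2)))
  expect_equal(mixture_loss(a, matrix(1, 1, 1), uncensored,
                            loss_config(gamma = 0)), 1)
  # censored loss ignores t_prime entirely
  shifted <- censored; shifted$t_prime <- 9
  shifted$event <- 0L
  expect_equal(mixture_loss(a, matrix(1, 1, 1), shifted), 3)
  expect_error(mixture_loss(a, matrix(1, 2, 1), censored), "per record")
})

test_that("loss increases in gamma with events present, and prefers weights
           consistent with the data", {
  set.seed(21)
  atoms <- atom_set(c(1.5, 6), c(2, 2))
  recs <- data.frame(t = c(1, 4, 2), t_prime = c(2, 4, 3),
                     event = c(1L, 0L, 1L))
  w <- matrix(rep(c(0.5, 0.5), 3), 3, 2, byrow = TRUE)
  losses <- sapply(c(0, 0.5, 1, 2), function(g) {
    mixture_loss(atoms, w, recs, loss_config(gamma = g))
  })
  expect_true(all(diff(losses) > 0))

  # records drawn from atom 1 should favour weight on atom 1
  t_true <- stats::rweibull(200, 2, 1.5)
  recs2 <- data.frame(t = pmax(t_true - 0.3, 0), t_prime = t_true + 0.3,
                      event = 1L)
  good <- matrix(rep(c(0.9, 0.1), 200), 200, 2, byrow = TRUE)
  bad <- matrix(rep(c(0.1, 0.9), 200), 200, 2, byrow = TRUE)
  expect_lt(mixture_loss(atoms, good, recs2),
            mixture_loss(atoms, bad, recs2))
})

test_that("mode-of-density prediction matches the closed-form Weibull mode
           and a dense-grid oracle", {
  grid <- time_grid()
  step <- grid[2] - grid[1]
  for (beta in c(1.5, 2, 3)) {
    mode_cf <- 2 * ((beta - 1) / beta)^(1 / beta)
    expect_lt(abs(predict_time(atom_set(2, beta), 1, grid) - mode_cf), step)
  }
  # beta = 1: monotone-decreasing density, argmax at the lower grid bound
  expect_equal(predict_time(atom_set(2, 1), 1, grid), grid[1])
  # two-atom mixture against an independent fine-grid argmax
  atoms <- atom_set(c(1, 4), c(3, 3))
  w <- c(0.3, 0.7)
  fine <- seq(0.001, 15, length.out = 1e6)
  dens <- w[1] * stats::dweibull(fine, 3, 1) +
    w[2] * stats::dweibull(fine, 3, 4)
  oracle <- fine[which.max(dens)]
  expect_lt(abs(predict_time(atoms, w, grid) - oracle), step)
  expect_error(predict_time(atoms, w, numeric(0)), "non-empty")
})

test_that("single-atom mixture matches the reference Weibull distribution", {
  # independent cross-check against stats' Weibull implementation
  ts <- c(0.5, 1, 2.5, 7)
  expect_equal(mixture_survival(atom_set(3, 1.7), 1, ts),
               stats::pweibull(ts, 1.7, 3, lower.tail = FALSE))
  expect_equal(mixture_density(atom_set(3, 1.7), 1, ts),
               stats::dweibull(ts, 1.7, 3))
})

test_that("atom sets round-trip through JSON", {
  atoms <- sample_atoms(atom_prior(K = 16, seed = 9))
  path <- withr::local_tempfile(fileext = ".json")
  atoms_to_json(atoms, path)
  back <- atoms_from_json(path)
  expect_equal(back$alpha, atoms$alpha)
  expect_equal(back$beta, atoms$beta)
  expect_equal(back$prior$seed, atoms$prior$seed)
})
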