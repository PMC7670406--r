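# Event-driven simulator: closed-form waiting-time oracles, determinism,
# trajectory bookkeeping, and agreement with the independent thinning
# implementation.

test_that("a model with all rates zero produces no events and no death", {
  p <- wnm_params_zero(toy_hyper(2))
  tr <- simulate_individual(p, health_state(c(0, 0), 0), horizon = 120,
                            seed = 1)
  expect_identical(nrow(tr$events), 0L)
  expect_true(is.na(tr$death_age))
})

test_that("constant-rate first-event times are exponential", {
  lambda <- 0.2
  p <- wnm_params_zero(toy_hyper(1))
  p$gamma[1, 1] <- lambda
  p <- validate_params(p)
  n <- 20000
  ev <- vapply(seq_len(n), function(k) {
    tr <- simulate_individual(p, health_state(0, 0), horizon = 300, seed = 5,
                              stream = k)
    tr$events$age[1]
  }, numeric(1))
  # mean within 4 standard errors of 1/lambda
  expect_lt(abs(mean(ev) - 1 / lambda), 4 * (1 / lambda) / sqrt(n))
  expect_gt(stats::ks.test(ev, stats::pexp, rate = lambda)$p.value, 0.01)
})

test_that("constant-mortality survival matches exp(-mt) pointwise", {
  m <- 0.05
  p <- wnm_params_zero(toy_hyper(1))
  p$alpha[1] <- m
  p <- validate_params(p)
  death <- agenet:::cpp_sim_death_ages(agenet:::cpp_pack(p), 0, 0L, 1000,
                                       20000L, 3, 0)
  for (t in c(5, 10, 20, 40)) {
    s_hat <- mean(death > t)
    s <- exp(-m * t)
    expect_lt(abs(s_hat - s), 3 * sqrt(s * (1 - s) / 20000) + 1e-9)
  }
})

test_that("simulation is deterministic in (seed, stream) and streams differ", {
  p <- rand_params(toy_hyper(3), 11)
  s <- health_state(c(0, 0, 0), 0)
  t1 <- simulate_individual(p, s, seed = 42, stream = 1)
  t2 <- simulate_individual(p, s, seed = 42, stream = 1)
  expect_identical(t1, t2)
  t3 <- simulate_individual(p, s, seed = 42, stream = 2)
  expect_false(identical(t1$events, t3$events) && identical(t1$death_age, t3$death_age))

  ch1 <- simulate_cohort(p, list(s), horizon = 120, seed = 7,
                         replicates_per_baseline = 3)
  ch2 <- simulate_cohort(p, list(s), horizon = 120, seed = 7,
                         replicates_per_baseline = 3)
  expect_identical(ch1, ch2)
  expect_length(unique(vapply(ch1, function(x) {
    paste(x$events$age, collapse = ",")
  }, character(1))), 3)
  expect_length(simulate_cohort(p, list(s), seed = 1,
                                replicates_per_baseline = 0), 0)
  expect_error(simulate_cohort(p, list(), seed = 1), "non-empty")
})

test_that("state_at_age applies events right-continuously and refuses queries after death", {
  tr <- agenet:::new_trajectory(start_age = 60, d0 = c(0, 0),
                                ev_age = 65, ev_node = 2L,
                                death_age = 80, horizon = 120)
  expect_equal(state_at_age(tr, 64.9)$deficits, c(0, 0))
  expect_equal(state_at_age(tr, 65)$deficits, c(0, 1))  # inclusive at the event
  expect_equal(state_at_age(tr, 79)$deficits, c(0, 1))
  expect_error(state_at_age(tr, 80), "death")
  expect_error(state_at_age(tr, 59), "precedes")

  tr0 <- agenet:::new_trajectory(60, c(1, 0), numeric(0), integer(0), Inf, 120)
  expect_equal(state_at_age(tr0, 100)$deficits, c(1, 0))
})

test_that("deficits are irreversible along simulated trajectories", {
  p <- rand_params(toy_hyper(4), 3)
  for (k in 1:20) {
    tr <- simulate_individual(p, health_state(rep(0, 4), 0), seed = 8,
                              stream = k)
    expect_false(is.unsorted(tr$events$age, strictly = TRUE))
    expect_false(any(duplicated(tr$events$node)))
    if (!is.na(tr$death_age) && nrow(tr$events) > 0) {
      expect_gte(tr$death_age, max(tr$events$age))
    }
  }
})

test_that("mean frailty index of a birth cohort is non-decreasing with age", {
  p <- rand_params(toy_hyper(4), 21)
  pool <- agenet:::cpp_sim_pool_codes(agenet:::cpp_pack(p), 3000L, 120,
                                      c(10, 30, 50, 70, 90), 13, 0)
  mean_fi <- apply(pool$codes, 2, function(cb) {
    cb <- cb[cb >= 0]
    if (length(cb) == 0) return(NA_real_)
    mean(vapply(cb, function(code) {
      sum(bitwAnd(code, bitwShiftL(1L, 0:3)) > 0)
    }, numeric(1))) / 4
  })
  ok <- !is.na(mean_fi)
  expect_true(all(diff(mean_fi[ok]) >= -1e-9))
})

test_that("time-dependent hazard inversion matches the analytic inverted-hazard law", {
  # pure linear hazard via the mortality channel: Gamma_D(t) = c t
  p <- wnm_params_zero(toy_hyper(1))
  p$alpha <- c(0, 1)
  p$eta <- c(0, 0.02)
  p <- validate_params(p)  # hazard 0.02 t, cumulative 0.01 t^2
  death <- agenet:::cpp_sim_death_ages(agenet:::cpp_pack(p), 0, 0L, 1000,
                                       20000L, 17, 0)
  expect_gt(stats::ks.test(death, function(q) 1 - exp(-0.01 * q^2))$p.value,
            0.01)
})

test_that("hazard-inversion and thinning simulators agree distributionally", {
  h <- toy_hyper(2)
  p <- wnm_params_zero(h)
  p$W[1, 2] <- 1.2
  p$W[2, 1] <- 0.6
  p$mu[, 1] <- c(0.01, 0.02)
  p$gamma[, 1] <- c(0.02, 0.03)
  p$gamma[, 2] <- c(0.3, 0.2)
  p$beta <- c(0.8, 0.5)
  p$eta <- c(0, 0.01)
  p$alpha <- c(0, 0.5)
  p <- validate_params(p)
  n <- 400
  s0 <- health_state(c(0, 0), 0)
  d_inv <- vapply(seq_len(n), function(k) {
    tr <- simulate_individual(p, s0, seed = 2, stream = k)
    if (is.na(tr$death_age)) 120 else tr$death_age
  }, numeric(1))
  d_thin <- vapply(seq_len(n), function(k) {
    tr <- simulate_individual_thinning(p, s0, seed = 1000 + k)
    if (is.na(tr$death_age)) 120 else tr$death_age
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(d_inv, d_thin)$p.value), 0.01)
  # first damage-event ages agree too
  e_inv <- vapply(seq_len(n), function(k) {
    tr <- simulate_individual(p, s0, seed = 2, stream = k)
    if (nrow(tr$events) > 0) tr$events$age[1] else 120
  }, numeric(1))
  e_thin <- vapply(seq_len(n), function(k) {
    tr <- simulate_individual_thinning(p, s0, seed = 1000 + k)
    if (nrow(tr$events) > 0) tr$events$age[1] else 120
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(e_inv, e_thin)$p.value), 0.01)
})

test_that("trajectory export is long-format with one terminal row each", {
  p <- rand_params(toy_hyper(3), 5)
  trs <- simulate_cohort(p, list(health_state(c(0, 0, 0), 0)), seed = 3,
                         replicates_per_baseline = 5)
  tab <- trajectory_table(trs)
  expect_setequal(names(tab), c("id", "age", "event"))
  expect_equal(sum(tab$event %in% c("DEATH", "CENSORED")), 5)
  f <- tempfile()
  write_trajectories(trs, f)
  re <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(re), nrow(tab))
  unlink(f)
})
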