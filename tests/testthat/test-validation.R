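# Metrics: prevalence curves, FI distribution, AUC/C-index/Brier oracles,
# Kaplan-Meier, conditional damage rates.

make_traj <- function(start_age, d0, ev_age = numeric(0), ev_node = integer(0),
                      death_age = Inf, horizon = 120) {
  agenet:::new_trajectory(start_age, d0, ev_age, ev_node, death_age, horizon)
}

test_that("roc_auc equals the brute-force pair count, with midrank ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1), c(1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.8, 0.9, 0.1), c(1, 0, 0)), 0.5)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "undefined")
  set.seed(7)
  for (k in 1:5) {
    sc <- sample(seq(0, 1, 0.1), 40, replace = TRUE)  # forces ties
    lb <- stats::rbinom(40, 1, 0.4)
    if (length(unique(lb)) < 2) next
    pairs <- expand.grid(i = which(lb == 1), j = which(lb == 0))
    brute <- mean(ifelse(sc[pairs$i] > sc[pairs$j], 1,
                         ifelse(sc[pairs$i] == sc[pairs$j], 0.5, 0)))
    expect_equal(roc_auc(sc, lb), brute)
    # independent reference implementation (fixed direction: higher score
    # predicts label 1)
    expect_equal(roc_auc(sc, lb),
                 as.numeric(pROC::auc(lb, sc, direction = "<",
                                      levels = c(0, 1), quiet = TRUE)))
  }
})

test_that("deficit prevalence tracks survivors and the closed-form law", {
  # zero-rate healthy cohort: 0 everywhere
  trs <- lapply(1:50, function(k) make_traj(0, c(0, 0)))
  pv <- deficit_prevalence(trs, c(10, 50, 90))
  expect_true(all(pv$prevalence == 0))
  # half the cohort damaged at birth, no dynamics: 0.5 everywhere
  trs <- c(lapply(1:25, function(k) make_traj(0, c(1, 0))),
           lapply(1:25, function(k) make_traj(0, c(0, 0))))
  pv <- deficit_prevalence(trs, c(10, 50))
  expect_true(all(pv$prevalence[pv$deficit == 1] == 0.5))
  expect_true(all(pv$prevalence[pv$deficit == 2] == 0))
  # N = 1 constant rate, no mortality
  lambda <- 0.05
  p <- wnm_params_zero(toy_hyper(1))
  p$gamma[1, 1] <- lambda
  p <- validate_params(p)
  n <- 4000
  trs <- simulate_cohort(p, list(health_state(0, 0)), horizon = 120, seed = 3,
                         replicates_per_baseline = n)
  pv <- deficit_prevalence(trs, c(10, 30))
  for (r in seq_len(nrow(pv))) {
    p_true <- 1 - exp(-lambda * pv$age[r])
    expect_lt(abs(pv$prevalence[r] - p_true),
              3 * sqrt(p_true * (1 - p_true) / n))
  }
})

test_that("pairwise prevalence respects independence, coupling and Frechet bounds", {
  # perfectly coupled: both damaged at birth in half the cohort
  trs <- c(lapply(1:30, function(k) make_traj(0, c(1, 1))),
           lapply(1:30, function(k) make_traj(0, c(0, 0))))
  pp <- pairwise_prevalence(trs, c(20, 60), c(1, 2))
  expect_true(all(pp$prevalence == 0.5))
  # disjoint deficits: joint prevalence 0
  trs <- c(lapply(1:30, function(k) make_traj(0, c(1, 0))),
           lapply(1:30, function(k) make_traj(0, c(0, 1))))
  expect_true(all(pairwise_prevalence(trs, 50, c(1, 2))$prevalence == 0))
  # independent-by-construction deficits: product of marginals within MC error
  p <- wnm_params_zero(toy_hyper(2))
  p$gamma[, 1] <- c(0.03, 0.05)
  p <- validate_params(p)
  n <- 4000
  trs <- simulate_cohort(p, list(health_state(c(0, 0), 0)), horizon = 120,
                         seed = 9, replicates_per_baseline = n)
  ages <- c(15, 40)
  pp <- pairwise_prevalence(trs, ages, c(1, 2))
  pv <- deficit_prevalence(trs, ages)
  for (k in seq_along(ages)) {
    p1 <- pv$prevalence[pv$deficit == 1 & pv$age == ages[k]]
    p2 <- pv$prevalence[pv$deficit == 2 & pv$age == ages[k]]
    expect_lt(abs(pp$prevalence[k] - p1 * p2), 4 / sqrt(n))
    expect_gte(pp$prevalence[k] + 1e-12, max(0, p1 + p2 - 1))
    expect_lte(pp$prevalence[k] - 1e-12, min(p1, p2))
  }
})

test_that("frailty-index distribution is a proper point mass for degenerate cohorts", {
  trs <- lapply(1:20, function(k) make_traj(0, rep(0, 10)))
  d <- fi_distribution(trs, 50)
  expect_equal(unname(d[1]), 1)
  expect_equal(sum(d), 1)
  trs <- lapply(1:20, function(k) make_traj(0, c(1, rep(0, 9))))
  d <- fi_distribution(trs, 50)
  expect_equal(unname(d[2]), 1)  # mass at 0.1
  p <- rand_params(toy_hyper(3), 2)
  trs <- simulate_cohort(p, list(health_state(c(0, 0, 0), 0)), seed = 5,
                         replicates_per_baseline = 200)
  d <- fi_distribution(trs, 40)
  if (!anyNA(d)) expect_equal(sum(d), 1)
})

test_that("kaplan_meier reproduces product-limit hand calculations", {
  km <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_equal(eval_km(km, 2.5), 1 / 3)
  expect_equal(eval_km(km, 0.5), 1)
  km <- kaplan_meier(c(5, 8), c(1, 1))
  expect_true(all(km$surv == 1))
  # deaths at 1 and 3, censored at 2: S(2.5) = 2/3, S(3+) = 0
  km <- kaplan_meier(c(1, 2, 3), c(0, 1, 0))
  expect_equal(eval_km(km, 2.5), 2 / 3)
  expect_equal(eval_km(km, 3.1), 0)
})

test_that("mean survival curve averages individual curves exactly", {
  m <- 0.05
  p <- wnm_params_zero(toy_hyper(1))
  p$alpha[1] <- m
  p <- validate_params(p)
  recs <- data.frame(age = c(60, 60), d1 = c(0, 0), surv_age = c(66, 66),
                     censored = c(1, 1))
  grid <- seq(60, 100, by = 5)
  mc <- mean_survival_curve(p, recs, n_sim = 500, seed = 4, age_grid = grid)
  one <- mean_survival_curve(p, recs[1, ], n_sim = 500, seed = 4,
                             age_grid = grid)
  expect_identical(mc$surv, one$surv)  # identical records share streams
  expect_true(all(diff(mc$surv) <= 0))

  # mixture of a zero-hazard and an instant-death record
  h <- toy_hyper(2)
  p2 <- wnm_params_zero(h)
  p2$beta <- c(50, 0)
  p2$alpha <- c(0, 2)
  p2 <- validate_params(p2)  # deficit 1 lethal, otherwise immortal
  recs <- data.frame(age = c(60, 60), d1 = c(0, 1), d2 = c(0, 0),
                     surv_age = c(66, 66), censored = c(1, 1))
  mc <- mean_survival_curve(p2, recs, n_sim = 400, seed = 5,
                            age_grid = c(61, 80, 110))
  expect_true(all(abs(mc$surv - 0.5) < 0.01))
})

test_that("td_c_index matches exhaustive pair enumeration", {
  # 3 individuals whose predicted curves are ordered with their death ages:
  # at every earlier death age the earlier-dying individual predicts lower
  # survival, so every pair is concordant
  pred <- list(fake_survfn(0, seq(0.5, 3, length.out = 10)),
               fake_survfn(0, seq(3, 7, length.out = 10)),
               fake_survfn(0, seq(8, 12, length.out = 10)))
  r <- td_c_index(pred, surv_ages = c(1.5, 4, 8), censored = c(0, 0, 0),
                  n_boot = 50)
  expect_equal(r$estimate[1], 1)
  # identical constant predictions: all ties -> 0.5
  pred <- replicate(3, fake_survfn(0, rep(100, 5)), simplify = FALSE)
  r <- td_c_index(pred, c(1.5, 4, 8), c(0, 0, 0), n_boot = 50)
  expect_equal(r$estimate[1], 0.5)

  # random cohorts <= 50: O(M^2) brute force
  set.seed(11)
  for (k in 1:3) {
    M <- 30
    surv <- round(stats::runif(M, 60, 90), 1)
    cens <- stats::rbinom(M, 1, 0.3)
    pred <- lapply(seq_len(M), function(m) {
      fake_survfn(55, 55 + stats::rexp(40, 1 / stats::runif(1, 5, 40)))
    })
    num <- 0; den <- 0
    for (m1 in seq_len(M)) {
      if (cens[m1] == 1) next
      for (m2 in seq_len(M)) {
        if (m2 == m1 || surv[m2] <= surv[m1]) next
        s1 <- eval_survfn(pred[[m1]], surv[m1])
        s2 <- eval_survfn(pred[[m2]], surv[m1])
        num <- num + (s1 < s2) + 0.5 * (s1 == s2)
        den <- den + 1
      }
    }
    r <- td_c_index(pred, surv, cens, n_boot = 20)
    expect_equal(r$estimate[1], num / den)
  }
})

test_that("brier_r2 matches the direct IPCW formula and its fixed points", {
  # model identical to the reference population curve -> R2 = 0
  surv <- c(2, 4, 6, 8)
  cens <- c(0, 0, 0, 0)
  et <- c(3, 5)
  km <- kaplan_meier(surv, cens)
  ref_pred <- matrix(rep(eval_km(km, et), each = 4), 4)
  r <- brier_r2(ref_pred, surv, cens, et, n_boot = 20)
  expect_equal(r$estimate[1], 0)
  # perfect 0/1 predictions, no censoring -> R2 = 1
  perfect <- cbind(as.numeric(surv > 3), as.numeric(surv > 5))
  r <- brier_r2(perfect, surv, cens, et, n_boot = 20)
  expect_equal(r$estimate[1], 1)

  # 4-individual toy with censoring: direct hand formula
  surv <- c(2, 5, 7, 9)
  cens <- c(0, 1, 0, 1)
  et <- 6
  pred <- matrix(c(0.2, 0.7, 0.6, 0.9), 4)
  kmc <- kaplan_meier(surv, 1 - cens)  # censoring KM
  g <- function(x) eval_km(kmc, x)
  bs_direct <- function(p) {
    terms <- c(p[1]^2 / g(2),      # died before t
               0,                  # censored before t: no contribution
               (1 - p[3])^2 / g(6),  # alive at t
               (1 - p[4])^2 / g(6))
    sum(terms) / 4
  }
  ref <- eval_km(kaplan_meier(surv, cens), et)
  expected <- 1 - bs_direct(pred[, 1]) / bs_direct(rep(ref, 4))
  r <- brier_r2(pred, surv, cens, et, n_boot = 20)
  expect_equal(r$estimate[1], expected)
})

test_that("window mortality AUC flags degenerate labels and matches pair enumeration", {
  p0 <- wnm_params_zero(toy_hyper(2))  # nobody dies
  recs <- data.frame(age = c(70, 75), d1 = c(0, 1), d2 = c(0, 0),
                     surv_age = c(76, 81), censored = c(1, 1))
  expect_error(window_mortality_auc(p0, recs, window = 5, n_sim = 50,
                                    seed = 1), "identical")

  # lethal deficit separates perfectly
  p <- wnm_params_zero(toy_hyper(2))
  p$beta <- c(50, 0)
  p$alpha <- c(0, 2)
  p <- validate_params(p)
  recs <- data.frame(age = rep(70, 6), d1 = c(1, 1, 1, 0, 0, 0),
                     d2 = 0, surv_age = c(70.3, 70.1, 70.6, 75, 75, 75),
                     censored = c(0, 0, 0, 1, 1, 1))
  r <- window_mortality_auc(p, recs, window = 5, n_sim = 100, seed = 2,
                            n_boot = 50)
  expect_equal(r$estimate, 1)

  # AUC equals brute force on the same internally reproduced scores
  gt <- make_ground_truth(3, seed = 15)
  coh <- sample_cross_sectional(gt, small_csha_design(40), seed = 16)
  wend <- coh$age + 5
  known <- !(coh$censored == 1 & coh$surv_age < wend)
  label <- as.integer(coh$censored == 0 & coh$surv_age <= wend)[known]
  codes <- apply(as.matrix(coh[known, 2:4]), 1, agenet:::state_code)
  sf <- agenet:::cpp_record_survfrac(
    agenet:::cpp_pack(gt), coh$age[known],
    matrix(as.integer(as.matrix(coh[known, 2:4])), nrow = sum(known)),
    wend[known], wend[known], 120, 80L, 3,
    agenet:::record_stream(coh$age[known], wend[known], codes, 0, 80))
  score <- 1 - sf[, 1]
  if (length(unique(label)) == 2) {
    r <- window_mortality_auc(gt, coh, window = 5, n_sim = 80, seed = 3,
                              n_boot = 20)
    expect_equal(r$estimate, roc_auc(score, label))
  }
})

test_that("conditional damage rates reduce to the marginal series without coupling", {
  h <- toy_hyper(3)
  p <- wnm_params_zero(h)
  p$gamma[, 1] <- c(0.005, 0.02, 0.01)
  p$gamma[, 2] <- c(0.05, 0.1, 0.05)
  p$mu[, 1] <- c(0.002, 0.01, 0.002)
  p <- validate_params(p)  # zero weights: rate of node 1 ignores other deficits
  cr <- conditional_damage_rate(p, source = 2, target = 1, ages = c(20, 40),
                                n_sim = 3000, seed = 5)
  for (k in 1:2) {
    expect_equal(cr$rate[k], damage_rate(p, 1, c(0, 1, 0), cr$age[k]),
                 tolerance = 1e-12)
  }

  # positive coupling raises the conditional rate above the uncoupled one
  p2 <- p
  p2$W[1, 2] <- 0.8
  p2 <- validate_params(p2)
  cr2 <- conditional_damage_rate(p2, 2, 1, c(20, 40), n_sim = 3000, seed = 5)
  expect_true(all(cr2$n > 0))
  expect_true(all(cr2$rate > cr$rate))

  # independent reconstruction from R-level trajectories
  trs <- simulate_cohort(p2, list(health_state(c(0, 0, 0), 0)), seed = 8,
                         replicates_per_baseline = 3000)
  st <- agenet:::alive_states(trs, 40)
  sel <- st[, 1] == 0 & st[, 2] == 1
  manual <- mean(apply(st[sel, , drop = FALSE], 1, function(d) {
    damage_rate(p2, 1, d, 40)
  }))
  expect_equal(cr2$rate[cr2$age == 40], manual, tolerance = 0.15)
})

test_that("left-out-deficit AUC is well-calibrated on degenerate scores", {
  # a model with strong coupling: deficit 2 predicts deficit 1
  h <- toy_hyper(2)
  p <- wnm_params_zero(h)
  p$W[1, 2] <- 3
  p$gamma[, 1] <- c(0.005, 0.05)
  p$gamma[, 2] <- c(0.5, 0)
  p <- validate_params(p)
  des <- cohort_design(M = 150, age_range = c(40, 80), window = 5,
                       age_dist = "uniform")
  coh <- sample_cross_sectional(p, des, seed = 21)
  if (length(unique(coh$d1)) == 2) {
    r <- leftout_deficit_auc(p, coh, leftout = 1, n_sim = 8000, seed = 22,
                             n_boot = 100)
    expect_gt(r$estimate[1], 0.5)
    expect_true(all(r$estimate >= 0 & r$estimate <= 1))
    expect_true(all(r$lower <= r$estimate & r$estimate <= r$upper))
  }
})
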