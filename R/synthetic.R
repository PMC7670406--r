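# Synthetic ground truths and cross-sectional cohort samplers emulating the
# structure of cross-sectional aging studies (baseline age + binary deficits +
# right-censored survival), so every stage of the pipeline is testable
# without restricted data.

#' Cohort design
#'
#' Structural description of a cross-sectional study: cohort size, baseline
#' age distribution, censoring window and per-deficit missingness.
#'
#' @param M Number of individuals.
#' @param age_range Length-2 vector `(age_min, age_max)`, years.
#' @param window Censoring window in years (> 0): deaths are only observed
#'   within `window` years of baseline.
#' @param age_dist `"uniform"` or `"truncnorm"` over `age_range`.
#' @param age_mean,age_sd Mean and SD (years) for `"truncnorm"`.
#' @param missingness Probability in `[0, 1)` that each deficit is missing,
#'   independently.
#' @param label Design label.
#' @param deficit_names Optional deficit names (metadata).
#' @return An object of class `wnm_design`.
#' @export
cohort_design <- function(M, age_range, window,
                          age_dist = c("uniform", "truncnorm"),
                          age_mean = NULL, age_sd = NULL, missingness = 0,
                          label = "custom", deficit_names = NULL) {
  age_dist <- match.arg(age_dist)
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stop("age_range must be (age_min, age_max) with age_min < age_max")
  }
  if (window <= 0) stop("censoring window must be positive")
  if (missingness < 0 || missingness >= 1) stop("missingness must be in [0, 1)")
  if (age_dist == "truncnorm" && (is.null(age_mean) || is.null(age_sd))) {
    stop("truncnorm age distribution needs age_mean and age_sd")
  }
  structure(list(M = as.integer(M), age_range = as.numeric(age_range),
                 window = window, age_dist = age_dist, age_mean = age_mean,
                 age_sd = age_sd, missingness = missingness, label = label,
                 deficit_names = deficit_names),
            class = "wnm_design")
}

#' @export
print.wnm_design <- function(x, ...) {
  cat(sprintf(
    "Cohort design '%s': M = %d, ages %g-%g (%s), %g-year censoring window, %g%% missingness\n",
    x$label, x$M, x$age_range[1], x$age_range[2], x$age_dist, x$window,
    100 * x$missingness))
  invisible(x)
}

#' Study-structure presets
#'
#' `csha_preset()`: 8547 individuals, baseline ages 65-99 (truncated normal,
#' mean 76, SD 7), 6-year censoring window, the ten ADL/IADL difficulty
#' items as deficit labels. `nhanes_preset()`: 9504 individuals, ages 20-85
#' (truncated normal, mean 51, SD 20), 10-year window, 10% per-deficit
#' missingness. These encode study *structure* only; no study data are
#' reproduced.
#'
#' @return A [cohort_design()].
#' @export
csha_preset <- function() {
  cohort_design(
    M = 8547, age_range = c(65, 99), window = 6, age_dist = "truncnorm",
    age_mean = 76, age_sd = 7, missingness = 0, label = "CSHA-like",
    deficit_names = c(
      "Walking difficulty", "Showering difficulty", "Phone difficulty",
      "Going out difficulty", "Shopping difficulty",
      "Preparing meal difficulty", "House work difficulty",
      "Take medicine difficulty", "Managing money difficulty",
      "Issues prevent normal activity"))
}

#' @rdname csha_preset
#' @export
nhanes_preset <- function() {
  cohort_design(
    M = 9504, age_range = c(20, 85), window = 10, age_dist = "truncnorm",
    age_mean = 51, age_sd = 20, missingness = 0.1, label = "NHANES-like",
    deficit_names = paste("attribute", 1:10))
}

draw_baseline_ages <- function(design, n) {
  if (design$age_dist == "uniform") {
    stats::runif(n, design$age_range[1], design$age_range[2])
  } else {
    out <- numeric(0)
    while (length(out) < n) {
      cand <- stats::rnorm(2 * n, design$age_mean, design$age_sd)
      out <- c(out, cand[cand >= design$age_range[1] &
                           cand <= design$age_range[2]])
    }
    out[seq_len(n)]
  }
}

#' Random ground-truth model parameters
#'
#' Draws a random sparse positive interaction network, monotone age-series
#' coefficients at magnitudes that keep rates plausible across a human
#' lifespan, and then calibrates the mortality-rate scale by a short pilot
#' simulation so a birth cohort's median death age lands in
#' `median_range` (bisection on a global mortality scale factor).
#'
#' @param N Number of deficits.
#' @param hyper Optional [wnm_hyper()]; default uses `N` with first-order
#'   series throughout (a small, well-identified generator).
#' @param density Probability that each off-diagonal weight is non-zero.
#' @param effect_scale Multiplier on weight and mortality-load magnitudes.
#' @param seed Integer seed.
#' @param median_range Target interval (years) for the birth-cohort median
#'   death age.
#' @param pilot_n Pilot simulations per calibration step.
#' @return A validated `wnm_params`.
#' @export
make_ground_truth <- function(N, hyper = NULL, density = 0.5,
                              effect_scale = 1, seed = 1L,
                              median_range = c(60, 100), pilot_n = 400) {
  if (is.null(hyper)) hyper <- wnm_hyper(N, n_f = 1, n_plus = 1, n_D1 = 1,
                                         n_D2 = 1)
  stopifnot(hyper$N == N)
  set.seed(seed)
  W <- matrix(0, N, N)
  off <- which(row(W) != col(W))
  nz <- off[stats::runif(length(off)) < density]
  W[nz] <- stats::runif(length(nz), 0.2, 1) * effect_scale

  mu <- matrix(0, N, hyper$n_f)
  for (n in seq_len(hyper$n_f)) {
    mu[, n] <- stats::runif(N, 0.1, 1) / 100^n  # ~O(1) contribution by age 100
  }
  gamma <- matrix(0, N, hyper$n_plus + 1L)
  gamma[, 1] <- stats::runif(N, 0.001, 0.01)
  for (n in seq_len(hyper$n_plus)) {
    gamma[, n + 1] <- stats::runif(N, 0.01, 0.05) / 2^(n - 1)
  }
  beta <- stats::runif(N, 0.5, 1.5) * effect_scale
  eta <- c(0, stats::runif(hyper$n_D2, 0.3, 1) / 100^seq_len(hyper$n_D2))
  if (hyper$n_D2 == 0L) eta <- 0
  alpha <- c(-0.01, stats::runif(max(hyper$n_D1, 0), 0.02, 0.06) /
               2^(seq_len(max(hyper$n_D1, 0)) - 1))
  if (hyper$n_D1 == 0L) alpha <- 0.02

  build <- function(scale) {
    a <- alpha
    if (hyper$n_D1 >= 1) a[-1] <- a[-1] * scale else a <- a * scale
    wnm_params(hyper, W, mu, gamma, beta, a, eta)
  }
  median_death <- function(p, s) {
    death <- cpp_sim_death_ages(cpp_pack(p), 0, integer(N), 200, pilot_n,
                                as.double(s), 0)
    stats::median(death)
  }
  p <- build(1)
  med <- median_death(p, seed)
  if (med < median_range[1] || med > median_range[2]) {
    lo <- -6; hi <- 6  # log2 mortality scale; median death age decreases in it
    found <- FALSE
    for (k in 1:30) {
      mid <- (lo + hi) / 2
      p_try <- build(2^mid)
      med <- median_death(p_try, seed)
      if (med >= median_range[1] && med <= median_range[2]) {
        p <- p_try
        found <- TRUE
        break
      }
      if (med < mean(median_range)) hi <- mid else lo <- mid
    }
    if (!found) {
      stop("calibration failed: pilot median death age ", round(med, 1))
    }
  }
  attr(p, "pilot_median_death") <- med
  p
}

#' Sample a cross-sectional cohort
#'
#' Emulates study entry among the living (left truncation): per individual a
#' baseline age is drawn from the design's age distribution, a full life is
#' simulated from birth, and the draw is rejected (and redrawn) if the
#' individual died before baseline. The record keeps the deficit state at
#' baseline, the survival age `min(death age, baseline + window)` and the
#' censoring flag; missingness is then applied independently per deficit.
#'
#' @param params A `wnm_params` ground truth.
#' @param design A [cohort_design()].
#' @param seed Integer seed.
#' @param max_attempt_factor Abort (design infeasible) after
#'   `max_attempt_factor * M` simulated lives.
#' @return Cohort data.frame: `age`, `d1..dN`, `surv_age`, `censored`.
#' @export
sample_cross_sectional <- function(params, design, seed,
                                   max_attempt_factor = 200) {
  stopifnot(inherits(params, "wnm_params"), inherits(design, "wnm_design"))
  N <- params$hyper$N
  set.seed(seed)
  need <- design$M
  got_age <- numeric(0); got_code <- integer(0)
  got_surv <- numeric(0); got_cens <- integer(0)
  attempts <- 0L
  stream0 <- 0
  while (need > 0) {
    if (attempts > max_attempt_factor * design$M) {
      stop("design infeasible: ", attempts, " simulated lives yielded only ",
           design$M - need, " of ", design$M, " entrants alive at baseline")
    }
    batch <- max(need, 64L)
    ages <- draw_baseline_ages(design, batch)
    res <- cpp_sample_records(cpp_pack(params), ages, design$window,
                              as.double(seed), stream0)
    stream0 <- stream0 + batch
    attempts <- attempts + batch
    ok <- which(res$alive)
    if (length(ok) > need) ok <- ok[seq_len(need)]
    got_age <- c(got_age, ages[ok])
    got_code <- c(got_code, res$code[ok])
    got_surv <- c(got_surv, res$surv_age[ok])
    got_cens <- c(got_cens, res$censored[ok])
    need <- design$M - length(got_age)
  }
  d <- vapply(seq_len(N), function(j) {
    as.numeric(bitwAnd(got_code, bitwShiftL(1L, j - 1L)) > 0)
  }, numeric(design$M))
  d <- matrix(d, nrow = design$M)
  if (design$missingness > 0) {
    d[matrix(stats::runif(length(d)) < design$missingness, nrow(d))] <- NA
  }
  out <- data.frame(age = got_age)
  colnames(d) <- paste0("d", seq_len(N))
  out <- cbind(out, as.data.frame(d))
  out$surv_age <- got_surv
  out$censored <- got_cens
  out
}
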