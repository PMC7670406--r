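# Validation battery: prevalence forecasts, frailty-index distributions,
# left-out-deficit imputation AUC, survival curves and discrimination metrics.

# deficits of every trajectory alive at `age` (matrix, 0 rows if none)
alive_states <- function(trajectories, age) {
  rows <- lapply(trajectories, function(tr) {
    alive <- age >= tr$start_age && age <= tr$horizon &&
      (is.na(tr$death_age) || age < tr$death_age)
    if (!alive) return(NULL)
    state_at_age(tr, age)$deficits
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(matrix(numeric(0), 0, 0))
  do.call(rbind, rows)
}

metric_result <- function(stratum, estimate, lower, upper, n = NA_integer_) {
  data.frame(stratum = stratum, estimate = estimate, lower = lower,
             upper = upper, n = n)
}

# percentile bootstrap over individuals
boot_ci <- function(stat, n, n_boot, seed, level = 0.95) {
  set.seed(seed)
  vals <- vapply(seq_len(n_boot), function(b) stat(sample.int(n, replace = TRUE)),
                 numeric(1))
  vals <- vals[is.finite(vals)]
  stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
}

#' ROC AUC by the Mann-Whitney rank statistic
#'
#' Midranks handle tied scores (a tie counts 1/2). Errors when all labels are
#' identical (the AUC is undefined).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 truth.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: all labels identical")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Deficit prevalence along simulated trajectories
#'
#' Among trajectories alive at each grid age, the fraction with deficit `i`,
#' with binomial standard errors.
#'
#' @param trajectories List of `wnm_trajectory`.
#' @param ages Increasing age grid.
#' @return data.frame with columns `deficit`, `age`, `prevalence`, `se`,
#'   `n_alive`.
#' @export
deficit_prevalence <- function(trajectories, ages) {
  N <- length(trajectories[[1]]$initial)
  out <- list()
  for (a in ages) {
    st <- alive_states(trajectories, a)
    n <- nrow(st)
    p <- if (n > 0) colMeans(st) else rep(NA_real_, N)
    se <- if (n > 0) sqrt(p * (1 - p) / n) else rep(NA_real_, N)
    out[[length(out) + 1L]] <- data.frame(
      deficit = seq_len(N), age = a, prevalence = p, se = se, n_alive = n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise deficit prevalence
#'
#' Joint fraction `p(d_i = 1, d_j = 1 | alive at age)` among survivors; lies
#' within the Frechet bounds of the two marginals by construction.
#'
#' @inheritParams deficit_prevalence
#' @param pair Length-2 vector of deficit indices.
#' @return data.frame with columns `age`, `prevalence`, `se`, `n_alive`.
#' @export
pairwise_prevalence <- function(trajectories, ages, pair) {
  stopifnot(length(pair) == 2)
  out <- lapply(ages, function(a) {
    st <- alive_states(trajectories, a)
    n <- nrow(st)
    p <- if (n > 0) mean(st[, pair[1]] == 1 & st[, pair[2]] == 1) else NA_real_
    data.frame(age = a, prevalence = p,
               se = if (n > 0) sqrt(p * (1 - p) / n) else NA_real_,
               n_alive = n)
  })
  do.call(rbind, out)
}

#' Frailty-index distribution at an age
#'
#' Distribution of `F = sum(d) / N` over `{0, 1/N, ..., 1}` among
#' trajectories alive at the given age.
#'
#' @inheritParams deficit_prevalence
#' @param age Query age.
#' @return Named numeric vector of probabilities over `0, 1/N, ..., 1`
#'   summing to 1 (all `NA` if no survivor).
#' @export
fi_distribution <- function(trajectories, age) {
  N <- length(trajectories[[1]]$initial)
  st <- alive_states(trajectories, age)
  levels <- (0:N) / N
  if (nrow(st) == 0) {
    return(stats::setNames(rep(NA_real_, N + 1), format(levels)))
  }
  fi <- rowSums(st)
  stats::setNames(tabulate(fi + 1L, nbins = N + 1L) / nrow(st), format(levels))
}

#' Left-out-deficit imputation AUC
#'
#' For each test record, the probability of the left-out deficit is
#' estimated from birth-cohort simulations: among simulated individuals
#' alive in the record's 1-year age bin whose state matches the record's
#' observed coordinates (all but the left-out one), the fraction with the
#' left-out deficit. If no simulated individual matches, the age bin widens
#' symmetrically up to 5 years before the record is dropped (dropped count
#' reported via the `dropped` attribute). The scores are assessed against
#' the true left-out values by ROC AUC, overall and per baseline-age
#' stratum, with percentile bootstrap confidence intervals.
#'
#' @param params A `wnm_params` object.
#' @param records Cohort data.frame; the left-out column must be observed.
#' @param leftout Index of the left-out deficit.
#' @param n_sim Birth-cohort pool size.
#' @param seed Integer seed.
#' @param age_strata Optional vector of stratum breaks (years); default
#'   5-year bins across the observed ages.
#' @param n_boot Bootstrap resamples for the CI.
#' @param horizon Simulation horizon.
#' @return data.frame of metric rows (`stratum`, `estimate`, `lower`,
#'   `upper`, `n`), first row `"all"`.
#' @export
leftout_deficit_auc <- function(params, records, leftout, n_sim, seed,
                                age_strata = NULL, n_boot = 1000,
                                horizon = 120) {
  N <- params$hyper$N
  parts <- cohort_parts(records, N)
  if (anyNA(parts$d[, leftout])) {
    stop("records must be observed at the left-out coordinate")
  }
  edges <- seq(floor(min(parts$age)), ceiling(max(parts$age)) + 1, by = 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  pool <- cpp_sim_pool_codes(cpp_pack(params), as.integer(n_sim), horizon,
                             mids, as.double(seed), 0)
  bin_of <- findInterval(parts$age, edges, rightmost.closed = TRUE)
  nbins <- length(mids)
  lo_bit <- bitwShiftL(1L, leftout - 1L)

  M <- length(parts$age)
  score <- rep(NA_real_, M)
  for (m in seq_len(M)) {
    d <- parts$d[m, ]
    obs <- setdiff(which(!is.na(d)), leftout)
    mask <- if (length(obs) > 0) sum(bitwShiftL(1L, obs - 1L)) else 0L
    target <- sum(bitwShiftL(1L, obs[d[obs] == 1] - 1L))
    for (widen in 0:2) {  # 1-year bin, widened symmetrically up to 5 years
      bins <- max(1, bin_of[m] - widen):min(nbins, bin_of[m] + widen)
      cb <- as.vector(pool$codes[, bins])
      match <- cb >= 0L & bitwAnd(cb, mask) == target
      if (any(match)) {
        score[m] <- mean(bitwAnd(cb[match], lo_bit) > 0)
        break
      }
    }
  }
  keep <- !is.na(score)
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " record(s) dropped: no matching simulated individual")
  }
  truth <- parts$d[keep, leftout]
  sc <- score[keep]
  ages <- parts$age[keep]

  rows <- metric_result(
    "all", roc_auc(sc, truth),
    boot_ci(function(i) tryCatch(roc_auc(sc[i], truth[i]), error = function(e) NA),
            length(sc), n_boot, seed)[1],
    boot_ci(function(i) tryCatch(roc_auc(sc[i], truth[i]), error = function(e) NA),
            length(sc), n_boot, seed)[2],
    n = length(sc))
  if (is.null(age_strata)) {
    age_strata <- seq(floor(min(ages) / 5) * 5, ceiling(max(ages) / 5) * 5, by = 5)
  }
  sb <- findInterval(ages, age_strata, rightmost.closed = TRUE)
  for (b in sort(unique(sb))) {
    idx <- which(sb == b)
    if (length(unique(truth[idx])) < 2) next
    ci <- boot_ci(function(i) {
      tryCatch(roc_auc(sc[idx][i], truth[idx][i]), error = function(e) NA)
    }, length(idx), n_boot, seed + b)
    rows <- rbind(rows, metric_result(
      sprintf("[%g,%g)", age_strata[b], age_strata[b + 1]),
      roc_auc(sc[idx], truth[idx]), ci[1], ci[2], n = length(idx)))
  }
  attr(rows, "dropped") <- dropped
  rows
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with Greenwood ("plain") 95% confidence bands,
#' via the survival package. Supply `entry_ages` for left-truncated
#' (delayed-entry) cohorts on the age scale.
#'
#' @param surv_ages Survival or censoring ages.
#' @param censored 1 = censored, 0 = death observed.
#' @param entry_ages Optional baseline (entry) ages for delayed entry.
#' @return data.frame with columns `time`, `surv`, `lower`, `upper`,
#'   `n_risk`, `n_event`.
#' @export
kaplan_meier <- function(surv_ages, censored, entry_ages = NULL) {
  event <- 1L - as.integer(censored)
  fit <- if (is.null(entry_ages)) {
    survival::survfit(survival::Surv(surv_ages, event) ~ 1,
                      conf.type = "plain")
  } else {
    survival::survfit(survival::Surv(entry_ages, surv_ages, event) ~ 1,
                      conf.type = "plain")
  }
  data.frame(time = fit$time, surv = fit$surv,
             lower = ifelse(is.na(fit$lower), 0, fit$lower),
             upper = ifelse(is.na(fit$upper), 1, fit$upper),
             n_risk = fit$n.risk, n_event = fit$n.event)
}

#' Evaluate a Kaplan-Meier table at arbitrary ages
#'
#' Right-continuous step interpolation of the `surv` column (1 before the
#' first event time).
#'
#' @param km data.frame from [kaplan_meier()].
#' @param ages Query ages.
#' @return Survival probabilities.
#' @export
eval_km <- function(km, ages) {
  idx <- findInterval(ages, km$time)
  c(1, km$surv)[idx + 1L]
}

#' Population mean predicted survival curve
#'
#' Simulates each record's individual survival function from its observed
#' baseline state and averages them on a common age grid (individual curves
#' are 1 below their own baseline age).
#'
#' @param params A `wnm_params` object.
#' @param records Cohort data.frame with fully observed deficits.
#' @param n_sim Forward simulations per record.
#' @param seed Integer seed.
#' @param age_grid Common evaluation grid; default 1-year steps across the
#'   observed range up to the horizon.
#' @param horizon Simulation horizon.
#' @return data.frame with columns `age`, `surv`.
#' @export
mean_survival_curve <- function(params, records, n_sim, seed, age_grid = NULL,
                                horizon = 120) {
  N <- params$hyper$N
  parts <- cohort_parts(records, N)
  if (anyNA(parts$d)) stop("records must be fully observed")
  if (is.null(age_grid)) {
    age_grid <- seq(floor(min(parts$age)), horizon, by = 1)
  }
  M <- length(parts$age)
  acc <- numeric(length(age_grid))
  for (m in seq_len(M)) {
    strm <- record_stream(parts$age[m], parts$age[m],
                          state_code(parts$d[m, ]), 0, n_sim)
    s <- survival_function(params, parts$d[m, ], parts$age[m], n_sim, seed,
                           stream = strm, horizon = horizon)
    acc <- acc + eval_survfn(s, age_grid)
  }
  data.frame(age = age_grid, surv = acc / M)
}

#' Time-dependent concordance index
#'
#' `C^td`: over all comparable pairs (the first member uncensored with the
#' earlier survival age), the fraction in which the earlier-dying individual
#' has the lower predicted survival evaluated at that death age; tied
#' predictions count 1/2. The stratified variant restricts pairs to a common
#' baseline-age bin. Percentile bootstrap CIs over individuals.
#'
#' @param pred List of `wnm_survfn` predicted survival curves, one per
#'   individual.
#' @param surv_ages,censored Observed survival ages and censor flags.
#' @param baseline_ages Baseline ages (needed for stratification).
#' @param age_strata Optional stratum breaks (years); 5-year bins by default
#'   when `baseline_ages` given.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @return data.frame of metric rows, first row `"all"`.
#' @export
td_c_index <- function(pred, surv_ages, censored, baseline_ages = NULL,
                       age_strata = NULL, n_boot = 1000, seed = 1L) {
  M <- length(surv_ages)
  stopifnot(length(pred) == M, length(censored) == M)
  cmp <- matrix(NA_real_, M, M)  # cmp[m1, m2]: concordance of the pair
  for (m1 in seq_len(M)) {
    if (censored[m1] == 1) next
    a1 <- surv_ages[m1]
    comparable <- which(surv_ages > a1)
    if (length(comparable) == 0) next
    s1 <- eval_survfn(pred[[m1]], a1)
    s2 <- vapply(comparable, function(m2) eval_survfn(pred[[m2]], a1),
                 numeric(1))
    cmp[m1, comparable] <- ifelse(s1 < s2, 1, ifelse(s1 == s2, 0.5, 0))
  }
  cstat <- function(idx) {
    sub <- cmp[idx, idx, drop = FALSE]
    mean(sub, na.rm = TRUE)
  }
  if (all(is.na(cmp))) stop("no comparable pairs")
  ci <- boot_ci(function(i) cstat(i), M, n_boot, seed)
  rows <- metric_result("all", cstat(seq_len(M)), ci[1], ci[2],
                        n = sum(!is.na(cmp)))
  if (!is.null(baseline_ages)) {
    if (is.null(age_strata)) {
      age_strata <- seq(floor(min(baseline_ages) / 5) * 5,
                        ceiling(max(baseline_ages) / 5) * 5, by = 5)
    }
    sb <- findInterval(baseline_ages, age_strata, rightmost.closed = TRUE)
    for (b in sort(unique(sb))) {
      idx <- which(sb == b)
      sub <- cmp[idx, idx, drop = FALSE]
      if (all(is.na(sub))) next
      ci <- boot_ci(function(i) cstat(idx[i]), length(idx), n_boot, seed + b)
      rows <- rbind(rows, metric_result(
        sprintf("[%g,%g)", age_strata[b], age_strata[b + 1]),
        mean(sub, na.rm = TRUE), ci[1], ci[2], n = sum(!is.na(sub))))
    }
  }
  rows
}

#' Brier-score R-squared
#'
#' `1 - BS(model) / BS(reference)` at each evaluation time, with inverse
#' probability-of-censoring weights from the Kaplan-Meier estimate of the
#' censoring distribution, and the population Kaplan-Meier curve as the
#' reference prediction. A positive value means the model's survival
#' predictions beat the population curve.
#'
#' @param pred_surv Matrix `M x length(eval_times)` of predicted survival
#'   probabilities.
#' @param surv_ages,censored Observed survival ages and censor flags.
#' @param eval_times Evaluation times (same scale as `surv_ages`).
#' @param n_boot Bootstrap resamples for the CI on the aggregate.
#' @param seed Integer seed.
#' @return data.frame: one row per evaluation time plus an `"all"` row with
#'   bootstrap CI (per-time rows carry `NA` CIs).
#' @export
brier_r2 <- function(pred_surv, surv_ages, censored, eval_times,
                     n_boot = 1000, seed = 1L) {
  pred_surv <- as.matrix(pred_surv)
  M <- length(surv_ages)
  stopifnot(nrow(pred_surv) == M, ncol(pred_surv) == length(eval_times))
  km_pop <- kaplan_meier(surv_ages, censored)
  km_cens <- kaplan_meier(surv_ages, 1 - censored)  # censoring distribution
  ref <- eval_km(km_pop, eval_times)

  bs <- function(pred_col, tt, idx) {
    a <- surv_ages[idx]
    cc <- censored[idx]
    p <- pred_col[idx]
    died <- cc == 0 & a <= tt
    alive <- a > tt
    g_at_a <- pmax(eval_km(km_cens, pmin(a, tt)), 1e-8)
    g_at_t <- pmax(eval_km(km_cens, tt), 1e-8)
    w <- numeric(length(idx))
    w[died] <- 1 / g_at_a[died]
    w[alive] <- 1 / g_at_t
    err <- numeric(length(idx))
    err[died] <- p[died]^2
    err[alive] <- (1 - p[alive])^2
    sum(w * err) / length(idx)
  }
  r2_at <- function(idx) {
    num <- vapply(seq_along(eval_times),
                  function(k) bs(pred_surv[, k], eval_times[k], idx), numeric(1))
    den <- vapply(seq_along(eval_times),
                  function(k) bs(rep(ref[k], M), eval_times[k], idx), numeric(1))
    1 - sum(num) / sum(den)
  }
  per_time <- vapply(seq_along(eval_times), function(k) {
    1 - bs(pred_surv[, k], eval_times[k], seq_len(M)) /
      bs(rep(ref[k], M), eval_times[k], seq_len(M))
  }, numeric(1))
  ci <- boot_ci(r2_at, M, n_boot, seed)
  rbind(
    metric_result("all", r2_at(seq_len(M)), ci[1], ci[2], n = M),
    metric_result(sprintf("t=%g", eval_times), per_time, NA_real_, NA_real_,
                  n = M))
}

#' Windowed dead/alive prediction AUC
#'
#' Score each record by its predicted probability of dying within `window`
#' years of baseline, `1 - S(t0 + window)`, and compute the ROC AUC against
#' the observed vital status at the window end. Records censored before the
#' window end are excluded (status unknown). Errors when all retained labels
#' are identical.
#'
#' @param params A `wnm_params` object.
#' @param records Cohort data.frame with fully observed deficits.
#' @param window Prediction window in years.
#' @param n_sim Forward simulations per record.
#' @param seed Integer seed.
#' @param n_boot Bootstrap resamples.
#' @param horizon Simulation horizon.
#' @return One metric row (`stratum = "all"`).
#' @export
window_mortality_auc <- function(params, records, window, n_sim, seed,
                                 n_boot = 1000, horizon = 120) {
  N <- params$hyper$N
  parts <- cohort_parts(records, N)
  if (anyNA(parts$d)) stop("records must be fully observed")
  wend <- parts$age + window
  known <- !(parts$censored == 1 & parts$surv_age < wend)
  if (!any(known)) stop("no record has known status at the window end")
  label <- as.integer(parts$censored == 0 & parts$surv_age <= wend)[known]
  codes <- apply(parts$d[known, , drop = FALSE], 1, state_code)
  sf <- cpp_record_survfrac(
    cpp_pack(params), parts$age[known],
    matrix(as.integer(parts$d[known, , drop = FALSE]), nrow = sum(known)),
    wend[known], wend[known], horizon, as.integer(n_sim), as.double(seed),
    record_stream(parts$age[known], wend[known], codes, 0, n_sim))
  score <- 1 - sf[, 1]
  auc <- roc_auc(score, label)  # errors if labels degenerate
  ci <- boot_ci(function(i) {
    tryCatch(roc_auc(score[i], label[i]), error = function(e) NA)
  }, length(score), n_boot, seed)
  metric_result("all", auc, ci[1], ci[2], n = length(score))
}

#' Conditional damage-propagation rate
#'
#' Average damage rate of the target node at each age among simulated
#' individuals who already have the source deficit but not the target one,
#' averaged over the simulated distribution of the remaining deficits:
#' `Gamma_{target <- source}(t)`.
#'
#' @param params A `wnm_params` object.
#' @param source,target Node indices (source damaged, target undamaged).
#' @param ages Query ages.
#' @param n_sim Birth-cohort pool size.
#' @param seed Integer seed.
#' @param horizon Simulation horizon.
#' @return data.frame with columns `age`, `rate`, `n` (conditioning count).
#' @export
conditional_damage_rate <- function(params, source, target, ages, n_sim, seed,
                                    horizon = 120) {
  stopifnot(source != target)
  N <- params$hyper$N
  pool <- cpp_sim_pool_codes(cpp_pack(params), as.integer(n_sim), horizon,
                             as.numeric(ages), as.double(seed), 0)
  s_bit <- bitwShiftL(1L, source - 1L)
  t_bit <- bitwShiftL(1L, target - 1L)
  out <- lapply(seq_along(ages), function(q) {
    cb <- pool$codes[, q]
    sel <- cb >= 0L & bitwAnd(cb, s_bit) > 0L & bitwAnd(cb, t_bit) == 0L
    if (!any(sel)) {
      return(data.frame(age = ages[q], rate = NA_real_, n = 0L))
    }
    tab <- table(cb[sel])
    codes <- as.integer(names(tab))
    rates <- vapply(codes, function(code) {
      d <- as.integer(bitwAnd(code, bitwShiftL(1L, seq_len(N) - 1L)) > 0L)
      damage_rate(params, target, d, ages[q])
    }, numeric(1))
    data.frame(age = ages[q],
               rate = sum(rates * as.integer(tab)) / sum(tab),
               n = sum(tab))
  })
  do.call(rbind, out)
}
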