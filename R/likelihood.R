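# Simulation-based likelihood for right-censored cross-sectional cohorts.
#
# The log-likelihood factorizes into a health part and a mortality part:
#   L = sum_{c=0} log p(a | {d}, t)  +  sum_m log p({d_i} | t)
#                                    +  sum_{c=1} log S(a | {d}, t).
# The health term is read from a simulated birth-cohort estimate of the
# age-binned joint state distribution p({d_i} | t); mortality terms come from
# forward simulations conditioned on the observed baseline state (or, for
# records with missing deficits, from pool individuals matching the observed
# sub-vector).

state_code <- function(deficits) {
  sum(as.integer(deficits) * bitwShiftL(1L, seq_along(deficits) - 1L))
}

# codes of all completions of a deficit vector with NAs
completion_codes <- function(deficits) {
  miss <- which(is.na(deficits))
  if (length(miss) > 12) stop("too many missing deficits to marginalize (> 12)")
  base <- deficits
  base[miss] <- 0
  base_code <- state_code(base)
  if (length(miss) == 0) return(base_code)
  bits <- bitwShiftL(1L, miss - 1L)
  combos <- expand.grid(rep(list(0:1), length(miss)))
  apply(as.matrix(combos), 1, function(row) base_code + sum(bits * row))
}

#' Estimate the age-binned joint state distribution
#'
#' Simulates `n_sim` individuals from birth (age 0, no deficits) and, at each
#' age bin's midpoint, tallies the joint deficit state among those alive,
#' applying additive (pseudo-count) smoothing so every one of the `2^N`
#' states has positive probability. Bins in which no simulated individual is
#' alive are signalled with a warning and carry `NA` probabilities (distinct
#' from a zero-probability state).
#'
#' @param params A `wnm_params` object.
#' @param n_sim Number of simulated individuals (>= 1000 recommended).
#' @param age_bins Increasing vector of bin edges (years) covering the ages
#'   of interest.
#' @param seed Integer RNG seed.
#' @param pseudo Additive smoothing pseudo-count per state per bin.
#' @param horizon Simulation horizon in years.
#' @return A `wnm_statedist`: list with `edges`, `mids`, `probs` (bins x
#'   `2^N` matrix, rows summing to 1), `counts`, `alive`, `pseudo`, `N`.
#' @export
estimate_state_distribution <- function(params, n_sim, age_bins, seed,
                                        pseudo = 0.5, horizon = 120) {
  stopifnot(inherits(params, "wnm_params"), n_sim >= 1,
            length(age_bins) >= 2, !is.unsorted(age_bins, strictly = TRUE))
  mids <- (age_bins[-1] + age_bins[-length(age_bins)]) / 2
  pool <- cpp_sim_pool_codes(cpp_pack(params), as.integer(n_sim), horizon,
                             mids, as.double(seed), 0)
  sd <- make_statedist(pool$codes, params$hyper$N, age_bins, pseudo)
  if (length(attr(sd, "empty_bins")) > 0) {
    warning("age bins with no simulated survivor: ",
            paste(attr(sd, "empty_bins"), collapse = ", "))
  }
  sd
}

# Tally a pool code matrix (individuals x bins, -1 = dead) into a smoothed
# state distribution.
make_statedist <- function(codes, N, edges, pseudo) {
  n_states <- bitwShiftL(1L, N)
  nbins <- ncol(codes)
  counts <- matrix(0L, nbins, n_states)
  alive <- integer(nbins)
  for (b in seq_len(nbins)) {
    cb <- codes[, b]
    cb <- cb[cb >= 0L]
    alive[b] <- length(cb)
    if (length(cb) > 0) counts[b, ] <- tabulate(cb + 1L, nbins = n_states)
  }
  probs <- (counts + pseudo) / (alive + pseudo * n_states)
  empty <- which(alive == 0L)
  probs[empty, ] <- NA_real_
  structure(
    list(edges = edges, mids = (edges[-1] + edges[-length(edges)]) / 2,
         probs = probs, counts = counts, alive = alive, pseudo = pseudo,
         N = N),
    class = "wnm_statedist", empty_bins = empty
  )
}

#' @export
print.wnm_statedist <- function(x, ...) {
  cat(sprintf(
    "WNM state distribution: %d age bins over [%g, %g], %d joint states\n",
    length(x$mids), min(x$edges), max(x$edges), ncol(x$probs)))
  invisible(x)
}

#' Look up a state probability
#'
#' Smoothed probability of a (possibly partially observed) deficit vector in
#' the age bin containing `t`; missing entries are marginalized by summing
#' over all completions.
#'
#' @param statedist A `wnm_statedist`.
#' @param deficits 0/1/NA vector of length `N`.
#' @param t Age in years; must fall inside the binned range.
#' @return Probability in (0, 1], or `NA` if the bin had no simulated
#'   survivor.
#' @export
state_probability <- function(statedist, deficits, t) {
  b <- findInterval(t, statedist$edges, rightmost.closed = TRUE)
  if (b < 1 || b > nrow(statedist$probs)) stop("age outside the binned range")
  sum(statedist$probs[b, completion_codes(deficits) + 1L])
}

#' Simulated individual survival function
#'
#' Forward-simulates `n_sim` trajectories from a fully observed baseline
#' state and returns the empirical survival step function: `S(a) = 1` for
#' `a <= t0`, the fraction of simulated replicates alive at `a` afterwards.
#' The value at the horizon is reported even when positive (replicates alive
#' at the horizon count as survivors at all queried ages).
#'
#' @param params A `wnm_params` object.
#' @param deficits Fully observed 0/1 baseline deficits (no `NA`).
#' @param t0 Baseline age in years.
#' @param n_sim Number of forward simulations (>= 100 recommended).
#' @param seed Integer RNG seed.
#' @param stream Base stream id for the replicates.
#' @param horizon Simulation horizon in years.
#' @return A `wnm_survfn`; evaluate with [eval_survfn()].
#' @export
survival_function <- function(params, deficits, t0, n_sim, seed, stream = 0L,
                              horizon = 120) {
  if (any(is.na(deficits))) {
    stop("survival_function() requires fully observed deficits")
  }
  d <- as_deficits(deficits, params$hyper$N)
  death <- cpp_sim_death_ages(cpp_pack(params), t0, as.integer(d), horizon,
                              as.integer(n_sim), as.double(seed),
                              as.double(stream))
  structure(list(t0 = t0, death_ages = sort(death), n_sim = n_sim,
                 horizon = horizon),
            class = "wnm_survfn")
}

#' Evaluate a simulated survival function
#'
#' @param s A `wnm_survfn`.
#' @param a Vector of query ages.
#' @return `S(a)` for each query age (1 below the baseline age).
#' @export
eval_survfn <- function(s, a) {
  stopifnot(inherits(s, "wnm_survfn"))
  n <- length(s$death_ages)
  # death_ages sorted; number strictly greater than a via findInterval
  surv <- (n - findInterval(a, s$death_ages)) / n
  ifelse(a <= s$t0, 1, surv)
}

#' @export
print.wnm_survfn <- function(x, ...) {
  cat(sprintf("WNM survival function: baseline %.1f, %d sims, S(%g) = %.3f\n",
              x$t0, x$n_sim, x$horizon, eval_survfn(x, x$horizon)))
  invisible(x)
}

# ---- full censored log-likelihood -------------------------------------------

# Normalize a cohort data.frame into internal pieces. Columns: age, d1..dN,
# surv_age, censored.
cohort_parts <- function(data, N) {
  dn <- paste0("d", seq_len(N))
  need <- c("age", dn, "surv_age", "censored")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) stop("cohort is missing columns: ",
                             paste(miss, collapse = ", "))
  list(age = as.numeric(data$age),
       d = as.matrix(data[, dn, drop = FALSE]),
       surv_age = as.numeric(data$surv_age),
       censored = as.integer(data$censored))
}

# Content-addressed RNG stream id for a record's forward simulations:
# depends only on the record's fields (not its row position), so the
# likelihood is exactly invariant to record order, duplicated records
# contribute exactly twice, and streams stay common across parameter values.
# Hash collisions across distinct records merely correlate their Monte Carlo
# noise, which is harmless.
record_stream <- function(age, surv_age, code, censored, block) {
  h <- (floor(age * 16) * 2654435 + floor(surv_age * 16) * 40503 +
          code * 97 + censored * 13) %% 2^24
  2^21 + h * block
}

#' Censored cross-sectional log-likelihood
#'
#' Simulation-based estimate of the full log-likelihood of a cohort: for
#' every record a health term `log p({d_i} | t)` read from a shared
#' birth-cohort state distribution; for uncensored records a mortality
#' density term estimated by a symmetric finite difference of the simulated
#' survival function over a `delta`-year window; for censored records the
#' log survival probability at the censoring age. Records with missing
#' deficits are marginalized: the health term sums the state distribution
#' over all completions, and mortality terms condition on pool individuals
#' matching the observed sub-vector in the record's baseline age bin. All
#' terms are floored away from zero so the result is always finite.
#'
#' @param params A `wnm_params` object.
#' @param data Cohort data.frame with columns `age`, `d1..dN`, `surv_age`,
#'   `censored` (deficits 0/1/NA).
#' @param n_pool Size of the shared birth-cohort simulation pool.
#' @param n_per_record Forward simulations per fully observed censored
#'   record.
#' @param n_per_record_unc Forward simulations per fully observed uncensored
#'   record; defaults to `5 * n_per_record` because the density finite
#'   difference counts deaths inside a short window and needs a finer
#'   empirical survival step than a single survival probability does.
#' @param seed Integer RNG seed; fixed seed gives common random numbers
#'   across evaluations at different parameters.
#' @param bin_width Age bin width (years) for the state distribution.
#' @param pseudo Additive smoothing pseudo-count.
#' @param delta Death-age window (years) for the density finite difference.
#' @param horizon Simulation horizon in years.
#' @param floor_density Lower floor for density terms (per year).
#' @return Scalar log-likelihood (finite).
#' @export
log_likelihood <- function(params, data, n_pool = 10000, n_per_record = 500,
                           n_per_record_unc = 5 * n_per_record, seed,
                           bin_width = 1, pseudo = 0.5, delta = 1,
                           horizon = 120, floor_density = 1e-10) {
  stopifnot(inherits(params, "wnm_params"))
  if (n_pool < 1 || n_per_record < 1) stop("simulation budgets must be >= 1")
  N <- params$hyper$N
  parts <- cohort_parts(data, N)
  M <- length(parts$age)
  if (M == 0) stop("empty cohort")
  if (any(parts$surv_age < parts$age)) stop("surv_age < baseline age")

  edges <- seq(floor(min(parts$age) / bin_width) * bin_width,
               ceiling(max(parts$age) / bin_width) * bin_width + bin_width,
               by = bin_width)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  pool <- cpp_sim_pool_codes(cpp_pack(params), as.integer(n_pool), horizon,
                             mids, as.double(seed), 0)
  sdist <- make_statedist(pool$codes, N, edges, pseudo)

  bin_of <- findInterval(parts$age, edges, rightmost.closed = TRUE)
  n_states <- bitwShiftL(1L, N)
  prob_floor <- pseudo / (n_pool + pseudo * n_states)
  surv_floor <- 0.5 / n_per_record

  if (any(rowSums(!is.na(parts$d)) == 0)) {
    stop("every record needs at least one observed deficit")
  }
  full <- which(rowSums(is.na(parts$d)) == 0)
  partial <- setdiff(seq_len(M), full)
  ll <- 0

  # health terms
  for (m in seq_len(M)) {
    ph <- sum(sdist$probs[bin_of[m], completion_codes(parts$d[m, ]) + 1L])
    if (is.na(ph)) ph <- prob_floor  # model puts nobody alive in this bin
    ll <- ll + log(max(ph, prob_floor))
  }

  # mortality terms, fully observed records: batched forward simulations with
  # one stream block per record index so random numbers are common across
  # parameter values
  full_cens <- full[parts$censored[full] == 1L]
  full_unc <- full[parts$censored[full] == 0L]
  codes_full <- apply(parts$d, 1, function(dd) {
    dd[is.na(dd)] <- 0
    state_code(dd)
  })
  if (length(full_cens) > 0) {
    a <- parts$surv_age[full_cens]
    sf <- cpp_record_survfrac(
      cpp_pack(params), parts$age[full_cens],
      matrix(as.integer(parts$d[full_cens, , drop = FALSE]),
             nrow = length(full_cens)),
      a, a, horizon, as.integer(n_per_record), as.double(seed),
      record_stream(parts$age[full_cens], a, codes_full[full_cens], 1,
                    n_per_record))
    ll <- ll + sum(log(pmax(sf[, 1], surv_floor)))
  }
  if (length(full_unc) > 0) {
    a <- parts$surv_age[full_unc]
    sf <- cpp_record_survfrac(
      cpp_pack(params), parts$age[full_unc],
      matrix(as.integer(parts$d[full_unc, , drop = FALSE]),
             nrow = length(full_unc)),
      a - delta / 2, a + delta / 2, horizon, as.integer(n_per_record_unc),
      as.double(seed),
      record_stream(parts$age[full_unc], a, codes_full[full_unc], 0,
                    n_per_record_unc))
    ll <- ll + sum(log(pmax((sf[, 1] - sf[, 2]) / delta, floor_density)))
  }

  # mortality terms, records with missing deficits: condition on pool
  # individuals matching the observed sub-vector in the baseline age bin
  for (m in partial) {
    d <- parts$d[m, ]
    a <- parts$surv_age[m]
    cens <- parts$censored[m] == 1L
    obs <- which(!is.na(d))
    mask <- sum(bitwShiftL(1L, obs - 1L))
    target <- sum(bitwShiftL(1L, obs[d[obs] == 1] - 1L))
    cb <- pool$codes[, bin_of[m]]
    match <- cb >= 0L & bitwAnd(cb, mask) == target
    nm <- sum(match)
    if (nm == 0) {
      ll <- ll + log(if (cens) surv_floor else floor_density)
    } else {
      md <- pool$death_age[match]
      Sc <- function(x) if (x <= parts$age[m]) 1 else sum(md > x) / nm
      if (cens) {
        ll <- ll + log(max(Sc(a), 0.5 / nm))
      } else {
        dens <- (Sc(a - delta / 2) - Sc(a + delta / 2)) / delta
        ll <- ll + log(max(dens, floor_density))
      }
    }
  }
  ll
}
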