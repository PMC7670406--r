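# Constrained simulation-based maximum likelihood via particle swarm
# optimization.

#' Default parameter bounds
#'
#' Box constraints that enforce the model's monotonicity requirements: every
#' power-series coefficient of order >= 1 has lower bound 0 (so f_i, the
#' damage rates, x and the mortality rate are non-decreasing in age and in
#' what drives them); network weights, mortality weights and zeroth-order
#' coefficients may be negative and get a symmetric interval (the hinge
#' keeps the rates themselves non-negative). Diagonal weights are fixed at
#' `[0, 0]`. Upper bounds of order-n age-series coefficients (`mu`, `eta`)
#' are scaled by `age_scale^-n` so the series stays O(`weight_bound`) across
#' the representable age range.
#'
#' @param hyper A [wnm_hyper()] object.
#' @param weight_bound Half-width of the symmetric interval for weights and
#'   zeroth-order coefficients (default 10).
#' @param age_scale Age scale (years) used to damp upper bounds of age-series
#'   coefficients (default 100).
#' @return data.frame with columns `name`, `lower`, `upper`, `free` covering
#'   every written coefficient; the `free` rows (in [flatten_params()] order)
#'   are what the fitter varies.
#' @export
default_bounds <- function(hyper, weight_bound = 10, age_scale = 100) {
  stopifnot(inherits(hyper, "wnm_hyper"))
  N <- hyper$N
  rows <- list()
  add <- function(name, lower, upper, free = TRUE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, lower = lower, upper = upper, free = free)
  }
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) add(sprintf("W[%d,%d]", i, j), 0, 0, free = FALSE)
    else add(sprintf("W[%d,%d]", i, j), -weight_bound, weight_bound)
  }
  for (i in seq_len(N)) {
    add(sprintf("mu[%d,0]", i), 0, 0, free = FALSE)
    for (n in seq_len(hyper$n_f)) {
      add(sprintf("mu[%d,%d]", i, n), 0, weight_bound / age_scale^n)
    }
  }
  for (i in seq_len(N)) {
    add(sprintf("gamma[%d,0]", i), -weight_bound, weight_bound)
    for (n in seq_len(hyper$n_plus)) add(sprintf("gamma[%d,%d]", i, n), 0, weight_bound)
  }
  for (j in seq_len(N)) add(sprintf("beta[%d]", j), -weight_bound, weight_bound)
  add("alpha[0]", -weight_bound, weight_bound)
  for (n in seq_len(hyper$n_D1)) add(sprintf("alpha[%d]", n), 0, weight_bound)
  add("eta[0]", -weight_bound, weight_bound)
  for (n in seq_len(hyper$n_D2)) {
    add(sprintf("eta[%d]", n), 0, weight_bound / age_scale^n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Free-coordinate bound matrix in flatten order, reordered from the
# default_bounds() table by coordinate name.
free_bounds <- function(bounds, hyper) {
  fb <- bounds[bounds$free, ]
  nm <- flat_names(hyper)
  idx <- match(nm, fb$name)
  if (anyNA(idx)) stop("bounds table does not cover the free coordinates")
  cbind(lower = fb$lower[idx], upper = fb$upper[idx])
}

#' Fit configuration
#'
#' Settings for [fit()]: swarm size and iteration count, the standard
#' constriction-style PSO coefficients, box bounds, L1 regularization
#' strength, and the simulation budgets of each likelihood evaluation.
#'
#' @param swarm Number of particles (>= 2).
#' @param iterations PSO iterations (0 = best of the initial swarm).
#' @param inertia,cognitive,social PSO coefficients.
#' @param bounds Bounds table from [default_bounds()]; `NULL` uses defaults.
#' @param lambda L1 regularization strength on `W` and `beta` (default 0:
#'   bare likelihood).
#' @param n_pool,n_per_record Simulation budgets per likelihood evaluation
#'   (see [log_likelihood()]).
#' @param seed Integer seed driving both the swarm randomness and the
#'   common-random-numbers likelihood seed.
#' @param init_scale Fraction of the bound box used to initialize particles
#'   (keeps initial rates at plausible magnitudes).
#' @param bin_width,pseudo,delta,horizon Passed to [log_likelihood()].
#' @param verbose Print the global best every `verbose` iterations (0 = quiet).
#' @return A list of class `wnm_fit_config`.
#' @export
fit_config <- function(swarm = 50, iterations = 200, inertia = 0.72,
                       cognitive = 1.49, social = 1.49, bounds = NULL,
                       lambda = 0, n_pool = 10000, n_per_record = 500,
                       seed = 1L, init_scale = 0.1, bin_width = 1,
                       pseudo = 0.5, delta = 1, horizon = 120, verbose = 0) {
  if (swarm < 2) stop("swarm size must be >= 2")
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(swarm = swarm, iterations = iterations, inertia = inertia,
                 cognitive = cognitive, social = social, bounds = bounds,
                 lambda = lambda, n_pool = n_pool,
                 n_per_record = n_per_record, seed = seed,
                 init_scale = init_scale, bin_width = bin_width,
                 pseudo = pseudo, delta = delta, horizon = horizon,
                 verbose = verbose),
            class = "wnm_fit_config")
}

#' L1-penalized log-likelihood objective
#'
#' `log_likelihood(params, data) - lambda (||W||_1 + ||beta||_1)`; with
#' `lambda = 0` (the default configuration) this is the bare likelihood.
#'
#' @param params A `wnm_params` object; must satisfy the configured bounds.
#' @param data Cohort data.frame.
#' @param config A [fit_config()].
#' @return Scalar penalized log-likelihood.
#' @export
penalized_objective <- function(params, data, config) {
  stopifnot(inherits(config, "wnm_fit_config"))
  bounds <- if (is.null(config$bounds)) default_bounds(params$hyper) else config$bounds
  fb <- free_bounds(bounds, params$hyper)
  th <- flatten_params(params)
  if (any(th < fb[, "lower"] - 1e-12) || any(th > fb[, "upper"] + 1e-12)) {
    stop("parameters violate the configured bounds")
  }
  ll <- log_likelihood(params, data, n_pool = config$n_pool,
                       n_per_record = config$n_per_record,
                       seed = config$seed, bin_width = config$bin_width,
                       pseudo = config$pseudo, delta = config$delta,
                       horizon = config$horizon)
  ll - config$lambda * (sum(abs(params$W)) + sum(abs(params$beta)))
}

# Method-of-moments warm start for the swarm: marginal prevalences give
# constant-rate damage intercepts (solve prev = 1 - exp(-lambda t_bar)), the
# person-years death rate gives the mortality scale, and the age series are
# started so the background terms are O(1) at the mean age. Purely
# data-driven; returns a flat vector clamped into the bounds.
moment_init <- function(data, hyper, lo, hi) {
  parts <- cohort_parts(data, hyper$N)
  N <- hyper$N
  tbar <- mean(parts$age)
  prev <- colMeans(parts$d, na.rm = TRUE)
  th <- stats::setNames(numeric(length(lo)), flat_names(hyper))
  lamb <- -log(1 - pmin(pmax(prev, 0.02), 0.95)) / tbar
  th[sprintf("gamma[%d,0]", seq_len(N))] <- lamb
  if (hyper$n_plus >= 1) th[sprintf("gamma[%d,1]", seq_len(N))] <- lamb
  if (hyper$n_f >= 1) th[sprintf("mu[%d,1]", seq_len(N))] <- 0.2 / tbar
  person_years <- max(sum(parts$surv_age - parts$age), 1)
  mhat <- max(sum(parts$censored == 0), 0.5) / person_years
  xbar <- 1 + 0.3 * sum(prev)
  if (hyper$n_D2 >= 1) th["eta[1]"] <- 1 / tbar  # load ~ 1 at the mean age
  if (hyper$n_D1 >= 1) th["alpha[1]"] <- mhat / xbar else th["alpha[0]"] <- mhat
  th[sprintf("beta[%d]", seq_len(N))] <- 0.3
  pmin(pmax(th, lo), hi)
}

#' Fit the model by particle swarm optimization
#'
#' Global-best PSO over the free-coefficient vector with reflecting bound
#' handling. The swarm is seeded around a method-of-moments warm start
#' (prevalence-implied damage intercepts, person-years death rate), with the
#' remaining particles drawn uniformly inside the initialization box, so the
#' search starts at lifelike rate magnitudes. The stochastic likelihood is
#' tamed by common random numbers: a fixed likelihood seed is reused at
#' every parameter value, so the objective surface is deterministic within
#' one fit. Deterministic under a fixed config seed.
#'
#' @param data Cohort data.frame (columns `age`, `d1..dN`, `surv_age`,
#'   `censored`).
#' @param hyper A [wnm_hyper()] object.
#' @param config A [fit_config()].
#' @return A `wnm_fit`: list with `params` (best-ever `wnm_params`), `value`
#'   (best penalized log-likelihood), `trace` (per-iteration global best,
#'   non-decreasing), `n_evals`.
#' @export
fit <- function(data, hyper, config = fit_config()) {
  stopifnot(inherits(hyper, "wnm_hyper"), inherits(config, "wnm_fit_config"))
  if (nrow(data) == 0) stop("empty cohort")
  bounds <- if (is.null(config$bounds)) default_bounds(hyper) else config$bounds
  fb <- free_bounds(bounds, hyper)
  lo <- fb[, "lower"]
  hi <- fb[, "upper"]
  D <- length(lo)
  objective <- function(th) {
    p <- unflatten_params(pmin(pmax(th, lo), hi), hyper)
    ll <- log_likelihood(p, data, n_pool = config$n_pool,
                         n_per_record = config$n_per_record,
                         seed = config$seed, bin_width = config$bin_width,
                         pseudo = config$pseudo, delta = config$delta,
                         horizon = config$horizon)
    ll - config$lambda * (sum(abs(p$W)) + sum(abs(p$beta)))
  }

  set.seed(config$seed)
  S <- config$swarm
  # initialize inside a shrunken box so rates start at plausible magnitudes
  ilo <- lo * config$init_scale
  ihi <- hi * config$init_scale
  X <- matrix(stats::runif(S * D, rep(ilo, each = S), rep(ihi, each = S)), S, D)
  ws <- moment_init(data, hyper, lo, hi)
  X[1, ] <- ws
  for (s in 2:max(2, floor(S / 2))) {
    jit <- ws * exp(stats::rnorm(D, 0, 0.5))
    jit[ws == 0] <- stats::rnorm(sum(ws == 0), 0, 0.2)
    X[s, ] <- pmin(pmax(jit, lo), hi)
  }
  V <- matrix(0, S, D)
  # velocities capped at the scale of plausible coefficients, not of the box
  vmax <- 0.5 * pmax(ihi - ilo, 2 * abs(ws), 1e-8)

  fX <- apply(X, 1, objective)
  n_evals <- S
  if (all(!is.finite(fX))) {
    stop("objective non-finite at every initial particle; check data and bounds")
  }
  Pbest <- X
  fP <- fX
  g <- which.max(fP)
  gbest <- Pbest[g, ]
  fg <- fP[g]
  trace <- numeric(config$iterations)

  reflect <- function(x) {
    for (k in 1:50) {
      below <- x < lo
      above <- x > hi
      if (!any(below | above)) break
      x[below] <- 2 * lo[below] - x[below]
      x[above] <- 2 * hi[above] - x[above]
    }
    pmin(pmax(x, lo), hi)
  }

  for (it in seq_len(config$iterations)) {
    for (s in seq_len(S)) {
      r1 <- stats::runif(D)
      r2 <- stats::runif(D)
      V[s, ] <- config$inertia * V[s, ] +
        config$cognitive * r1 * (Pbest[s, ] - X[s, ]) +
        config$social * r2 * (gbest - X[s, ])
      V[s, ] <- pmin(pmax(V[s, ], -vmax), vmax)
      newx <- X[s, ] + V[s, ]
      out <- newx < lo | newx > hi
      V[s, out] <- -V[s, out]  # reflecting bound handling
      X[s, ] <- reflect(newx)
      val <- objective(X[s, ])
      n_evals <- n_evals + 1L
      if (is.finite(val) && val > fP[s]) {
        fP[s] <- val
        Pbest[s, ] <- X[s, ]
        if (val > fg) {
          fg <- val
          gbest <- X[s, ]
        }
      }
    }
    trace[it] <- fg
    if (config$verbose > 0 && it %% config$verbose == 0) {
      message(sprintf("iteration %d / %d: best objective %.3f",
                      it, config$iterations, fg))
    }
  }

  structure(list(params = unflatten_params(gbest, hyper), value = fg,
                 trace = trace, n_evals = n_evals, config = config),
            class = "wnm_fit")
}

#' @export
print.wnm_fit <- function(x, ...) {
  cat(sprintf("WNM fit: best penalized log-likelihood %.3f after %d evaluations\n",
              x$value, x$n_evals))
  invisible(x)
}

#' Age-balanced train/test split
#'
#' Bins individuals by baseline age and draws up to `per_bin` at random from
#' each bin into the training set; everyone else goes to the test set. This
#' keeps the training set's age distribution approximately uniform so no age
#' dominates the fit.
#'
#' @param data Cohort data.frame with an `age` column.
#' @param bin_width Age bin width in years (default 5).
#' @param per_bin Training individuals drawn per bin.
#' @param seed Integer seed.
#' @return List with disjoint data.frames `train` and `test` whose union is
#'   the input.
#' @export
balanced_train_test_split <- function(data, bin_width = 5, per_bin, seed) {
  if (bin_width <= 0) stop("bin_width must be positive")
  set.seed(seed)
  bin <- floor(data$age / bin_width)
  train_idx <- integer(0)
  for (b in sort(unique(bin))) {
    members <- which(bin == b)
    k <- min(per_bin, length(members))
    train_idx <- c(train_idx, sample(members, k))
  }
  train_idx <- sort(train_idx)
  list(train = data[train_idx, , drop = FALSE],
       test = data[setdiff(seq_len(nrow(data)), train_idx), , drop = FALSE])
}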