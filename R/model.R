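# Model core: parameter containers and the deterministic rate functions of the
# weighted network model (WNM) of aging.
#
# An individual carries N binary, irreversible deficits d_i. Node i's local
# frailty is f_i(t, {d_j}) = phi(sum_j w_ij d_j + mu_i(t)) with mu_i(t) a
# monotone power series in age; its damage (0 -> 1) rate is a hinged power
# series in f_i. Mortality is a separate hazard, a hinged power series in the
# deficit load x(t, {d_j}) = phi(sum_j beta_j d_j + eta(t)).

#' Hinge (rectifier) function
#'
#' `hinge(x) = max(x, 0)`, applied elementwise. Used throughout the model to
#' clip rate and load expressions to non-negative values while allowing
#' effective thresholding ("turning on" at older ages).
#'
#' @param x Numeric vector; must be finite.
#' @return Non-negative numeric vector of the same length.
#' @examples
#' hinge(c(-3.2, 0, 1.7))
#' @export
hinge <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("hinge() requires finite numeric input")
  }
  pmax(x, 0)
}

#' Model hyperparameters
#'
#' Sizes of the model: the number of binary health attributes `N` and the
#' highest powers of the four power series (background frailty `mu_i(t)`,
#' damage rate in `f_i`, mortality rate in `x`, and the age series inside
#' `x`). Defaults are the orders used for the 10-deficit human-study fits.
#'
#' @param N Number of binary health attributes (nodes), `>= 1`.
#' @param n_f Highest power in the background series `mu_i(t)`.
#' @param n_plus Highest power of the damage-rate series in `f_i`.
#' @param n_D1 Highest power of the mortality-rate series in `x`.
#' @param n_D2 Highest power of the age series inside `x`.
#' @return An object of class `wnm_hyper`.
#' @examples
#' wnm_hyper(N = 10)
#' @export
wnm_hyper <- function(N, n_f = 3L, n_plus = 4L, n_D1 = 3L, n_D2 = 3L) {
  vals <- c(N = N, n_f = n_f, n_plus = n_plus, n_D1 = n_D1, n_D2 = n_D2)
  if (any(!is.finite(vals)) || any(vals != round(vals)) || any(vals < 0)) {
    stop("hyperparameters must be non-negative integers")
  }
  if (N < 1) stop("N must be >= 1")
  structure(
    list(N = as.integer(N), n_f = as.integer(n_f), n_plus = as.integer(n_plus),
         n_D1 = as.integer(n_D1), n_D2 = as.integer(n_D2)),
    class = "wnm_hyper"
  )
}

#' @export
print.wnm_hyper <- function(x, ...) {
  cat(sprintf(
    "WNM hyperparameters: N = %d, n_f = %d, n_plus = %d, n_D1 = %d, n_D2 = %d\n",
    x$N, x$n_f, x$n_plus, x$n_D1, x$n_D2))
  cat(sprintf("free parameters: %d\n", count_parameters(x)))
  invisible(x)
}

#' Number of free model parameters
#'
#' Returns `N (N + n_f + n_plus + 1) + n_D1 + n_D2 + 2`, the number of free
#' coefficients under the package's fixing conventions: the diagonal of the
#' weight matrix is fixed at zero (a node's own weight never enters its
#' damage rate, which is only evaluated while the node is undamaged) and the
#' constant term of each `mu_i` series is fixed at zero (redundant with the
#' damage-rate intercept).
#'
#' @param hyper A [wnm_hyper()] object.
#' @return Integer count of free parameters.
#' @examples
#' count_parameters(wnm_hyper(N = 10))  # 188
#' @export
count_parameters <- function(hyper) {
  stopifnot(inherits(hyper, "wnm_hyper"))
  with(hyper, N * (N + n_f + n_plus + 1L) + n_D1 + n_D2 + 2L)
}

#' Model parameters
#'
#' Container for all fitted quantities of the weighted network model.
#'
#' @param hyper A [wnm_hyper()] object.
#' @param W `N x N` matrix of directed connection weights `w_ij` (row i =
#'   receiving node); the diagonal must be zero.
#' @param mu `N x n_f` matrix of background-frailty coefficients
#'   `mu_{i,n}`, columns n = 1..n_f (the constant term is fixed at 0);
#'   all entries `>= 0` so `mu_i(t)` is non-decreasing in age.
#' @param gamma `N x (n_plus + 1)` matrix of damage-rate coefficients
#'   `gamma_{i,n}`, columns n = 0..n_plus; columns for n >= 1 must be `>= 0`.
#' @param beta length-`N` vector of mortality deficit weights.
#' @param alpha length-`(n_D1 + 1)` mortality-rate coefficients, n = 0..n_D1;
#'   entries for n >= 1 must be `>= 0`.
#' @param eta length-`(n_D2 + 1)` age-series coefficients inside the
#'   mortality load, n = 0..n_D2; entries for n >= 1 must be `>= 0`.
#' @return An object of class `wnm_params`.
#' @examples
#' p <- wnm_params_zero(wnm_hyper(N = 2, n_f = 1, n_plus = 1, n_D1 = 1, n_D2 = 1))
#' p$gamma[, 1] <- 0.1
#' p <- validate_params(p)
#' @export
wnm_params <- function(hyper, W, mu, gamma, beta, alpha, eta) {
  p <- structure(
    list(hyper = hyper,
         W = as.matrix(W), mu = as.matrix(mu), gamma = as.matrix(gamma),
         beta = as.numeric(beta), alpha = as.numeric(alpha),
         eta = as.numeric(eta)),
    class = "wnm_params"
  )
  validate_params(p)
}

#' All-zero parameter skeleton
#'
#' Convenience constructor: every coefficient zero (all rates identically 0).
#'
#' @inheritParams wnm_params
#' @return A valid `wnm_params` object with all entries zero.
#' @export
wnm_params_zero <- function(hyper) {
  stopifnot(inherits(hyper, "wnm_hyper"))
  N <- hyper$N
  wnm_params(
    hyper,
    W = matrix(0, N, N),
    mu = matrix(0, N, max(hyper$n_f, 0L)),
    gamma = matrix(0, N, hyper$n_plus + 1L),
    beta = numeric(N),
    alpha = numeric(hyper$n_D1 + 1L),
    eta = numeric(hyper$n_D2 + 1L)
  )
}

#' Validate a parameter object
#'
#' Checks dimensions, finiteness, the zero diagonal of `W`, and the
#' non-negativity of all order `>= 1` series coefficients (which makes
#' `f_i`, `Gamma_i^+`, `x` and `Gamma_D` monotone non-decreasing in age and
#' in the quantities that drive them).
#'
#' @param p A `wnm_params` object.
#' @return `p`, invisibly usable, after validation (errors otherwise).
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "wnm_params"), inherits(p$hyper, "wnm_hyper"))
  h <- p$hyper
  N <- h$N
  if (!all(dim(p$W) == c(N, N))) stop("W must be N x N")
  if (!all(dim(p$mu) == c(N, h$n_f))) stop("mu must be N x n_f")
  if (!all(dim(p$gamma) == c(N, h$n_plus + 1L))) {
    stop("gamma must be N x (n_plus + 1)")
  }
  if (length(p$beta) != N) stop("beta must have length N")
  if (length(p$alpha) != h$n_D1 + 1L) stop("alpha must have length n_D1 + 1")
  if (length(p$eta) != h$n_D2 + 1L) stop("eta must have length n_D2 + 1")
  allv <- c(p$W, p$mu, p$gamma, p$beta, p$alpha, p$eta)
  if (any(!is.finite(allv))) stop("all parameters must be finite")
  if (any(diag(p$W) != 0)) stop("diagonal of W must be zero")
  if (any(p$mu < 0)) stop("mu coefficients (n >= 1) must be >= 0")
  if (h$n_plus >= 1 && any(p$gamma[, -1, drop = FALSE] < 0)) {
    stop("gamma coefficients of order >= 1 must be >= 0")
  }
  if (h$n_D1 >= 1 && any(p$alpha[-1] < 0)) {
    stop("alpha coefficients of order >= 1 must be >= 0")
  }
  if (h$n_D2 >= 1 && any(p$eta[-1] < 0)) {
    stop("eta coefficients of order >= 1 must be >= 0")
  }
  p
}

#' @export
print.wnm_params <- function(x, ...) {
  h <- x$hyper
  cat(sprintf("WNM parameters (N = %d, %d free parameters)\n",
              h$N, count_parameters(h)))
  cat(sprintf("  |w_ij| in [%.3g, %.3g], %d non-zero off-diagonal weights\n",
              min(abs(x$W[x$W != 0]), Inf), max(abs(x$W)),
              sum(x$W != 0)))
  cat(sprintf("  beta in [%.3g, %.3g]\n", min(x$beta), max(x$beta)))
  invisible(x)
}

#' Health state
#'
#' One individual's binary deficit vector at an age.
#'
#' @param deficits Vector of 0/1 values, length `N`.
#' @param age Age in years, `>= 0`.
#' @return An object of class `wnm_state`.
#' @examples
#' health_state(c(0, 1, 0), age = 70)
#' @export
health_state <- function(deficits, age) {
  deficits <- as.numeric(deficits)
  if (any(is.na(deficits)) || !all(deficits %in% c(0, 1))) {
    stop("deficits must be exactly 0 or 1")
  }
  if (!is.finite(age) || age < 0) stop("age must be a finite non-negative number")
  structure(list(deficits = deficits, age = as.numeric(age)),
            class = "wnm_state")
}

# Extract a 0/1 deficit vector from either a wnm_state or a bare vector.
as_deficits <- function(state, N) {
  d <- if (inherits(state, "wnm_state")) state$deficits else as.numeric(state)
  if (length(d) != N) stop("deficit vector has wrong length")
  if (any(is.na(d)) || !all(d %in% c(0, 1))) stop("deficits must be 0 or 1")
  d
}

# Horner evaluation of sum_{n=0}^{K} coef[n+1] * x^n.
horner <- function(coef, x) {
  acc <- 0
  for (cn in rev(coef)) acc <- acc * x + cn
  acc
}

# Background frailty series mu_i(t) = sum_{n>=1} mu_{i,n} t^n.
mu_series <- function(p, node, t) {
  if (p$hyper$n_f == 0L) return(0)
  horner(c(0, p$mu[node, ]), t)
}

#' Local frailty of a node
#'
#' `f_i(t, {d_j}) = hinge(sum_j w_ij d_j + mu_i(t))`: the weighted sum of the
#' node's damaged neighbours plus the monotone age-dependent background term
#' that stands in for unobserved nodes.
#'
#' @param params A `wnm_params` object.
#' @param node Node index in `1..N`.
#' @param state A [health_state()] or bare 0/1 deficit vector.
#' @param t Age in years, `>= 0`.
#' @return Non-negative local frailty value.
#' @export
local_frailty <- function(params, node, state, t) {
  h <- params$hyper
  if (node < 1 || node > h$N) stop("node index out of range")
  if (!is.finite(t) || t < 0) stop("age must be non-negative")
  d <- as_deficits(state, h$N)
  hinge(sum(params$W[node, ] * d) + mu_series(params, node, t))
}

#' Damage rate of an undamaged node
#'
#' `Gamma_i^+ = hinge(sum_{n=0}^{n_plus} gamma_{i,n} f_i^n)`, the 0 -> 1
#' transition rate (per year) for node `i`. Only defined while the node is
#' undamaged; querying a damaged node is a contract violation and errors.
#'
#' @inheritParams local_frailty
#' @return Damage rate in 1/year.
#' @export
damage_rate <- function(params, node, state, t) {
  h <- params$hyper
  if (node < 1 || node > h$N) stop("node index out of range")
  d <- as_deficits(state, h$N)
  if (d[node] != 0) {
    stop("damage_rate() queried for an already-damaged node (deficits are irreversible)")
  }
  f <- local_frailty(params, node, d, t)
  hinge(horner(params$gamma[node, ], f))
}

#' Mortality load
#'
#' `x(t, {d_j}) = hinge(sum_j beta_j d_j + sum_{n=0}^{n_D2} eta_n t^n)`: the
#' deficit-weighted load, plus a monotone age series, that drives mortality.
#'
#' @inheritParams local_frailty
#' @return Non-negative load value.
#' @export
mortality_load <- function(params, state, t) {
  h <- params$hyper
  if (!is.finite(t) || t < 0) stop("age must be non-negative")
  d <- as_deficits(state, h$N)
  hinge(sum(params$beta * d) + horner(params$eta, t))
}

#' Mortality rate
#'
#' `Gamma_D = hinge(sum_{n=0}^{n_D1} alpha_n x^n)`, the death hazard (per
#' year) at age `t` given the current deficits.
#'
#' @inheritParams local_frailty
#' @return Mortality rate in 1/year.
#' @export
mortality_rate <- function(params, state, t) {
  x <- mortality_load(params, state, t)
  hinge(horner(params$alpha, x))
}

#' Frailty index
#'
#' The fraction of an individual's potential deficits that are present,
#' `F = sum_i d_i / N`.
#'
#' @param state A [health_state()] or bare 0/1 deficit vector.
#' @return Value in `[0, 1]`.
#' @export
frailty_index <- function(state) {
  d <- if (inherits(state, "wnm_state")) state$deficits else as.numeric(state)
  if (any(is.na(d)) || !all(d %in% c(0, 1))) stop("deficits must be 0 or 1")
  mean(d)
}

# ---- flatten / unflatten ---------------------------------------------------

# Names of the free coordinates, in flatten order: W off-diagonal (column
# within row), mu, gamma, beta, alpha, eta.
flat_names <- function(hyper) {
  N <- hyper$N
  nm <- character(0)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) if (i != j) nm <- c(nm, sprintf("W[%d,%d]", i, j))
  }
  if (hyper$n_f >= 1) {
    nm <- c(nm, sprintf("mu[%d,%d]", rep(seq_len(N), each = hyper$n_f),
                        rep(seq_len(hyper$n_f), N)))
  }
  nm <- c(nm, sprintf("gamma[%d,%d]", rep(seq_len(N), each = hyper$n_plus + 1L),
                      rep(0:hyper$n_plus, N)))
  nm <- c(nm, sprintf("beta[%d]", seq_len(N)))
  nm <- c(nm, sprintf("alpha[%d]", 0:hyper$n_D1))
  nm <- c(nm, sprintf("eta[%d]", 0:hyper$n_D2))
  nm
}

#' Flatten model parameters to the free-coefficient vector
#'
#' Returns the named numeric vector of free coefficients the fitter varies:
#' off-diagonal weights (row-major), `mu` (per node, n = 1..n_f), `gamma`
#' (per node, n = 0..n_plus), `beta`, `alpha`, `eta`. Its length equals
#' [count_parameters()].
#'
#' @param params A `wnm_params` object.
#' @return Named numeric vector.
#' @seealso [unflatten_params()]
#' @export
flatten_params <- function(params) {
  h <- params$hyper
  N <- h$N
  offdiag <- as.vector(t(params$W))[as.vector(t(diag(N) == 0))]
  th <- c(offdiag,
          if (h$n_f >= 1) as.vector(t(params$mu)) else numeric(0),
          as.vector(t(params$gamma)),
          params$beta, params$alpha, params$eta)
  names(th) <- flat_names(h)
  th
}

#' Rebuild model parameters from a flat vector
#'
#' Inverse of [flatten_params()]: the fixed entries (diagonal of `W`, the
#' `mu` constant terms) are restored as zeros.
#'
#' @param theta Numeric vector of length [count_parameters()].
#' @param hyper A [wnm_hyper()] object.
#' @return A validated `wnm_params` object.
#' @export
unflatten_params <- function(theta, hyper) {
  stopifnot(inherits(hyper, "wnm_hyper"))
  N <- hyper$N
  if (length(theta) != count_parameters(hyper)) {
    stop("theta has wrong length: expected ", count_parameters(hyper))
  }
  pos <- 0L
  take <- function(k) {
    out <- theta[(pos + 1L):(pos + k)]
    pos <<- pos + k
    out
  }
  W <- matrix(0, N, N)
  for (i in seq_len(N)) W[i, -i] <- take(N - 1L)
  mu <- if (hyper$n_f >= 1) {
    matrix(take(N * hyper$n_f), N, hyper$n_f, byrow = TRUE)
  } else matrix(0, N, 0)
  gamma <- matrix(take(N * (hyper$n_plus + 1L)), N, hyper$n_plus + 1L,
                  byrow = TRUE)
  beta <- take(N)
  alpha <- take(hyper$n_D1 + 1L)
  eta <- take(hyper$n_D2 + 1L)
  wnm_params(hyper, W, mu, gamma, beta, alpha, eta)
}

# ---- serialization ---------------------------------------------------------

#' Write / read model parameters as JSON
#'
#' Parameters are stored under keys `W`, `mu`, `gamma`, `beta`, `alpha`,
#' `eta`, `hyper`. The decimal representation written round-trips exactly.
#'
#' @param params A `wnm_params` object.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   validated `wnm_params`.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "wnm_params"))
  obj <- list(
    hyper = unclass(params$hyper),
    W = params$W, mu = params$mu, gamma = params$gamma,
    beta = params$beta, alpha = params$alpha, eta = params$eta
  )
  # 17 significant digits: doubles survive the decimal round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- do.call(wnm_hyper, as.list(obj$hyper))
  mu <- obj$mu
  if (h$n_f == 0L || length(mu) == 0) mu <- matrix(0, h$N, 0)
  wnm_params(h, W = obj$W, mu = mu, gamma = obj$gamma,
             beta = obj$beta, alpha = obj$alpha, eta = obj$eta)
}
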