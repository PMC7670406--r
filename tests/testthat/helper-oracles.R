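# Shared fixtures and independent oracles, all built in code.

toy_hyper <- function(N, k = 1L) wnm_hyper(N, n_f = k, n_plus = k,
                                           n_D1 = k, n_D2 = k)

# random valid parameters at lifelike magnitudes
rand_params <- function(hyper, seed) {
  set.seed(seed)
  N <- hyper$N
  W <- matrix(stats::runif(N * N, -1, 1), N, N)
  diag(W) <- 0
  mu <- matrix(stats::runif(N * hyper$n_f, 0, 0.02), N, hyper$n_f)
  gamma <- cbind(stats::runif(N, -0.05, 0.05),
                 matrix(stats::runif(N * hyper$n_plus, 0, 0.1), N))
  beta <- stats::runif(N, -0.5, 1.5)
  alpha <- c(stats::runif(1, -0.05, 0.02),
             stats::runif(hyper$n_D1, 0, 0.05))
  eta <- c(stats::runif(1, -0.5, 0.5), stats::runif(hyper$n_D2, 0, 0.01))
  wnm_params(hyper, W, mu,
             gamma[, seq_len(hyper$n_plus + 1), drop = FALSE],
             beta, alpha[seq_len(hyper$n_D1 + 1)],
             eta[seq_len(hyper$n_D2 + 1)])
}

# N = 1 model: constant damage rate lambda; mortality m0 healthy, m1 damaged
params_n1 <- function(lambda, m0, m1) {
  p <- wnm_params_zero(toy_hyper(1))
  p$gamma[1, 1] <- lambda
  p$alpha <- c(m0, 1)
  p$beta <- m1 - m0
  p$eta <- c(0, 0)
  validate_params(p)
}

# closed-form pieces for the N = 1 constant-rate model
n1_joint_alive <- function(lambda, m0, m1, t) {
  # P(alive, d = 0 at t) and P(alive, d = 1 at t) from birth
  p0 <- exp(-(lambda + m0) * t)
  k <- lambda + m0 - m1
  p1 <- lambda * exp(-m1 * t) * (1 - exp(-k * t)) / k
  c(p0, p1)
}
n1_surv <- function(lambda, m0, m1, d, tau) {
  # P(alive at t + tau | alive with deficit d at t)
  if (d == 1) return(exp(-m1 * tau))
  k <- lambda + m0 - m1
  exp(-(lambda + m0) * tau) +
    lambda * (exp(-m1 * tau) - exp(-(lambda + m0) * tau)) / k
}
n1_density <- function(lambda, m0, m1, d, tau, h = 1e-6) {
  # exact death density by high-accuracy differentiation of the exact survival
  (n1_surv(lambda, m0, m1, d, tau - h) -
     n1_surv(lambda, m0, m1, d, tau + h)) / (2 * h)
}

# exact log-likelihood of a cohort under the N = 1 constant-rate model
n1_loglik <- function(lambda, m0, m1, data) {
  ll <- 0
  for (m in seq_len(nrow(data))) {
    t0 <- data$age[m]
    d <- data$d1[m]
    a <- data$surv_age[m]
    pj <- n1_joint_alive(lambda, m0, m1, t0)
    ll <- ll + log(pj[d + 1] / sum(pj))
    if (data$censored[m] == 1) {
      ll <- ll + log(n1_surv(lambda, m0, m1, d, a - t0))
    } else {
      ll <- ll + log(n1_density(lambda, m0, m1, d, a - t0))
    }
  }
  ll
}

# N = 2 time-independent master-equation oracle: returns P(state) over
# {00, 10, 01, 11, dead} at age t, starting undamaged at birth, by matrix
# exponential of the explicit generator (independent of the event simulator).
n2_master_probs <- function(params, t) {
  states <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  Q <- matrix(0, 5, 5)
  for (s in 1:4) {
    d <- states[[s]]
    for (i in 1:2) {
      if (d[i] == 0) {
        d2 <- d
        d2[i] <- 1
        s2 <- which(vapply(states, identical, logical(1), as.numeric(d2)))
        Q[s, s2] <- damage_rate(params, i, d, 0)
      }
    }
    Q[s, 5] <- mortality_rate(params, d, 0)
    Q[s, s] <- -sum(Q[s, -s])
  }
  p0 <- c(1, 0, 0, 0, 0)
  as.numeric(p0 %*% as.matrix(Matrix::expm(Q * t)))
}

# small CSHA-like synthetic study used across tests
small_csha_design <- function(M) {
  cohort_design(M = M, age_range = c(65, 99), window = 6,
                age_dist = "truncnorm", age_mean = 76, age_sd = 7,
                label = "CSHA-like-small")
}

# fabricate a survival step function from explicit death ages (for metric
# oracle tests)
fake_survfn <- function(t0, death_ages, horizon = 120) {
  structure(list(t0 = t0, death_ages = sort(death_ages),
                 n_sim = length(death_ages), horizon = horizon),
            class = "wnm_survfn")
}
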