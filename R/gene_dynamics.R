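# Local solutions for a single gene element over one synchronization step.
#
# Scenario 1: promoter activity enters as a constant probability a over the
# step and the product follows the closed-form linear birth-death solution.
# Scenario 2: the promoter switches stochastically between on and off at
# the effective rates; the product follows the closed form piecewise.
# Scenario 3: additionally, product synthesis and decay are discrete
# stochastic events (Poisson births during on-periods, binomial survival
# during off-periods).

#' Deterministic gene-product advance (scenario 1)
#'
#' Closed-form solution of \code{dn/dt = a*nu - delta*n} with the
#' activation probability \code{a} held constant over the step:
#' \code{n(dt) = n0 exp(-delta dt) + a nu/delta (1 - exp(-delta dt))}.
#'
#' @param n0 abundance at the start of the step
#' @param a activation probability in [0, 1]
#' @param nu synthesis rate (molecules/s)
#' @param delta degradation rate (1/s), > 0
#' @param dt step length (s)
#' @return abundance at the end of the step
#' @export
advance_deterministic <- function(n0, a, nu, delta, dt) {
  if (delta <= 0) stop("delta must be > 0")
  stopifnot(a >= 0, a <= 1)
  e <- exp(-delta * dt)
  n0 * e + a * nu / delta * (1 - e)
}

#' Draw an exponential switching time from a uniform deviate
#'
#' Inverse-transform sampling of the waiting time to the next promoter
#' switch: \code{t = -log(u)/alpha}.
#'
#' @param alpha current switching rate (1/s), > 0
#' @param u uniform draw in (0, 1]
#' @return waiting time in seconds
#' @export
draw_switch_time <- function(alpha, u) {
  if (alpha <= 0) stop("alpha must be > 0 (a zero rate never switches)")
  -log(u) / alpha
}

# Realize the on/off partition of [0, dt] for a telegraph promoter with
# constant rates.  Returns the final state and a matrix of intervals
# (columns: duration, on).  Rates equal to zero freeze the current state.
.realize_switching <- function(on, lambda_eff, mu_eff, dt) {
  durs <- numeric(0); states <- logical(0)
  t <- 0
  repeat {
    rate <- if (on) mu_eff else lambda_eff
    tau <- if (rate <= 0) Inf else draw_switch_time(rate, stats::runif(1))
    if (t + tau >= dt) {
      durs <- c(durs, dt - t); states <- c(states, on)
      break
    }
    durs <- c(durs, tau); states <- c(states, on)
    t <- t + tau
    on <- !on
  }
  list(on = on, intervals = cbind(duration = durs, on = as.numeric(states)))
}

#' Advance a gene with stochastic promoter switching (scenario 2)
#'
#' The promoter toggles at exponential waiting times drawn from the
#' effective rates (constant within the step); between toggles the product
#' follows the deterministic on/off closed forms.  The realized on/off
#' partition of the step is returned alongside the new state.
#'
#' @param state list with elements \code{n} (product abundance) and
#'   \code{on} (logical promoter state)
#' @param rates an \code{\link{effective_rates}} object
#' @param nu,delta synthesis and degradation rates
#' @param dt step length (s)
#' @return list with elements \code{n}, \code{on} and \code{intervals}
#'   (matrix with columns duration, on)
#' @export
advance_two_state <- function(state, rates, nu, delta, dt) {
  sw <- .realize_switching(state$on, rates$lambda_eff, rates$mu_eff, dt)
  n <- state$n
  for (i in seq_len(nrow(sw$intervals))) {
    tau <- unname(sw$intervals[i, 1L])
    a <- unname(sw$intervals[i, 2L])
    n <- advance_deterministic(n, a, nu, delta, tau)
  }
  list(n = n, on = sw$on, intervals = sw$intervals)
}

#' Poisson number of birth events during an on-period
#'
#' @param nu synthesis rate (molecules/s)
#' @param tau_on duration of the on-period (s)
#' @return integer count, Poisson with mean \code{nu * tau_on}
#' @export
sample_births <- function(nu, tau_on) {
  stopifnot(tau_on >= 0)
  if (tau_on == 0 || nu == 0) return(0L)
  stats::rpois(1L, nu * tau_on)
}

#' Binomial number of survivors after an off-period
#'
#' Each of \code{n} molecules independently survives a period of length
#' \code{tau_off} with probability \code{exp(-delta * tau_off)}.
#'
#' @param n integer molecule count at the start
#' @param delta degradation rate (1/s)
#' @param tau_off period length (s)
#' @return integer count of surviving molecules
#' @export
sample_survivors <- function(n, delta, tau_off) {
  stopifnot(n >= 0)
  if (n == 0) return(0L)
  if (delta == 0) return(as.integer(n))
  stats::rbinom(1L, n, exp(-delta * tau_off))
}

# Round a non-negative real to an integer preserving the mean:
# floor plus a Bernoulli draw on the fractional part.
stochastic_round <- function(x) {
  f <- floor(x)
  as.integer(f + (stats::runif(length(x)) < (x - f)))
}

#' Advance a gene with stochastic switching and birth/death (scenario 3)
#'
#' Per realized on-interval, the surviving pre-existing molecules are
#' obtained by applying the deterministic decay factor (with stochastic
#' rounding of the fractional part) and new molecules are added as a
#' Poisson draw with mean \code{nu * tau_on}; per off-interval the count is
#' thinned by a binomial survival draw.  The product abundance stays
#' integer.
#'
#' @inheritParams advance_two_state
#' @return list with elements \code{n} (integer), \code{on} and
#'   \code{intervals}
#' @export
advance_stochastic <- function(state, rates, nu, delta, dt) {
  sw <- .realize_switching(state$on, rates$lambda_eff, rates$mu_eff, dt)
  n <- as.integer(round(state$n))
  for (i in seq_len(nrow(sw$intervals))) {
    tau <- unname(sw$intervals[i, 1L])
    if (sw$intervals[i, 2L] > 0) {
      n <- stochastic_round(n * exp(-delta * tau)) + sample_births(nu, tau)
    } else {
      n <- sample_survivors(n, delta, tau)
    }
  }
  list(n = n, on = sw$on, intervals = sw$intervals)
}

#' Partial-fraction coefficients of a rate-limiting chain
#'
#' Coefficients \code{alpha_i} of the partial-fraction expansion of the
#' transfer function of a linear chain of first-order steps with pairwise
#' distinct rates \code{beta_1..beta_N}:
#' \code{alpha_i = prod(beta_1..beta_{N-1}) / prod_{n != i}(beta_n - beta_i)}.
#'
#' @param betas vector of positive, pairwise distinct rates
#' @return numeric vector of coefficients, one per rate
#' @export
partial_fraction_coeffs <- function(betas) {
  n <- length(betas)
  stopifnot(n >= 1, all(betas > 0))
  if (n == 1L) return(1)
  if (min(abs(diff(sort(betas)))) / max(betas) < 1e-9)
    stop("near-equal chain rates; perturb them by a relative 1e-6 before calling")
  num <- prod(betas[-n])
  vapply(seq_len(n), function(i) num / prod(betas[-i] - betas[i]), numeric(1))
}

# Closed-form matrix exponential of the lower-bidiagonal cascade generator
# with removal rates r_i and feed rates r_{i-1} (the chain of Eq.-24 type):
# E[i, j] = (prod_{k=j}^{i-1} r_k) * sum_m exp(-r_m t) / prod_{k != m}(r_k - r_m)
.chain_expm <- function(rates, tau) {
  n <- length(rates)
  E <- matrix(0, n, n)
  ex <- exp(-rates * tau)
  for (j in seq_len(n)) {
    E[j, j] <- ex[j]
    for (i in seq_len(n)[-seq_len(j)]) {
      idx <- j:i
      num <- prod(rates[j:(i - 1L)])
      s <- 0
      for (m in idx) s <- s + ex[m] / prod(rates[setdiff(idx, m)] - rates[m])
      E[i, j] <- num * s
    }
  }
  E
}

#' Exact advance of a deterministic rate-limiting delay chain
#'
#' Propagates the linear cascade \code{dc_1/dt = a nu - r_1 c_1},
#' \code{dc_i/dt = r_{i-1} c_{i-1} - r_i c_i} exactly over a step with
#' piecewise-constant drive \code{a}.  The rates vector holds the chain
#' rates in order; when used for a gene, the last rate is the product
#' degradation rate \code{delta} so that the final stage is the mature
#' product.
#'
#' @param chain numeric vector of stage abundances
#' @param a drive: a single probability held constant over \code{dt}, or a
#'   matrix of realized intervals (columns duration, on) as returned by
#'   \code{\link{advance_two_state}}
#' @param nu synthesis rate feeding the first stage
#' @param rates positive, pairwise distinct stage rates (same length as
#'   \code{chain})
#' @param dt step length, used when \code{a} is scalar
#' @return the chain vector at the end of the step
#' @export
advance_delay_chain <- function(chain, a, nu, rates, dt = NULL) {
  n <- length(rates)
  stopifnot(length(chain) == n, all(rates > 0))
  if (n > 1L && min(abs(diff(sort(rates)))) / max(rates) < 1e-9)
    stop("near-equal chain rates; perturb them by a relative 1e-6")
  if (is.matrix(a)) {
    ivals <- a
  } else {
    stopifnot(!is.null(dt))
    ivals <- cbind(dt, a)
  }
  cstar_unit <- nu / rates * c(1, rep(1, n - 1L))  # steady state for a = 1
  # (c*_1 = nu/r_1, c*_i = r_{i-1} c*_{i-1} / r_i = nu / r_i)
  for (i in seq_len(nrow(ivals))) {
    tau <- ivals[i, 1L]; ai <- ivals[i, 2L]
    if (tau <= 0) next
    cs <- ai * cstar_unit
    chain <- cs + .chain_expm(rates, tau) %*% (chain - cs)
  }
  as.numeric(chain)
}

#' Fixed reporting delay via a ring queue
#'
#' Returns the output from \code{m} synchronization steps ago and pushes
#' the current output; with an empty queue (\code{m = 0}) the current
#' output passes through unchanged.
#'
#' @param queue numeric vector of the last \code{m} outputs (oldest first)
#' @param current_output output computed this step
#' @return list with \code{out} (the reported, delayed value) and
#'   \code{queue} (updated)
#' @export
delayed_output <- function(queue, current_output) {
  if (length(queue) == 0L)
    return(list(out = current_output, queue = queue))
  list(out = queue[1L], queue = c(queue[-1L], current_output))
}

#' Check the synchronization-step criterion for a gene
#'
#' The hybrid scheme assumes changes of less than one molecule per element
#' and step; for a gene this is \code{p_on * nu * dt < 1}.  Returns a
#' warning record when the criterion is violated, otherwise \code{NULL}.
#'
#' @param p_on stationary on-probability of the promoter
#' @param nu synthesis rate
#' @param dt synchronization step
#' @return \code{NULL}, or a character string describing the violation
#' @export
check_step_criterion <- function(p_on, nu, dt) {
  if (p_on * nu * dt >= 1)
    sprintf("p_on*nu*dt = %.3g >= 1; reduce dt", p_on * nu * dt)
  else NULL
}
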