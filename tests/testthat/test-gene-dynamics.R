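test_that("deterministic advance solves the linear birth-death ODE", {
  # pure decay
  expect_equal(advance_deterministic(50, 0, 1, 0.1, 7), 50 * exp(-0.7))
  # fixed point
  expect_equal(advance_deterministic(0.8 * 2 / 0.1, 0.8, 2, 0.1, 13),
               0.8 * 2 / 0.1)
  # against adaptive numerical integration
  num <- deSolve::ode(y = c(n = 0), times = c(0, 10),
                      func = function(t, y, p) list(2 - 0.1 * y),
                      parms = NULL, rtol = 1e-12, atol = 1e-12)[2, 2] |> unname()
  expect_equal(advance_deterministic(0, 1, 2, 0.1, 10), num,
               tolerance = 1e-9)
  expect_error(advance_deterministic(1, 0.5, 1, 0, 1))
})

test_that("switch times invert the exponential law", {
  expect_equal(draw_switch_time(3, 1), 0)
  expect_equal(draw_switch_time(2, exp(-2)), 1)
  expect_error(draw_switch_time(0, 0.5))
  set.seed(21)
  draws <- vapply(stats::runif(1e5), draw_switch_time, numeric(1), alpha = 0.5)
  expect_lt(abs(mean(draws) - 2), 3 * 2 / sqrt(1e5))  # exp mean = sd = 2
})

test_that("two-state advance partitions the step and freezes at zero rates", {
  set.seed(1)
  st <- advance_two_state(list(n = 40, on = FALSE),
                          effective_rates(0, 1), nu = 1, delta = 0.01, dt = 50)
  expect_equal(st$n, 40 * exp(-0.5))       # never activates, pure decay
  expect_equal(nrow(st$intervals), 1L)
  expect_equal(sum(st$intervals[, 1]), 50)

  # near-instant deactivation: first on-interval is essentially zero
  set.seed(2)
  st2 <- advance_two_state(list(n = 10, on = TRUE),
                           effective_rates(1e-300, 1e12), 1, 0.01, 10)
  expect_true(st2$intervals[1, 2] == 1)
  expect_lt(st2$intervals[1, 1], 1e-9)
  expect_equal(sum(st2$intervals[, 1]), 10)

  # long-run time-average of the on-indicator matches p_on
  set.seed(3)
  r <- effective_rates(0.01, 0.04)
  on_time <- 0; state <- list(n = 0, on = FALSE)
  nstep <- 2000; dt <- 500
  for (i in seq_len(nstep)) {
    state <- advance_two_state(state, r, 0, 1e-9, dt)
    iv <- state$intervals
    on_time <- on_time + sum(iv[iv[, 2] == 1, 1])
  }
  frac <- on_time / (nstep * dt)
  n_cycles <- nstep * dt * r$lambda_eff * r$p_on  # rough independent cycles
  expect_lt(abs(frac - 0.2), 3 * 0.4 / sqrt(n_cycles))
})

test_that("birth and survivor draws have the right moments", {
  expect_identical(sample_births(5, 0), 0L)
  set.seed(4)
  b <- replicate(1e5, sample_births(1.5, 2))       # mean 3
  expect_lt(abs(mean(b) - 3), 3 * sqrt(3 / 1e5))
  expect_lt(abs(stats::var(b) - 3), 3 * 3 * sqrt(2 / 1e5))
  expect_identical(sample_survivors(0, 1, 1), 0L)
  expect_identical(sample_survivors(17, 0, 5), 17L)
  set.seed(5)
  s <- replicate(1e5, sample_survivors(100, -log(0.8), 1))
  expect_lt(abs(mean(s) - 80), 3 * sqrt(100 * 0.8 * 0.2 / 1e5))
})

test_that("scenario-3 advance keeps counts integer and reaches the Poisson law", {
  set.seed(6)
  st <- advance_stochastic(list(n = 0, on = FALSE),
                           effective_rates(0, 1), 1, 0.01, 10)
  expect_identical(st$n, 0L)
  # always-on gene: stationary mean nu/delta, Fano ~ 1
  set.seed(7)
  nu <- 2; delta <- 0.02; dt <- 0.4          # nu*dt < 1
  state <- list(n = as.integer(nu / delta), on = TRUE)
  r <- effective_rates(1e12, 1e-12)
  vals <- integer(20000)
  for (i in seq_along(vals)) {
    state <- advance_stochastic(state, r, nu, delta, dt)
    vals[i] <- state$n
  }
  vals <- vals[-(1:2000)]
  tau_corr <- 1 / delta / dt                  # samples per correlation time
  n_eff <- length(vals) / (2 * tau_corr)
  m <- mean(vals); v <- stats::var(vals)
  expect_lt(abs(m - nu / delta), 3 * sqrt(v / n_eff))
  expect_lt(abs(v / m - 1), 3 * sqrt(2 / n_eff) + 0.02)
})

test_that("partial fractions follow the chain transfer function", {
  expect_equal(partial_fraction_coeffs(5), 1)
  expect_equal(partial_fraction_coeffs(c(1, 2)), c(1, -1))
  set.seed(8)
  for (N in 2:5) {
    betas <- sort(stats::runif(N, 0.1, 2))
    alpha <- partial_fraction_coeffs(betas)
    # steady state of the cascade driven at unit activity: sum alpha_i/beta_i
    expect_equal(sum(alpha / betas), 1 / betas[N], tolerance = 1e-9)
  }
  expect_error(partial_fraction_coeffs(c(1, 1 + 1e-12)), "perturb")
})

test_that("delay-chain propagation is exact against numerical integration", {
  rates <- c(0.11, 0.23, 0.05)
  # constant drive reaches nu/beta_N at every stage's own scale
  ch <- advance_delay_chain(c(0, 0, 0), a = 1, nu = 0.7, rates = rates,
                            dt = 2000)
  expect_equal(ch, 0.7 / rates, tolerance = 1e-6)
  # piecewise on/off drive vs deSolve
  ivals <- cbind(duration = c(30, 55, 20, 45), on = c(1, 0, 1, 0))
  ch0 <- c(1, 2, 3)
  got <- advance_delay_chain(ch0, ivals, nu = 0.7, rates = rates)
  a_of_t <- stats::stepfun(cumsum(ivals[, 1]), c(ivals[, 2], 0))
  rhs <- function(t, y, p) {
    a <- a_of_t(t - 1e-12)
    list(c(a * 0.7 - rates[1] * y[1],
           rates[1] * y[1] - rates[2] * y[2],
           rates[2] * y[2] - rates[3] * y[3]))
  }
  num <- deSolve::ode(y = ch0, times = c(0, sum(ivals[, 1])), func = rhs,
                      parms = NULL, rtol = 1e-10, atol = 1e-10)
  expect_equal(got, as.numeric(num[2, 2:4]), tolerance = 1e-6)
})

test_that("delay chain conserves throughput after the transient", {
  # time-integral of beta_N c_N equals the integral of a*nu
  rates <- c(0.05, 0.02)
  ch <- c(0, 0); dt <- 5; nsteps <- 40000
  out_int <- 0; in_int <- 0
  set.seed(9)
  for (q in seq_len(nsteps)) {
    a <- as.numeric(q %% 40 < 20)            # square-wave activity
    ch <- advance_delay_chain(ch, a, nu = 0.3, rates = rates, dt = dt)
    if (q > 2000) {
      out_int <- out_int + rates[2] * ch[2] * dt
      in_int <- in_int + a * 0.3 * dt
    }
  }
  expect_lt(abs(out_int - in_int) / in_int, 0.01)
})

test_that("queue delay is a pure shift", {
  expect_equal(delayed_output(numeric(0), 42)$out, 42)
  q <- rep(0, 10)
  outs <- numeric(15)
  for (i in 1:15) {
    d <- delayed_output(q, i)
    outs[i] <- d$out; q <- d$queue
  }
  expect_equal(outs, c(rep(0, 10), 1:5))
})

test_that("the step criterion flags fast product gain", {
  expect_null(check_step_criterion(0.5, 0.1, 1))
  expect_match(check_step_criterion(1, 2, 1), "reduce dt")
  expect_match(check_step_criterion(0.5, 2, 1), "reduce dt")  # boundary = 1
})
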