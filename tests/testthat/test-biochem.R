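# Closed-form reaction elements against quadrature/ODE oracles.

dimer_rhs <- function(N1, N2, lambda, D, j) {
  function(t, y, p) list(lambda * (N1 - y) * (N2 - y) - D * y + j)
}

test_that("fixed points solve the complex quadratic", {
  # binding goes to completion when unbinding/degradation vanish
  fp <- dimer_fixed_points(30, 80, 1, 1e-9, 0, 0, 0)
  expect_equal(fp[1], 30, tolerance = 1e-6)
  # symmetric double root at N when K^-1 = 0
  fp2 <- dimer_fixed_points(50, 50, 2, 0, 0, 0, 0)
  expect_equal(fp2[1], fp2[2], tolerance = 1e-9)
  expect_equal(fp2[1], 50, tolerance = 1e-9)
  # textbook quadratic: f^2 - 250 f + 5000
  fp3 <- dimer_fixed_points(100, 50, 0.01, 1, 0, 0, 0)
  expect_equal(fp3[1], (250 - sqrt(250^2 - 4 * 5000)) / 2, tolerance = 1e-9)
  expect_equal(fp3[1], 21.922, tolerance = 1e-4)
  # the stable root really zeroes the derivative
  rhs <- dimer_rhs(100, 50, 0.01, 1, 0)
  expect_equal(rhs(0, fp3[1], NULL)[[1]], 0, tolerance = 1e-9)
})

test_that("complex trajectory matches adaptive integration and is monotone", {
  N1 <- 100; N2 <- 50; lambda <- 0.01; D <- 1; j <- 2
  fp <- dimer_fixed_points(N1, N2, lambda, 0.5, 0.3, 0.2, j)
  for (f0 in c(0, 5, fp[1], 40)) {
    num <- deSolve::ode(y = c(f = f0), times = c(0, 10),
                        func = dimer_rhs(N1, N2, lambda, 1, j),
                        parms = NULL, rtol = 1e-12, atol = 1e-12)[2, 2] |> unname()
    expect_equal(dimer_advance(f0, 10, fp[1], fp[2], lambda), num,
                 tolerance = 1e-6)
  }
  # fixed point stays; t -> infinity converges to the stable root
  expect_equal(dimer_advance(fp[1], 5, fp[1], fp[2], lambda), fp[1])
  expect_equal(dimer_advance(40, 1e9, fp[1], fp[2], lambda), fp[1],
               tolerance = 1e-9)
  expect_equal(dimer_advance(fp[2], 3, fp[1], fp[2], lambda), fp[2])
  # monotone approach to f1 from both sides
  ts <- seq(0.5, 20, by = 0.5)
  from_above <- vapply(ts, function(t) dimer_advance(40, t, fp[1], fp[2], lambda),
                       numeric(1))
  expect_true(all(diff(from_above) < 1e-12))
  from_below <- vapply(ts, function(t) dimer_advance(0, t, fp[1], fp[2], lambda),
                       numeric(1))
  expect_true(all(diff(from_below) > -1e-12))
})

test_that("mean occupancy and fluxes agree with quadrature of the exact path", {
  N1 <- 100; N2 <- 50; lambda <- 0.01; mu <- 0.5; d1 <- 0.3; d2 <- 0.2; j <- 2
  D <- d1 + d2 + mu
  fp <- dimer_fixed_points(N1, N2, lambda, mu, d1, d2, j)
  f0 <- 5; dt <- 10
  num <- deSolve::ode(
    y = c(f = f0, If = 0), times = c(0, dt),
    func = function(t, y, p) list(c(
      lambda * (N1 - y[1]) * (N2 - y[1]) - D * y[1] + j, y[1])),
    parms = NULL, rtol = 1e-12, atol = 1e-12)
  fbar_num <- unname(num[2, 3]) / dt
  expect_equal(dimer_mean_complex(f0, dt, fp[1], fp[2], lambda), fbar_num,
               tolerance = 1e-7)
  # flux integrands: association - (mu + other delta) f + j
  quad <- deSolve::ode(
    y = c(f = f0, J1 = 0, J2 = 0), times = c(0, dt),
    func = function(t, y, p) {
      assoc <- lambda * (N1 - y[1]) * (N2 - y[1])
      list(c(assoc - D * y[1] + j,
             assoc - (d2 + mu) * y[1] + j,
             assoc - (d1 + mu) * y[1] + j))
    }, parms = NULL, rtol = 1e-12, atol = 1e-12)
  fl <- dimer_fluxes(f0, dt, fp[1], fp[2], lambda, d1, d2)
  expect_equal(unname(fl[1]), unname(quad[2, "J1"]), tolerance = 1e-5)
  expect_equal(unname(fl[2]), unname(quad[2, "J2"]), tolerance = 1e-5)
  # no reaction, no complex: both fluxes vanish
  z <- homodimer_advance(0, 50, 0, 0.1, 0.05, 0, 5)
  expect_equal(z$consumed_monomer, 0)
})

test_that("homodimer reuses the dimer solution under the documented mapping", {
  N <- 80; lambda <- 0.005; mu <- 0.2; d1 <- 0.1; j <- 1
  num <- deSolve::ode(y = c(f = 3), times = c(0, 7),
                      func = function(t, y, p)
                        list(lambda * (N - 2 * y)^2 - (2 * d1 + mu) * y + j),
                      parms = NULL, rtol = 1e-12, atol = 1e-12)[2, 2] |> unname()
  expect_equal(homodimer_advance(3, N, lambda, mu, d1, j, 7)$f, num,
               tolerance = 1e-6)
  # lambda = 0: linear relaxation to j/(2 d1 + mu)
  lin <- homodimer_advance(0, N, 0, mu, d1, j, 1e6)
  expect_equal(lin$f, j / (2 * d1 + mu), tolerance = 1e-9)
  # starting at the mapped stable root stays put
  fp <- dimer_fixed_points(N / 2, N / 2, 4 * lambda, mu, d1, d1, j)
  expect_equal(homodimer_advance(fp[1], N, lambda, mu, d1, j, 50)$f, fp[1],
               tolerance = 1e-9)
})

test_that("enzyme element: reduction, steady state, and dt -> 0 convergence", {
  Ns <- 60; Ne <- 20; lambda <- 0.002; mu <- 0.1; d <- c(0.01, 0.005, 0.02)
  # nu = 0 reduces the complex to a plain hetero-dimer and the product decays
  e0 <- enzyme_advance(list(f = 2, m = 10), Ns, Ne, lambda, mu, 0, d,
                       0, 0, 15)
  fp <- dimer_fixed_points(Ns, Ne, lambda, mu, d[1], d[2], 0)
  expect_equal(e0$f, dimer_advance(2, 15, fp[1], fp[2], lambda))
  expect_equal(e0$m, 10 * exp(-d[3] * 15))
  # dt -> infinity with stationary complex: m -> (nu fbar + j)/d3
  eb <- enzyme_advance(list(f = fp[1], m = 0), Ns, Ne, lambda, mu, 0, d,
                       0, 0.3, 1e6)
  expect_equal(eb$m, 0.3 / d[3], tolerance = 1e-9)
  # product follows its closed form in fbar exactly
  nu <- 0.05
  e1 <- enzyme_advance(list(f = 2, m = 10), Ns, Ne, lambda, mu, nu, d,
                       0, 0.3, 20)
  m_expected <- 10 * exp(-d[3] * 20) +
    (nu * e1$fbar + 0.3) / d[3] * (1 - exp(-d[3] * 20))
  expect_equal(e1$m, m_expected, tolerance = 1e-12)
  # against the fully coupled ODE the error vanishes linearly in dt
  coupled <- function(dt) {
    num <- deSolve::ode(y = c(f = 2, m = 10), times = seq(0, 20, by = dt / 2),
      func = function(t, y, p) list(c(
        lambda * (Ns - y[1]) * (Ne - y[1]) - (d[1] + nu + d[2] + mu) * y[1],
        nu * y[1] - d[3] * y[2] + 0.3)),
      parms = NULL, rtol = 1e-12, atol = 1e-12)
    unname(num[nrow(num), 3])
  }
  m_exact <- coupled(0.5)
  err <- vapply(c(20, 10, 5), function(dt) {
    st <- list(f = 2, m = 10)
    for (k in seq_len(20 / dt))
      st <- enzyme_advance(st, Ns, Ne, lambda, mu, nu, d, 0, 0.3, dt)
    abs(st$m - m_exact)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], err[1] / 2)
  expect_error(enzyme_advance(list(f = 0, m = 0), Ns, Ne, lambda, mu, nu,
                              c(0.01, 0, 0), 0, 0, 1))
})

test_that("mass bookkeeping closes over a step", {
  # change in free monomers + change in complex + degraded amounts = 0
  N1 <- 100; N2 <- 50; lambda <- 0.01; mu <- 0.5; d1 <- 0.3; d2 <- 0.2
  D <- d1 + d2 + mu
  f0 <- 5; dt <- 4
  fp <- dimer_fixed_points(N1, N2, lambda, mu, d1, d2, 0)
  fdt <- dimer_advance(f0, dt, fp[1], fp[2], lambda)
  fbar <- dimer_mean_complex(f0, dt, fp[1], fp[2], lambda)
  fl <- dimer_fluxes(f0, dt, fp[1], fp[2], lambda, d1, d2)
  # n1 lineage: free loss = consumed; complex gain = delta f; complex-side
  # degradation of the n1 member = d1 * fbar * dt
  expect_equal(unname(fl[1]), (fdt - f0) + d1 * fbar * dt, tolerance = 1e-9)
  expect_equal(unname(fl[2]), (fdt - f0) + d2 * fbar * dt, tolerance = 1e-9)
})

test_that("the flux-change criterion fires only on large jumps", {
  expect_null(check_flux_criterion(0.1, 0.15, 10))
  expect_match(check_flux_criterion(0.1, 0.3, 10), "reduce dt")
})
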