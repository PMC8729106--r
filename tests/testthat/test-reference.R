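test_that("gillespie birth-death reaches the Poisson stationary law", {
  # nu = 1, delta = 0.02: stationary Poisson(50)
  sys <- reaction_system(
    species = "X",
    stoich = matrix(c(1L, -1L), 1, 2),
    orders = matrix(c(0L, 1L), 1, 2),
    rates = c(1, 0.02))
  tr <- gillespie(sys, c(X = 0), t_end = 2e5, seed = 42, record_dt = 5)
  x <- tr$abundances[tr$times > 2e4, "X"]
  lambda <- 50
  # chi-square against Poisson(50) on thinned (weakly correlated) samples
  xs <- x[seq(1, length(x), by = 20)]          # 100 s apart = 2 lifetimes
  brk <- c(-Inf, seq(35, 65, by = 5), Inf)
  obs <- table(cut(xs, brk))
  pr <- diff(stats::ppois(c(-Inf, seq(35, 65, by = 5), Inf), lambda))
  ct <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = pr))
  expect_gt(ct$p.value, 0.01)
  expect_lt(abs(mean(x) - 50), 3 * stats::sd(x) / sqrt(length(xs)))
})

test_that("gillespie two-state gene matches the telegraph mean; dead systems stay flat", {
  lam <- 0.005; mu <- 0.01; nu <- 0.4; delta <- 0.004
  sys <- reaction_system(
    species = c("Goff", "Gon", "X"),
    stoich = cbind(c(-1L, 1L, 0L), c(1L, -1L, 0L), c(0L, 0L, 1L),
                   c(0L, 0L, -1L)),
    orders = cbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 1L, 0L),
                   c(0L, 0L, 1L)),
    rates = c(lam, mu, nu, delta))
  tr <- gillespie(sys, c(Goff = 1, Gon = 0, X = 0), t_end = 8e5, seed = 7,
                  record_dt = 50)
  x <- tr$abundances[tr$times > 1e5, "X"]
  mean_expected <- lam / (lam + mu) * nu / delta
  tau <- 1 / (lam + mu)                         # slowest correlation time
  n_eff <- (8e5 - 1e5) / (2 * tau)
  expect_lt(abs(mean(x) - mean_expected), 3 * stats::sd(x) / sqrt(n_eff))
  # zero propensities: trajectory is flat and fast-forwards
  dead <- reaction_system("X", matrix(1L, 1, 1), matrix(0L, 1, 1), rates = 0)
  trd <- gillespie(dead, c(X = 5), t_end = 100, seed = 1, record_dt = 10)
  expect_equal(unname(trd$abundances[, "X"]), rep(5, 11))
})

test_that("the cascade system reduces to independent activated genes without repression", {
  p <- cascade_params("fast")
  p$lambda_R0 <- 0                 # repression off
  cs <- build_cascade_system(p, n_links = 2)
  expect_equal(nrow(cs$system$stoich), 2 + 2 * 4)  # A, R0 + 4 species/link
  tr <- gillespie(cs$system, cs$x0, t_end = 3e5, seed = 5, record_dt = 50)
  lam_eff <- p$lambda_A0 * p$activator_level
  mean_expected <- lam_eff / (lam_eff + p$mu_A) * p$nu / p$delta
  for (sp in c("R1", "R2")) {
    x <- tr$abundances[tr$times > 5e4, sp]
    n_eff <- 2.5e5 / (2 / p$delta)
    expect_lt(abs(mean(x) - mean_expected), 3 * stats::sd(x) / sqrt(n_eff))
  }
})

test_that("feedback systems honour their structural switches", {
  p <- feedback_params("positive")
  p$lambda_A0 <- 0; p$lambda_b <- 0      # gene can never activate
  fs <- build_feedback_system("positive", p)
  tr <- gillespie(fs$system, fs$x0, 2e4, seed = 2, record_dt = 100)
  expect_equal(tail(tr$abundances[, "A"] + tr$abundances[, "EA"], 1)[[1]], 0)

  pn <- feedback_params("negative")
  pn$lambda_R0 <- 0                      # constitutive, unrepressed
  pn$lambda_E <- 0                       # spontaneous degradation only
  fsn <- build_feedback_system("negative", pn)
  trn <- gillespie(fsn$system, fsn$x0, 6e5, seed = 3, record_dt = 100)
  x <- trn$abundances[trn$times > 2e5, "R"]
  expect_lt(abs(mean(x) - pn$nu / pn$delta),
            3 * stats::sd(x) / sqrt(4e5 * pn$delta / 2))
})

test_that("the assembled mean-field ODE vanishes at its own steady state", {
  net <- cascade_network(cascade_params("slow"))
  sys <- assemble_ode(net)
  sol <- deSolve::ode(y = sys$y0, times = c(0, 5e5), func = sys$rhs,
                      parms = NULL, rtol = 1e-10, atol = 1e-10)
  y_ss <- sol[2, -1]
  dy <- sys$rhs(5e5, y_ss, NULL)[[1]]
  free <- !(sys$state_names %in% c("A", "R0"))
  expect_lt(max(abs(dy[free])), 1e-9)
  # single constitutive gene: rhs is nu - delta n
  one <- constitutive_gene_net(nu = 0.3, delta = 0.02)
  s1 <- assemble_ode(one)
  expect_equal(s1$rhs(0, c(X = 5), NULL)[[1]][1], 0.3 - 0.02 * 5,
               tolerance = 1e-12)
})

test_that("the two-enzyme loop RHS matches the coupled rate equations term by term", {
  net <- enzyme_loop_network()
  sys <- assemble_ode(net)
  p <- list(nu_src = 0.2, delta = 1e-3, lambda1 = 2e-3, mu1 = 0.05,
            nu1 = 0.05, F_level = 30, lambda2 = 2e-3, mu2 = 0.05,
            nu2 = 0.05, G_level = 20)
  set.seed(31)
  for (rep in 1:5) {
    y <- sys$y0
    y[c("N", "M")] <- stats::runif(2, 50, 100)
    y[c("NF", "MG")] <- stats::runif(2, 0, 15)
    dy <- sys$rhs(0, y, NULL)[[1]]
    names(dy) <- sys$state_names
    fN <- y[["NF"]]; fM <- y[["MG"]]
    expect_equal(dy[["N"]],
                 p$nu_src - p$delta * y[["N"]] - p$nu1 * fN + p$nu2 * fM,
                 tolerance = 1e-12)
    expect_equal(dy[["M"]],
                 -p$delta * y[["M"]] + p$nu1 * fN - p$nu2 * fM,
                 tolerance = 1e-12)
    expect_equal(dy[["NF"]],
                 p$lambda1 * (y[["N"]] - fN) * (p$F_level - fN) -
                   (p$delta + p$mu1 + p$nu1) * fN,
                 tolerance = 1e-12)
  }
})
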