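# Closed-form advancement of bimolecular reaction elements over one
# synchronization step.
#
# The complex abundance f of a (hetero/homo) dimer or enzyme-substrate
# pair obeys a Riccati-type ODE with constant totals and incoming flux
# frozen over the step,
#     df/dt = lambda (N1 - f)(N2 - f) - D f + j_in,   D = d1 + d2 + mu,
# which integrates in closed form between its two fixed points.  Flux
# bookkeeping uses the time-averaged complex occupancy over the step.

#' Fixed points of the complex abundance
#'
#' Real roots \code{f1 <= f2} of
#' \code{lambda (N1-f)(N2-f) - (d1+d2+mu) f + j_in = 0}; the smaller root
#' \code{f1} is the stable one.
#'
#' @param N1,N2 total abundances of the two binding partners
#' @param lambda association rate, > 0
#' @param mu complex dissociation rate
#' @param d1,d2 degradation rates of the two partners (also acting on the
#'   complex)
#' @param j_in incoming flux of complex from other elements (molecules/s)
#' @return numeric vector \code{c(f1, f2)}
#' @export
dimer_fixed_points <- function(N1, N2, lambda, mu, d1, d2, j_in = 0) {
  stopifnot(lambda > 0)
  D <- d1 + d2 + mu
  b <- lambda * (N1 + N2) + D
  cc <- lambda * N1 * N2 + j_in
  disc <- b^2 - 4 * lambda * cc
  if (disc < 0)
    stop("no real fixed point: incoming flux exceeds the element's capacity")
  q <- b + sqrt(disc)
  f2 <- q / (2 * lambda)
  f1 <- if (q > 0) 2 * cc / q else f2
  c(f1, f2)
}

# relative gap below which the two fixed points are treated as a double root
.dimer_degenerate <- function(f1, f2) {
  (f2 - f1) < 1e-9 * max(1, abs(f2))
}

#' Closed-form complex trajectory between its fixed points
#'
#' \code{f(t) = f1 + (f2-f1) u/(1+u)} with
#' \code{u = (f0-f1)/(f2-f0) exp(-k t)}, \code{k = lambda (f2-f1)}.  For a
#' (near-)double root the exact degenerate solution
#' \code{f1 + (f0-f1)/(1 + lambda (f0-f1) t)} is used.  Starting exactly at
#' the unstable root returns \code{f2}.
#'
#' @param f0 complex abundance at the start of the step
#' @param dt step length (s)
#' @param f1,f2 fixed points from \code{\link{dimer_fixed_points}}
#' @param lambda association rate
#' @return complex abundance after \code{dt}
#' @export
dimer_advance <- function(f0, dt, f1, f2, lambda) {
  stopifnot(f0 >= 0)
  if (.dimer_degenerate(f1, f2))
    return(f1 + (f0 - f1) / (1 + lambda * (f0 - f1) * dt))
  if (f0 == f2) return(f2)
  u <- (f0 - f1) / (f2 - f0) * exp(-lambda * (f2 - f1) * dt)
  f1 + (f2 - f1) * u / (1 + u)
}

#' Time-averaged complex occupancy over a step
#'
#' Closed-form step average of the \code{\link{dimer_advance}} trajectory,
#' \code{fbar = f1 + log((1+u0)/(1+u0 exp(-k dt))) / (lambda dt)}.
#'
#' @inheritParams dimer_advance
#' @return mean complex abundance over \code{[0, dt]}
#' @export
dimer_mean_complex <- function(f0, dt, f1, f2, lambda) {
  if (dt <= 0) return(f0)
  if (.dimer_degenerate(f1, f2))
    return(f1 + log1p(lambda * (f0 - f1) * dt) / (lambda * dt))
  if (f0 == f2) return(f2)
  u0 <- (f0 - f1) / (f2 - f0)
  k <- lambda * (f2 - f1)
  f1 + log((1 + u0) / (1 + u0 * exp(-k * dt))) / (lambda * dt)
}

#' Substrate amounts consumed by a dimerization element over a step
#'
#' Integrates the monomer uptake (association minus dissociation and minus
#' release through degradation of the partner inside the complex) in closed
#' form.  For monomer i the integrand equals \code{df/dt + d_i f}, so the
#' consumed amount is \code{(f(dt) - f0) + d_i fbar dt}.
#'
#' @inheritParams dimer_advance
#' @param d1,d2 monomer degradation rates
#' @return numeric vector \code{c(consumed_n1, consumed_n2)} (molecules)
#' @export
dimer_fluxes <- function(f0, dt, f1, f2, lambda, d1, d2) {
  fdt <- dimer_advance(f0, dt, f1, f2, lambda)
  fbar <- dimer_mean_complex(f0, dt, f1, f2, lambda)
  df <- fdt - f0
  c(consumed_n1 = df + d1 * fbar * dt,
    consumed_n2 = df + d2 * fbar * dt)
}

# Linear relaxation df/dt = j - D f, exact solution and step average.
.linear_relax <- function(f0, D, j, dt) {
  if (D <= 0) {
    f <- f0 + j * dt
    return(list(f = f, fbar = f0 + j * dt / 2))
  }
  e <- exp(-D * dt)
  fs <- j / D
  list(f = fs + (f0 - fs) * e,
       fbar = fs + (f0 - fs) * (1 - e) / (D * dt))
}

#' Advance a homo-dimerization element
#'
#' The homodimer ODE \code{df/dt = lambda (N-2f)^2 - (2 d1 + mu) f + j_in}
#' maps onto the hetero-dimer solution through the substitution
#' \code{lambda -> 4 lambda, N1 = N2 = N/2} (the incoming dimer flux
#' enters unchanged; scaling it would alter the homodimer ODE itself).
#' The monomer consumption is reported doubled, two monomers per dimer.
#' With \code{lambda = 0} the complex relaxes linearly towards
#' \code{j_in/(2 d1 + mu)}.
#'
#' @param f0 dimer abundance at step start
#' @param N total monomer abundance
#' @param lambda association rate
#' @param mu dimer dissociation rate
#' @param d1 monomer degradation rate
#' @param j_in incoming dimer flux (molecules/s)
#' @param dt step length
#' @return list with \code{f} (dimer after the step), \code{fbar} (step
#'   average) and \code{consumed_monomer} (molecules taken from the free
#'   monomer pool)
#' @export
homodimer_advance <- function(f0, N, lambda, mu, d1, j_in = 0, dt) {
  if (lambda == 0) {
    lr <- .linear_relax(f0, 2 * d1 + mu, j_in, dt)
    return(list(f = lr$f, fbar = lr$fbar,
                consumed_monomer = 2 * ((lr$f - f0) + d1 * lr$fbar * dt)))
  }
  fp <- dimer_fixed_points(N / 2, N / 2, 4 * lambda, mu, d1, d1, j_in)
  f <- dimer_advance(f0, dt, fp[1], fp[2], 4 * lambda)
  fbar <- dimer_mean_complex(f0, dt, fp[1], fp[2], 4 * lambda)
  list(f = f, fbar = fbar,
       consumed_monomer = 2 * ((f - f0) + d1 * fbar * dt))
}

#' Advance an enzyme-turnover element
#'
#' The enzyme-substrate complex follows the dimer machinery with the
#' substrate degradation rate augmented by the catalytic rate
#' (\code{d1 -> d1 + nu}); the product follows the linear closed form
#' \code{m(dt) = m0 exp(-d3 dt) + (nu fbar + j_in)/d3 (1 - exp(-d3 dt))}
#' driven by the step-averaged complex occupancy.
#'
#' @param state list with \code{f} (complex) and \code{m} (product)
#' @param N_sub total substrate abundance (free plus complexed)
#' @param N_enz total enzyme abundance
#' @param lambda,mu association/dissociation rates
#' @param nu catalytic rate
#' @param deltas degradation rates \code{c(d1, d2, d3)} of substrate,
#'   enzyme and product
#' @param j_in_complex incoming complex flux (molecules/s)
#' @param j_in_product incoming product flux (molecules/s)
#' @param dt step length
#' @param track_product set \code{FALSE} when the catalysed output is a
#'   sink (enzymatic degradation)
#' @return list with \code{f}, \code{fbar}, \code{m} and
#'   \code{catalysed} (molecules converted during the step)
#' @export
enzyme_advance <- function(state, N_sub, N_enz, lambda, mu, nu, deltas,
                           j_in_complex = 0, j_in_product = 0, dt,
                           track_product = TRUE) {
  d1 <- deltas[1] + nu; d2 <- deltas[2]; d3 <- deltas[3]
  if (lambda == 0) {
    lr <- .linear_relax(state$f, d1 + d2 + mu, j_in_complex, dt)
    f <- lr$f; fbar <- lr$fbar
  } else {
    fp <- dimer_fixed_points(N_sub, N_enz, lambda, mu, d1, d2, j_in_complex)
    f <- dimer_advance(state$f, dt, fp[1], fp[2], lambda)
    fbar <- dimer_mean_complex(state$f, dt, fp[1], fp[2], lambda)
  }
  m <- state$m
  if (track_product) {
    if (d3 <= 0) stop("product degradation rate d3 must be > 0")
    e <- exp(-d3 * dt)
    m <- state$m * e + (nu * fbar + j_in_product) / d3 * (1 - e)
  }
  list(f = f, fbar = fbar, m = m, catalysed = nu * fbar * dt)
}

#' Check the flux-change criterion for a reaction element
#'
#' The synchronization scheme assumes fluxes change slowly between steps;
#' a warning record is returned when \code{|dj| * dt >= 1}.
#'
#' @param j_prev,j_curr reported flux in the previous and current step
#' @param dt synchronization step
#' @return \code{NULL}, or a character string describing the violation
#' @export
check_flux_criterion <- function(j_prev, j_curr, dt) {
  if (abs(j_curr - j_prev) * dt >= 1)
    sprintf("|dj|*dt = %.3g >= 1; reduce dt", abs(j_curr - j_prev) * dt)
  else NULL
}
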