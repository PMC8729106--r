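# Independent reference solvers: an exact Gillespie direct-method
# simulator for explicit reaction systems, and a global mean-field ODE
# assembled from a network specification.  Both serve as oracles for the
# synchronized hybrid engine.

#' Define an explicit stochastic reaction system
#'
#' @param species character vector of species names
#' @param stoich integer matrix (species x reactions) of net changes
#' @param orders integer matrix (species x reactions) of reactant
#'   multiplicities (0, 1, 2); propensities are mass-action,
#'   \code{k * prod(x^order)} with combinatorial counting for order 2
#' @param rates numeric vector of rate constants, one per reaction
#' @return an object of class \code{reaction_system}
#' @export
reaction_system <- function(species, stoich, orders, rates) {
  stopifnot(nrow(stoich) == length(species), nrow(orders) == length(species),
            ncol(stoich) == length(rates), ncol(orders) == length(rates),
            all(rates >= 0))
  structure(list(species = species, stoich = stoich, orders = orders,
                 rates = rates),
            class = "reaction_system")
}

#' Exact Gillespie simulation of a reaction system
#'
#' Direct-method sample path: the time to the next event is exponential in
#' the total propensity and the reaction identity is drawn from the
#' relative propensities.  The state is recorded on a uniform grid.  When
#' every propensity vanishes the trajectory is fast-forwarded to
#' \code{t_end}.
#'
#' @param system a \code{\link{reaction_system}}
#' @param x0 named or ordered initial copy numbers (non-negative integers)
#' @param t_end total simulated time (s)
#' @param seed integer RNG seed
#' @param record_dt sampling interval of the output grid (s)
#' @return a \code{grn_trajectory}
#' @export
gillespie <- function(system, x0, t_end, seed = 1L, record_dt = t_end / 1000) {
  stopifnot(inherits(system, "reaction_system"))
  if (!is.null(names(x0))) x0 <- x0[system$species]
  stopifnot(length(x0) == length(system$species), all(x0 >= 0))
  set.seed(seed)
  res <- .gillespie_core(system$stoich, system$orders, system$rates,
                         as.numeric(x0), t_end, record_dt)
  ab <- res$abundances
  colnames(ab) <- system$species
  structure(list(times = res$times, abundances = ab,
                 warnings = data.frame(time = numeric(0),
                                       element = character(0),
                                       criterion = character(0)),
                 config = list(seed = seed, events = res$events)),
            class = "grn_trajectory")
}

# small helper to accumulate a reaction system column by column
.rs_builder <- function(species) {
  env <- new.env()
  env$species <- species
  env$sto <- list(); env$ord <- list(); env$k <- numeric(0)
  env$add <- function(rate, consume = character(0), produce = character(0)) {
    s <- integer(length(env$species)); names(s) <- env$species
    o <- s
    for (c1 in consume) { s[c1] <- s[c1] - 1L; o[c1] <- o[c1] + 1L }
    for (p1 in produce) s[p1] <- s[p1] + 1L
    env$sto[[length(env$sto) + 1L]] <- s
    env$ord[[length(env$ord) + 1L]] <- o
    env$k <- c(env$k, rate)
  }
  env$build <- function() reaction_system(
    env$species, do.call(cbind, env$sto), do.call(cbind, env$ord), env$k)
  env
}

#' Explicit reaction system of the repressive four-gene cascade
#'
#' Each link n has a three-state promoter (repressed / empty / active): a
#' shared constitutive activator A binds and activates it, the previous
#' link's product (or the input species R0 for link 1) represses it, and
#' the active promoter produces the repressor of the next link.
#'
#' @param params parameter list as returned by
#'   \code{\link{cascade_params}}
#' @param n_links number of links (default 4)
#' @return list with \code{system} (a \code{\link{reaction_system}}) and
#'   \code{x0} (initial state with the input and activator levels)
#' @export
build_cascade_system <- function(params = cascade_params(), n_links = 4L) {
  sp <- c("A", "R0")
  for (n in seq_len(n_links))
    sp <- c(sp, sprintf(c("P%d", "P%dA", "P%dR", "R%d"), n))
  b <- .rs_builder(sp)
  for (n in seq_len(n_links)) {
    P <- sprintf("P%d", n); PA <- sprintf("P%dA", n); PR <- sprintf("P%dR", n)
    Rn <- sprintf("R%d", n); Rprev <- sprintf("R%d", n - 1L)
    b$add(params$lambda_A0, c(P, "A"), PA)
    b$add(params$mu_A, PA, c(P, "A"))
    b$add(params$lambda_R0, c(P, Rprev), PR)
    b$add(params$mu_R, PR, c(P, Rprev))
    b$add(params$nu, PA, c(PA, Rn))
    b$add(params$delta, Rn, character(0))
  }
  x0 <- integer(length(sp)); names(x0) <- sp
  x0["A"] <- params$activator_level
  x0["R0"] <- params$input_level
  x0[sprintf("P%d", seq_len(n_links))] <- 1L
  list(system = b$build(), x0 = x0)
}

#' Explicit reaction systems of the autoregulatory feedback benchmarks
#'
#' \code{kind = "positive"}: a gene activated by its own product A through
#' one binding site, with a weak constitutive (basal) site, transcription
#' to RNA, maturation of RNA to A, and degradation of A both spontaneous
#' and catalysed by an enzyme E.  \code{kind = "negative"}: a
#' constitutively transcribing gene repressed by its own product R, with
#' the same RNA maturation and enzyme-assisted degradation.
#'
#' @param kind \code{"positive"} or \code{"negative"}
#' @param params parameter list as returned by
#'   \code{\link{feedback_params}}
#' @return list with \code{system} and \code{x0}
#' @export
build_feedback_system <- function(kind = c("positive", "negative"),
                                  params = feedback_params(kind)) {
  kind <- match.arg(kind)
  if (kind == "positive") {
    # promoter states: site 1 = product A, site 2 = basal activator
    sp <- c("P00", "P10", "P01", "P11", "RNA", "A", "E", "EA")
    b <- .rs_builder(sp)
    b$add(params$lambda_A0, c("P00", "A"), "P10")
    b$add(params$mu_A, "P10", c("P00", "A"))
    b$add(params$lambda_A0, c("P01", "A"), "P11")
    b$add(params$mu_A, "P11", c("P01", "A"))
    b$add(params$lambda_b, "P00", "P01")
    b$add(params$mu_b, "P01", "P00")
    b$add(params$lambda_b, "P10", "P11")
    b$add(params$mu_b, "P11", "P10")
    for (on in c("P10", "P01", "P11")) b$add(params$nu, on, c(on, "RNA"))
    b$add(params$beta, "RNA", "A")
    b$add(params$lambda_E, c("E", "A"), "EA")
    b$add(params$mu_E, "EA", c("E", "A"))
    b$add(params$nu_E, "EA", "E")
    b$add(params$delta, "A", character(0))
    x0 <- integer(length(sp)); names(x0) <- sp
    x0["P00"] <- 1L
    x0["E"] <- params$enzyme_level
    x0["A"] <- params$init_product
  } else {
    nb <- length(params$beta)
    rna <- sprintf("RNA%d", seq_len(nb))
    sp <- c("P", "PR", rna, "R", "E", "ER")
    b <- .rs_builder(sp)
    b$add(params$lambda_R0, c("P", "R"), "PR")
    b$add(params$mu_R, "PR", c("P", "R"))
    b$add(params$nu, "P", c("P", rna[1]))
    for (k in seq_len(nb))                     # maturation chain
      b$add(params$beta[k], rna[k], if (k < nb) rna[k + 1] else "R")
    b$add(params$lambda_E, c("E", "R"), "ER")
    b$add(params$mu_E, "ER", c("E", "R"))
    b$add(params$nu_E, "ER", "E")
    b$add(params$delta, "R", character(0))
    x0 <- integer(length(sp)); names(x0) <- sp
    x0["P"] <- 1L
    x0["E"] <- params$enzyme_level
    x0["R"] <- params$init_product
  }
  list(system = b$build(), x0 = x0)
}

# --- mean-field ODE --------------------------------------------------------

#' Assemble the global mean-field ODE of a network
#'
#' Builds the right-hand side of the network-wide deterministic rate
#' equations: genes contribute \code{p_on(x) nu - delta n} (with chain
#' stages as extra state variables), reaction elements contribute their
#' full mass-action complex dynamics without any freezing, and inputs are
#' evaluated from their time profile.
#'
#' @param spec a \code{\link{network_spec}}
#' @return list with \code{rhs} (a deSolve-style derivative function),
#'   \code{y0} (initial state) and \code{state_names}
#' @export
assemble_ode <- function(spec) {
  net <- .compile_network(spec)
  ns <- net$ns
  # chain stages appended after the species block
  chain_of <- list(); extra <- 0L
  for (gi in seq_along(net$genes)) {
    nb <- length(net$genes[[gi]]$spec$betas)
    if (nb > 0) { chain_of[[gi]] <- ns + extra + seq_len(nb); extra <- extra + nb }
    else chain_of[gi] <- list(NULL)
  }
  y0 <- numeric(ns + extra)
  nm <- c(net$species$name, rep("", extra))
  for (gi in seq_along(net$genes)) {
    ci <- chain_of[[gi]]
    if (!is.null(ci))
      nm[ci] <- sprintf("%s.c%d", net$genes[[gi]]$spec$product, seq_along(ci))
  }
  names(y0) <- nm
  for (ii in net$inputs) y0[ii$sp] <- evaluate_input(ii$spec, 0)
  for (g in net$genes) y0[g$product] <- g$spec$init
  for (s in names(spec$species_init)) y0[s] <- spec$species_init[[s]]
  for (r in net$reactions) {
    y0[r$cx] <- r$spec$init_complex
    if (!is.na(r$prod)) y0[r$prod] <- max(y0[r$prod], r$spec$init_product)
  }

  input_idx <- vapply(net$inputs, `[[`, integer(1), "sp")

  rhs <- function(t, y, parms) {
    x <- y[seq_len(ns)]
    for (k in seq_along(net$inputs))
      x[input_idx[k]] <- evaluate_input(net$inputs[[k]]$spec, t)
    dy <- numeric(length(y))
    xn <- x; names(xn) <- net$species$name

    for (gi in seq_along(net$genes)) {
      g <- net$genes[[gi]]
      p_on <- promoter_rates(g$spec, xn)$p_on
      ci <- chain_of[[gi]]
      if (is.null(ci)) {
        dy[g$product] <- dy[g$product] + p_on * g$spec$nu -
          g$spec$delta * x[g$product]
      } else {
        betas <- g$spec$betas
        cvals <- y[ci]
        dy[ci[1L]] <- p_on * g$spec$nu - betas[1L] * cvals[1L]
        if (length(ci) > 1L)
          for (k in 2:length(ci))
            dy[ci[k]] <- betas[k - 1L] * cvals[k - 1L] - betas[k] * cvals[k]
        dy[g$product] <- dy[g$product] +
          betas[length(betas)] * cvals[length(cvals)] -
          g$spec$delta * x[g$product]
      }
    }

    for (r in net$reactions) {
      rs <- r$spec; f <- x[r$cx]
      if (rs$kind == "hetero_dimer") {
        n1 <- x[r$sub[1]]; n2 <- x[r$sub[2]]
        assoc <- rs$lambda * n1 * n2
        dy[r$cx] <- dy[r$cx] + assoc - (sum(rs$deltas) + rs$mu) * f
        dy[r$sub[1]] <- dy[r$sub[1]] - assoc + (rs$mu + rs$deltas[2]) * f
        dy[r$sub[2]] <- dy[r$sub[2]] - assoc + (rs$mu + rs$deltas[1]) * f
      } else if (rs$kind == "homo_dimer") {
        nfree <- x[r$sub[1]]
        assoc <- rs$lambda * nfree * nfree
        dy[r$cx] <- dy[r$cx] + assoc - (2 * rs$deltas[1] + rs$mu) * f
        # association consumes 2 monomers; dissociation returns 2; death of
        # one in-complex monomer (rate 2 d1 f) releases the survivor
        dy[r$sub[1]] <- dy[r$sub[1]] - 2 * assoc + 2 * rs$mu * f +
          2 * rs$deltas[1] * f
      } else {
        Nsub <- x[r$sub[1]]; Nenz <- x[r$enz]
        assoc <- rs$lambda * pmax(Nsub - f, 0) * pmax(Nenz - f, 0)
        dy[r$cx] <- dy[r$cx] + assoc -
          (rs$deltas[1] + rs$nu + rs$deltas[2] + rs$mu) * f
        # substrate pool is the total (free + complexed): only catalysis
        # removes from it (its own delta is applied by the owner below)
        dy[r$sub[1]] <- dy[r$sub[1]] - rs$nu * f
        if (!is.na(r$prod)) dy[r$prod] <- dy[r$prod] + rs$nu * f
      }
    }

    for (s in which(net$owner == "pool"))
      dy[s] <- dy[s] - net$pool_delta[s] * x[s]
    for (r in net$reactions)
      if (!is.na(r$prod) && net$owner[r$prod] == "reaction_product")
        dy[r$prod] <- dy[r$prod] - rs_delta3(r) * x[r$prod]
    dy[input_idx] <- 0
    list(dy)
  }
  list(rhs = rhs, y0 = y0, state_names = nm, species = net$species$name)
}

rs_delta3 <- function(r) r$spec$deltas[3]

#' Solve the global mean-field ODE on a time grid
#'
#' @param spec a \code{\link{network_spec}}
#' @param times output time grid (s)
#' @param ... passed to \code{\link[deSolve]{ode}}
#' @return a \code{grn_trajectory} restricted to the network species
#' @export
ode_oracle <- function(spec, times, ...) {
  sys <- assemble_ode(spec)
  sol <- deSolve::ode(y = sys$y0, times = times, func = sys$rhs,
                      parms = NULL, rtol = 1e-8, atol = 1e-8, ...)
  ab <- sol[, match(sys$species, sys$state_names) + 1L, drop = FALSE]
  colnames(ab) <- sys$species
  structure(list(times = sol[, 1L], abundances = ab,
                 warnings = data.frame(time = numeric(0),
                                       element = character(0),
                                       criterion = character(0)),
                 config = NULL),
            class = "grn_trajectory")
}
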