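# The synchronization main loop.
#
# Per step dt every element advances in isolation using the species
# abundances and fluxes frozen at the previous synchronization point; the
# new abundances and the fluxes generated during the step are exchanged
# only at the step boundary.  Ownership is unique: every species is
# written by exactly one element (its producer), all other elements
# interact with it through reported fluxes that take effect one step
# later.

#' Evaluate an input element's profile at a time point
#'
#' Constant inputs return the amplitude; rectangular inputs alternate
#' between baseline + amplitude (on-fraction \code{duty} of each period)
#' and baseline; sinusoidal inputs follow
#' \code{baseline + amplitude * sin(2 pi t / period + phase)}.  Values are
#' clipped at zero.
#'
#' @param spec an \code{\link{input_spec}}
#' @param t time in seconds, >= 0
#' @return molecule number at time \code{t}
#' @export
evaluate_input <- function(spec, t) {
  v <- switch(spec$profile,
    constant = rep(spec$amplitude, length(t)),
    rectangular = {
      ph <- ((t - spec$phase) %% spec$period) / spec$period
      spec$baseline + spec$amplitude * (ph < spec$duty)
    },
    sinusoidal = spec$baseline +
      spec$amplitude * sin(2 * pi * t / spec$period + spec$phase))
  pmax(v, 0)
}

# deterministic element-wise RNG stream: every stochastic element draws
# from a seed derived from (master seed, element name, step), so element
# evaluation order and the presence of other elements do not perturb it
.name_hash <- function(name) {
  h <- 0
  for (v in utf8ToInt(name)) h <- (h * 131 + v) %% 2147483647
  h
}
.element_seed <- function(master, elem_hash, step) {
  a <- (elem_hash * 1103515245 + 12345) %% 2147483647
  b <- (step * 69069 + elem_hash * 97) %% 2147483647
  as.integer((master + a + b) %% 2147483647)
}

# effective promoter rates without the list churn of the public
# constructors; used only inside the main loop (same formulas as
# promoter_logic.R)
.gene_rates_fast <- function(g, n) {
  lam <- g$act_l0 * n[g$act_idx]
  mu <- g$act_mu
  logic <- g$spec$logic
  if (logic == "single") {
    lambda_eff <- lam[1L]; mu_eff <- mu[1L]
  } else if (logic == "and") {
    mu_eff <- sum(mu)
    p <- prod(lam / (lam + mu))
    lambda_eff <- p / (1 - p) * mu_eff
  } else if (logic == "or") {
    lambda_eff <- sum(lam)
    if (lambda_eff == 0) {
      mu_eff <- sum(mu)
    } else {
      p <- 1 - prod(mu / (lam + mu))
      mu_eff <- lambda_eff * (1 - p) / p
    }
  } else {                                   # constitutive
    rl <- g$rep_l0 * n[g$rep_idx]
    mu_eff <- sum(rl)
    if (length(rl) == 0L || mu_eff == 0) {
      lambda_eff <- 1e12; mu_eff <- 1e-12
    } else {
      p <- prod(1 / (1 + rl / g$rep_mu))
      lambda_eff <- p / (1 - p) * mu_eff
    }
    return(list(lambda_eff = lambda_eff, mu_eff = mu_eff,
                p_on = lambda_eff / (lambda_eff + mu_eff)))
  }
  if (length(g$rep_idx)) {
    rl <- g$rep_l0 * n[g$rep_idx]
    lambda_eff <- lambda_eff * prod(1 / (1 + rl / g$rep_mu))
  }
  list(lambda_eff = lambda_eff, mu_eff = mu_eff,
       p_on = lambda_eff / (lambda_eff + mu_eff))
}

# linear production/decay step n' = n e^(-d tau) + p/d (1 - e^(-d tau)),
# exact for constant production rate p (may be negative when it encodes a
# net outgoing flux); d = 0 handled exactly
.lin_step <- function(n, p, d, tau) {
  if (d <= 0) return(n + p * tau)
  e <- exp(-d * tau)
  n * e + p / d * (1 - e)
}

# --- compilation -----------------------------------------------------------

# Resolve species indices, ownership and pool decay rates once, before the
# main loop.
.compile_network <- function(spec) {
  diag <- validate_network(spec)
  if (length(diag))
    stop("invalid network:\n  ", paste(diag, collapse = "\n  "))
  sp <- network_species(spec)
  ns <- nrow(sp)
  idx <- function(name) match(name, sp$name)

  genes <- lapply(seq_along(spec$genes), function(gi) {
    g <- spec$genes[[gi]]
    role <- vapply(g$bindings, `[[`, character(1), "role")
    act <- which(role == "activator"); rp <- which(role == "repressor")
    bidx <- vapply(g$bindings, function(b) idx(b$tf), integer(1))
    list(spec = g, product = idx(g$product),
         act_idx = bidx[act],
         act_l0 = vapply(g$bindings[act], `[[`, numeric(1), "lambda0"),
         act_mu = vapply(g$bindings[act], `[[`, numeric(1), "mu"),
         rep_idx = bidx[rp],
         rep_l0 = vapply(g$bindings[rp], `[[`, numeric(1), "lambda0"),
         rep_mu = vapply(g$bindings[rp], `[[`, numeric(1), "mu"),
         hash = .name_hash(g$product),
         chain_rates = if (length(g$betas)) c(g$betas, g$delta) else NULL)
  })
  reactions <- lapply(spec$reactions, function(r) {
    list(spec = r,
         sub = vapply(r$substrates, idx, integer(1)),
         enz = if (is.null(r$enzyme)) NA_integer_ else idx(r$enzyme),
         prod = if (is.na(r$product)) NA_integer_ else idx(r$product),
         cx = idx(r$complex))
  })
  inputs <- lapply(spec$inputs, function(i) list(spec = i, sp = idx(i$species)))

  owner <- rep("pool", ns)
  owner[vapply(inputs, `[[`, integer(1), "sp")] <- "input"
  owner[vapply(genes, `[[`, integer(1), "product")] <- "gene"
  for (r in reactions) {
    owner[r$cx] <- "reaction"
    if (!is.na(r$prod) && owner[r$prod] == "pool") owner[r$prod] <- "reaction_product"
  }
  # pool decay rates come from the reactions that reference each pool
  pool_delta <- rep(0, ns)
  for (r in reactions) {
    rs <- r$spec
    if (rs$kind == "enzyme") {
      if (owner[r$sub[1]] == "pool") pool_delta[r$sub[1]] <- rs$deltas[1]
      if (owner[r$enz] == "pool") pool_delta[r$enz] <- rs$deltas[2]
    } else {
      for (k in seq_along(r$sub))
        if (owner[r$sub[k]] == "pool") pool_delta[r$sub[k]] <- rs$deltas[k]
    }
  }
  list(species = sp, ns = ns, inputs = inputs, genes = genes,
       reactions = reactions, owner = owner, pool_delta = pool_delta)
}

# --- main loop -------------------------------------------------------------

#' Run a hybrid synchronized simulation
#'
#' Advances the network from t = 0 to \code{cfg$t_end} in synchronization
#' steps of \code{cfg$dt}.  Scenario 1 treats promoter activity and
#' product birth/death deterministically; scenario 2 draws stochastic
#' promoter on/off switching; scenario 3 additionally draws discrete
#' Poisson birth and binomial death events of gene products.  Reaction
#' elements are always advanced with their deterministic closed forms.
#' Identical \code{(spec, cfg)} give identical trajectories.
#'
#' @param spec a \code{\link{network_spec}} that passes
#'   \code{\link{validate_network}}
#' @param cfg a \code{\link{sim_config}}
#' @return an object of class \code{grn_trajectory}: list with
#'   \code{times}, \code{abundances} (time x species matrix) and
#'   \code{warnings} (data.frame time/element/criterion)
#' @export
run_network <- function(spec, cfg) {
  stopifnot(inherits(spec, "network_spec"), inherits(cfg, "sim_config"))
  net <- .compile_network(spec)
  ns <- net$ns
  dt <- cfg$dt
  nsteps <- floor(cfg$t_end / dt + 1e-9)
  scen <- cfg$scenario

  # state
  n <- numeric(ns)
  names(n) <- net$species$name
  for (ii in net$inputs) n[ii$sp] <- evaluate_input(ii$spec, 0)
  for (g in net$genes) n[g$product] <- g$spec$init
  for (s in names(spec$species_init)) n[s] <- spec$species_init[[s]]
  for (r in net$reactions) {
    n[r$cx] <- r$spec$init_complex
    if (!is.na(r$prod)) n[r$prod] <- max(n[r$prod], r$spec$init_product)
  }
  flux <- numeric(ns)                 # net reported flux, frozen per step
  gstate <- lapply(net$genes, function(g) {
    n0 <- n[g$product]
    list(n = n0, on = g$spec$init_on,
         chain = if (is.null(g$chain_rates)) NULL
                 else numeric(length(g$spec$betas)),
         queue = rep(n0, g$spec$fixed_delay_steps))
  })
  rflux_prev <- lapply(net$reactions, function(r) 0)
  pools <- which(net$owner == "pool")

  nrec <- floor(nsteps / cfg$record_every) + 1L
  rec <- matrix(NA_real_, nrec, ns, dimnames = list(NULL, net$species$name))
  rec_t <- numeric(nrec)
  rec[1L, ] <- n; rec_t[1L] <- 0; ri <- 1L

  warn_t <- numeric(0); warn_e <- character(0); warn_c <- character(0)
  note_warn <- function(t, e, c) {
    if (length(warn_t) < 1000L) {
      warn_t <<- c(warn_t, t); warn_e <<- c(warn_e, e); warn_c <<- c(warn_c, c)
    }
  }

  for (q in seq_len(nsteps)) {
    t_new <- q * dt
    n_new <- n
    flux_new <- numeric(ns)

    for (ii in net$inputs)
      n_new[ii$sp] <- evaluate_input(ii$spec, t_new)

    for (gi in seq_along(net$genes)) {
      g <- net$genes[[gi]]; gs <- gstate[[gi]]
      rates <- .gene_rates_fast(g, n)
      nu <- g$spec$nu; delta <- g$spec$delta
      j <- flux[g$product]

      w <- check_step_criterion(rates$p_on, nu, dt)
      if (!is.null(w)) note_warn(t_new, g$spec$product, w)

      if (scen >= 2L)
        set.seed(.element_seed(cfg$seed, g$hash, q))

      if (is.null(g$chain_rates)) {
        if (scen == 1L) {
          gs$n <- max(0, .lin_step(gs$n, rates$p_on * nu + j, delta, dt))
        } else if (scen == 2L) {
          sw <- .realize_switching(gs$on, rates$lambda_eff, rates$mu_eff, dt)
          gs$on <- sw$on
          for (k in seq_len(nrow(sw$intervals)))
            gs$n <- .lin_step(gs$n, sw$intervals[k, 2L] * nu + j, delta,
                              sw$intervals[k, 1L])
          gs$n <- max(0, gs$n)
        } else {
          st <- advance_stochastic(list(n = gs$n, on = gs$on), rates, nu, delta, dt)
          gs$on <- st$on
          dn <- j * dt
          gs$n <- max(0L, st$n + sign(dn) * stochastic_round(abs(dn)))
        }
      } else {
        # deterministic rate-limiting chain; the final chain stage is the
        # mature product (removal rate delta)
        if (scen == 1L) {
          full <- advance_delay_chain(c(gs$chain, gs$n), rates$p_on, nu,
                                      g$chain_rates, dt)
          gs$chain <- full[-length(full)]
          gs$n <- max(0, full[length(full)] + j * dt)
        } else {
          sw <- .realize_switching(gs$on, rates$lambda_eff, rates$mu_eff, dt)
          gs$on <- sw$on
          if (scen == 2L) {
            full <- advance_delay_chain(c(gs$chain, gs$n), sw$intervals, nu,
                                        g$chain_rates)
            gs$chain <- full[-length(full)]
            gs$n <- max(0, full[length(full)] + j * dt)
          } else {
            # stages deterministic, product birth/death stochastic: births
            # are Poisson with the mean influx from the last stage
            nb <- length(gs$chain)
            c_old <- gs$chain
            gs$chain <- advance_delay_chain(gs$chain, sw$intervals, nu,
                                            g$spec$betas)
            beta_last <- g$spec$betas[nb]
            influx <- beta_last * (c_old[nb] + gs$chain[nb]) / 2 * dt
            nn <- sample_survivors(as.integer(round(gs$n)), delta, dt)
            nn <- nn + stats::rpois(1L, max(0, influx))
            dn <- j * dt
            gs$n <- max(0L, nn + sign(dn) * stochastic_round(abs(dn)))
          }
        }
      }

      del <- delayed_output(gs$queue, gs$n)
      gs$queue <- del$queue
      n_new[g$product] <- del$out
      gstate[[gi]] <- gs
    }

    for (rj in seq_along(net$reactions)) {
      r <- net$reactions[[rj]]; rs <- r$spec
      f0 <- n[r$cx]
      if (rs$kind == "hetero_dimer") {
        N1 <- n[r$sub[1]] + f0; N2 <- n[r$sub[2]] + f0
        jin <- flux[r$cx]
        if (rs$lambda > 0) {
          fp <- dimer_fixed_points(N1, N2, rs$lambda, rs$mu,
                                   rs$deltas[1], rs$deltas[2], jin)
          fdt <- dimer_advance(f0, dt, fp[1], fp[2], rs$lambda)
          fbar <- dimer_mean_complex(f0, dt, fp[1], fp[2], rs$lambda)
        } else {
          lr <- .linear_relax(f0, sum(rs$deltas) + rs$mu, jin, dt)
          fdt <- lr$f; fbar <- lr$fbar
        }
        cons1 <- (fdt - f0) + rs$deltas[1] * fbar * dt
        cons2 <- (fdt - f0) + rs$deltas[2] * fbar * dt
        n_new[r$cx] <- max(0, fdt)
        flux_new[r$sub[1]] <- flux_new[r$sub[1]] - cons1 / dt
        flux_new[r$sub[2]] <- flux_new[r$sub[2]] - cons2 / dt
        jrep <- (cons1 + cons2) / dt
      } else if (rs$kind == "homo_dimer") {
        N <- n[r$sub[1]] + 2 * f0
        res <- homodimer_advance(f0, N, rs$lambda, rs$mu, rs$deltas[1],
                                 flux[r$cx], dt)
        n_new[r$cx] <- max(0, res$f)
        flux_new[r$sub[1]] <- flux_new[r$sub[1]] - res$consumed_monomer / dt
        jrep <- res$consumed_monomer / dt
      } else {                         # enzyme
        own_prod <- !is.na(r$prod) && net$owner[r$prod] == "reaction_product"
        res <- enzyme_advance(
          state = list(f = f0, m = if (own_prod) n[r$prod] else 0),
          N_sub = n[r$sub[1]], N_enz = n[r$enz],
          lambda = rs$lambda, mu = rs$mu, nu = rs$nu, deltas = rs$deltas,
          j_in_complex = flux[r$cx],
          j_in_product = if (own_prod) flux[r$prod] else 0,
          dt = dt, track_product = own_prod)
        n_new[r$cx] <- max(0, res$f)
        # catalysis drains the (total) substrate pool
        flux_new[r$sub[1]] <- flux_new[r$sub[1]] - res$catalysed / dt
        if (own_prod) {
          n_new[r$prod] <- max(0, res$m)
        } else if (!is.na(r$prod)) {
          flux_new[r$prod] <- flux_new[r$prod] + res$catalysed / dt
        }
        jrep <- res$catalysed / dt
      }
      w <- check_flux_criterion(rflux_prev[[rj]], jrep, dt)
      if (!is.null(w)) note_warn(t_new, rs$complex, w)
      rflux_prev[[rj]] <- jrep
    }

    # implicit pool elements: first-order decay plus frozen net flux
    for (s in pools)
      n_new[s] <- max(0, .lin_step(n[s], flux[s], net$pool_delta[s], dt))

    if (any(!is.finite(n_new))) {
      bad <- net$species$name[!is.finite(n_new)][1]
      stop(sprintf("non-finite abundance of '%s' at t = %g s", bad, t_new))
    }

    n <- n_new
    flux <- flux_new
    if (q %% cfg$record_every == 0L) {
      ri <- ri + 1L
      rec[ri, ] <- n; rec_t[ri] <- t_new
    }
  }

  structure(list(times = rec_t[seq_len(ri)],
                 abundances = rec[seq_len(ri), , drop = FALSE],
                 warnings = data.frame(time = warn_t, element = warn_e,
                                       criterion = warn_c,
                                       stringsAsFactors = FALSE),
                 config = cfg),
            class = "grn_trajectory")
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d time points (0..%g s), %d species, %d warning(s)\n",
              length(x$times), max(x$times), ncol(x$abundances),
              nrow(x$warnings)))
  invisible(x)
}

#' Write a trajectory as TSV
#'
#' Column 1 is \code{time_s}; one column per species follows.  Warnings go
#' to a companion \code{<path>.warnings.log} when present.
#'
#' @param tr a \code{grn_trajectory}
#' @param path output TSV path
#' @return \code{path}, invisibly
#' @export
write_trajectory <- function(tr, path) {
  df <- data.frame(time_s = tr$times, tr$abundances, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(tr$warnings)) {
    wl <- sprintf("%g\t%s\t%s", tr$warnings$time, tr$warnings$element,
                  tr$warnings$criterion)
    writeLines(wl, paste0(path, ".warnings.log"))
  }
  invisible(path)
}

#' Read a trajectory written by \code{\link{write_trajectory}}
#'
#' @param path TSV path
#' @return a \code{grn_trajectory} (without warnings)
#' @export
read_trajectory <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  structure(list(times = df$time_s,
                 abundances = as.matrix(df[, -1, drop = FALSE]),
                 warnings = data.frame(time = numeric(0), element = character(0),
                                       criterion = character(0)),
                 config = NULL),
            class = "grn_trajectory")
}
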