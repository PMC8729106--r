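# Effective two-state promoter rates.
#
# A promoter with several binding sites is summarized by an equivalent
# two-state (telegraph) promoter with on-rate lambda_eff, off-rate mu_eff
# and stationary on-probability p_on = lambda_eff / (lambda_eff + mu_eff).

#' Construct an effective-rates triple
#'
#' Container for the effective two-state description of a promoter:
#' on-rate \code{lambda_eff} (1/s), off-rate \code{mu_eff} (1/s) and the
#' stationary on-probability \code{p_on}.
#'
#' @param lambda_eff effective on-rate (1/s), non-negative
#' @param mu_eff effective off-rate (1/s), strictly positive
#' @return an object of class \code{effective_rates}
#' @export
effective_rates <- function(lambda_eff, mu_eff) {
  if (!(is.finite(lambda_eff) && is.finite(mu_eff) &&
        lambda_eff >= 0 && mu_eff > 0))
    stop("need lambda_eff >= 0 and mu_eff > 0, both finite")
  out <- list(lambda_eff = lambda_eff, mu_eff = mu_eff,
              p_on = lambda_eff / (lambda_eff + mu_eff))
  class(out) <- "effective_rates"
  out
}

#' @export
print.effective_rates <- function(x, ...) {
  cat(sprintf("effective promoter rates: lambda_eff = %g /s, mu_eff = %g /s, p_on = %g\n",
              x$lambda_eff, x$mu_eff, x$p_on))
  invisible(x)
}

#' Effective rates for activation by a single transcription factor
#'
#' The promoter switches on when a transcription factor (TF) arrives, so the
#' on-rate is the total arrival rate \code{n_tf * lambda0}; the off-rate is
#' the TF dissociation rate \code{mu}.
#'
#' @param n_tf TF copy number (molecules, >= 0)
#' @param lambda0 per-molecule arrival rate (1/(s molecule))
#' @param mu dissociation rate (1/s)
#' @return an \code{effective_rates} object
#' @export
rates_single <- function(n_tf, lambda0, mu) {
  if (!is.finite(n_tf) || n_tf < 0)
    stop("n_tf must be a non-negative number")
  effective_rates(n_tf * lambda0, mu)
}

#' Effective rates for a promoter with AND logic
#'
#' The gene is on only while every TF is bound.  Losing any single TF ends
#' the on-period, so the effective off-rate is the sum of the individual
#' off-rates; the on-probability is the product of the per-site bound
#' probabilities, and the on-rate follows from detailed balance of the
#' equivalent two-state promoter.
#'
#' @param bindings list of numeric pairs \code{c(lambda_i, mu_i)}; each
#'   \code{lambda_i} must already be scaled by the TF copy number
#' @return an \code{effective_rates} object
#' @export
rates_and <- function(bindings) {
  if (length(bindings) == 0) stop("AND promoter needs at least one binding")
  lam <- vapply(bindings, `[`, numeric(1), 1L)
  mu  <- vapply(bindings, `[`, numeric(1), 2L)
  stopifnot(all(lam >= 0), all(mu > 0))
  mu_eff <- sum(mu)
  p_on <- prod(lam / (lam + mu))
  if (p_on >= 1) stop("degenerate AND promoter: p_on = 1")
  effective_rates(p_on / (1 - p_on) * mu_eff, mu_eff)
}

#' Effective rates for a promoter with OR logic
#'
#' The gene is on while at least one TF is bound.  The on-rate is the sum of
#' the individual arrival rates; the on-probability is one minus the
#' probability that every site is empty.  When every arrival rate is zero
#' the gene can never activate and the convention
#' \code{lambda_eff = 0, mu_eff = sum(mu_i)} is returned.
#'
#' @inheritParams rates_and
#' @return an \code{effective_rates} object
#' @export
rates_or <- function(bindings) {
  if (length(bindings) == 0) stop("OR promoter needs at least one binding")
  lam <- vapply(bindings, `[`, numeric(1), 1L)
  mu  <- vapply(bindings, `[`, numeric(1), 2L)
  stopifnot(all(lam >= 0), all(mu > 0))
  lambda_eff <- sum(lam)
  if (lambda_eff == 0)              # all sites empty forever
    return(effective_rates(0, sum(mu)))
  p_on <- 1 - prod(mu / (lam + mu))
  effective_rates(lambda_eff, lambda_eff * (1 - p_on) / p_on)
}

#' Effective rates for a constitutively active, repressible promoter
#'
#' The promoter transcribes whenever no repressor is bound: the off-rate is
#' the total repressor arrival rate and the on-rate is the repressor
#' dissociation rate.  With no repressor molecules present the gene is
#' permanently on (\code{p_on} approaches 1), which is signalled by a very
#' large \code{lambda_eff}.
#'
#' @param repressors list of numeric pairs \code{c(lambda_R, mu_R)} with
#'   \code{lambda_R} scaled by repressor copy number
#' @return an \code{effective_rates} object
#' @export
rates_constitutive <- function(repressors) {
  if (length(repressors) == 0)
    return(effective_rates(1e12, 1e-12))   # effectively always on
  lam <- vapply(repressors, `[`, numeric(1), 1L)
  mu  <- vapply(repressors, `[`, numeric(1), 2L)
  stopifnot(all(lam >= 0), all(mu > 0))
  mu_eff <- sum(lam)                       # arrival of any repressor
  p_on <- prod(1 / (1 + lam / mu))
  if (mu_eff == 0)
    return(effective_rates(1e12, 1e-12))
  effective_rates(p_on / (1 - p_on) * mu_eff, mu_eff)
}

#' Apply competitive repression to an effective promoter
#'
#' A bound repressor blocks activation but does not terminate an ongoing
#' on-period, so only the effective on-rate is reduced: each repressor
#' contributes a factor \code{1/(1 + K_R)} with \code{K_R = lambda_R/mu_R}
#' (arrival rate already scaled by copy number).  Several repressors act
#' multiplicatively.
#'
#' @param base an \code{effective_rates} object for the unrepressed promoter
#' @param repressors list of numeric pairs \code{c(lambda_R, mu_R)}
#' @return an \code{effective_rates} object with reduced \code{lambda_eff}
#' @export
apply_repression <- function(base, repressors) {
  stopifnot(inherits(base, "effective_rates"))
  if (length(repressors) == 0) return(base)
  fac <- 1
  for (r in repressors) {
    stopifnot(r[1] >= 0, r[2] > 0)
    fac <- fac / (1 + r[1] / r[2])
  }
  effective_rates(base$lambda_eff * fac, base$mu_eff)
}

# Effective rates of a gene's promoter given current species abundances.
# `levels` is a named numeric vector of copy numbers at the last
# synchronization point.  Internal work-horse used by the engine, the
# mean-field ODE assembly and the inference module.
promoter_rates <- function(gene, levels) {
  act <- list(); rep_ <- list()
  for (b in gene$bindings) {
    n <- levels[[b$tf]]
    pair <- c(b$lambda0 * n, b$mu)
    if (b$role == "activator") act[[length(act) + 1L]] <- pair
    else rep_[[length(rep_) + 1L]] <- pair
  }
  base <- switch(gene$logic,
    single = { stopifnot(length(act) == 1L)
               rates_single(1, act[[1L]][1L], act[[1L]][2L]) },
    and = rates_and(act),
    or = rates_or(act),
    constitutive = return(rates_constitutive(rep_)))
  apply_repression(base, rep_)
}
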