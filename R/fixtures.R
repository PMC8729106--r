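# Benchmark fixtures: the repressive four-gene cascade and the two
# autoregulatory feedback loops with enzyme-assisted degradation.  Each
# fixture exists in two synchronized forms -- a network specification for
# the hybrid engine and an explicit reaction system for the Gillespie
# oracle -- built from one shared parameter set.

#' Parameters of the repressive gene cascade
#'
#' Two documented switching regimes: \code{"slow"} puts the effective
#' promoter switching rates on the order of the product degradation rate
#' (bursty expression), \code{"fast"} makes switching several hundred
#' times faster than degradation (expression noise dominated by
#' birth/death events).  A constitutive activator A (100 copies) can
#' switch every link on; the input species R0 and every product repress
#' the next link.
#'
#' @param regime \code{"slow"} or \code{"fast"} promoter switching
#' @param input_level constant copy number of the input repressor R0
#' @return named parameter list
#' @export
cascade_params <- function(regime = c("slow", "fast"), input_level = 100) {
  regime <- match.arg(regime)
  p <- list(
    nu = 0.02,          # molecules/s while on
    delta = 1e-4,       # 1/s product degradation (lifetime ~2.8 h)
    lambda_R0 = 1e-3,   # repressor arrival per molecule
    mu_R = 0.01,        # repressor dissociation -> K_R = 0.1 per molecule
    activator_level = 100,
    input_level = input_level,
    regime = regime)
  if (regime == "slow") {
    p$lambda_A0 <- 2e-6   # lambda_eff = 2e-4 with 100 activator copies
    p$mu_A <- 2e-4
  } else {
    # 50x faster than degradation, but still slower than repressor
    # binding kinetics so the quasi-equilibrated promoter occupancy
    # underlying the effective two-state rates remains valid
    p$lambda_A0 <- 5e-5   # lambda_eff = 5e-3
    p$mu_A <- 5e-3
  }
  p
}

#' Network specification of the repressive cascade
#'
#' @param params list from \code{\link{cascade_params}}
#' @param n_links number of genes in the chain
#' @return a \code{\link{network_spec}} with genes producing R1..Rn
#' @export
cascade_network <- function(params = cascade_params(), n_links = 4L) {
  inputs <- list(
    input_spec("A", "constant", amplitude = params$activator_level),
    input_spec("R0", "constant", amplitude = params$input_level))
  genes <- lapply(seq_len(n_links), function(n) {
    gene_spec(sprintf("R%d", n), logic = "single",
              bindings = list(
                tf_binding("A", params$lambda_A0, params$mu_A, "activator"),
                tf_binding(sprintf("R%d", n - 1L), params$lambda_R0,
                           params$mu_R, "repressor")),
              nu = params$nu, delta = params$delta)
  })
  network_spec(inputs = inputs, genes = genes)
}

#' Two-enzyme loop fixture
#'
#' Two enzymes mutually take each other's product: F transforms substrate
#' N into M, G transforms M back into N.  A constitutively active source
#' gene supplies N; both metabolites decay slowly.  The steady state of
#' this coupled system is reproduced by the synchronized engine
#' independently of the step size, because each element advances its exact
#' local differential equation.
#'
#' @param params named list of rates (defaults built in)
#' @return a \code{\link{network_spec}}
#' @export
enzyme_loop_network <- function(params = list()) {
  p <- utils::modifyList(list(
    nu_src = 0.2,       # constitutive supply of N (molecules/s)
    delta = 1e-3,       # decay of both metabolites
    lambda1 = 2e-3, mu1 = 0.05, nu1 = 0.05, F_level = 30,
    lambda2 = 2e-3, mu2 = 0.05, nu2 = 0.05, G_level = 20), params)
  src <- gene_spec("N", logic = "constitutive", bindings = list(),
                   nu = p$nu_src, delta = p$delta)
  inputs <- list(input_spec("F", "constant", amplitude = p$F_level),
                 input_spec("G", "constant", amplitude = p$G_level))
  reactions <- list(
    reaction_spec("enzyme", substrates = "N", enzyme = "F", product = "M",
                  complex = "NF", lambda = p$lambda1, mu = p$mu1,
                  nu = p$nu1, deltas = c(p$delta, 0, p$delta)),
    reaction_spec("enzyme", substrates = "M", enzyme = "G", product = "N",
                  complex = "MG", lambda = p$lambda2, mu = p$mu2,
                  nu = p$nu2, deltas = c(p$delta, 0, p$delta)))
  network_spec(inputs = inputs, genes = list(src), reactions = reactions)
}

#' Parameters of the autoregulatory feedback fixtures
#'
#' \code{"positive"}: self-activation with slow promoter switching and a
#' weak constitutive basal site; discrete birth/death noise lets the
#' product dwell near extinction where reactivation is rare, which
#' produces a second low-expression mode.  \code{"negative"}:
#' constitutive transcription repressed by the product with fast
#' promoter kinetics, an RNA maturation step providing an effective
#' feedback delay, and enzyme-assisted degradation; molecular noise
#' sustains oscillations at the damped resonance frequency of the
#' mean-field dynamics.
#'
#' @param kind \code{"positive"} or \code{"negative"}
#' @return named parameter list
#' @export
feedback_params <- function(kind = c("positive", "negative")) {
  kind <- match.arg(kind)
  if (kind == "positive") {
    # deterministically bistable mean field (stable states ~3 and ~56
    # molecules); molecular birth/death noise drives transitions between
    # the two states, promoter switching alone does not
    # switching is fast enough that promoter noise alone cannot cross
    # the barrier between the two states (scenario 2 stays unimodal)
    list(
      lambda_A0 = 0.0216, # self-activation arrival per product molecule
      mu_A = 0.4,         # on-period 2.5 s
      lambda_b = 0.048,   # basal site keeps the low state off extinction
      mu_b = 0.4,
      nu = 0.43,          # RNA synthesis while on
      beta = 0.5,         # fast RNA maturation
      delta = 2e-3,       # spontaneous product degradation
      # few-copy, high-turnover enzyme: Vmax 0.25/s, K_M 5, but only ~2
      # copies so that complexed product stays a small fraction of the
      # total (the effective-rates promoter reads total copy numbers)
      lambda_E = 0.035, mu_E = 0.05, nu_E = 0.125,
      enzyme_level = 2,
      init_product = 50)
  } else {
    # weakly damped mean field (resonance period ~1200 s, quality factor
    # ~5 from the two-stage maturation delay); repressor binding is fast
    # so promoter-switching noise alone is negligible
    list(
      lambda_R0 = 0.4,    # self-repression arrival per molecule
      mu_R = 0.4,         # K_R = 1 per molecule
      nu = 4,             # constitutive RNA synthesis while free
      beta = c(1 / 195, 1 / 205),  # two maturation stages = delay
                                   # (slightly split: the closed-form
                                   # chain needs distinct rates)
      delta = 5e-4,
      lambda_E = 0.029, mu_E = 0.05, nu_E = 0.125, # Vmax 0.25/s, K_M 6
      enzyme_level = 2,
      init_product = 20)
  }
}

#' Network specification of a feedback fixture
#'
#' @param kind \code{"positive"} or \code{"negative"}
#' @param params list from \code{\link{feedback_params}}
#' @return a \code{\link{network_spec}}
#' @export
feedback_network <- function(kind = c("positive", "negative"),
                             params = feedback_params(kind)) {
  kind <- match.arg(kind)
  if (kind == "positive") {
    gene <- gene_spec("A", logic = "or",
                      bindings = list(
                        tf_binding("A", params$lambda_A0, params$mu_A, "activator"),
                        tf_binding("B", params$lambda_b, params$mu_b, "activator")),
                      nu = params$nu, delta = params$delta,
                      betas = params$beta, init = params$init_product)
    inputs <- list(input_spec("B", "constant", amplitude = 1),
                   input_spec("E", "constant", amplitude = params$enzyme_level))
    reactions <- list(reaction_spec("enzyme", substrates = "A", enzyme = "E",
                                    product = NA_character_, complex = "EA",
                                    lambda = params$lambda_E, mu = params$mu_E,
                                    nu = params$nu_E,
                                    deltas = c(params$delta, 0, 0)))
    network_spec(inputs = inputs, genes = list(gene), reactions = reactions)
  } else {
    gene <- gene_spec("R", logic = "constitutive",
                      bindings = list(
                        tf_binding("R", params$lambda_R0, params$mu_R, "repressor")),
                      nu = params$nu, delta = params$delta,
                      betas = params$beta, init = params$init_product)
    inputs <- list(input_spec("E", "constant", amplitude = params$enzyme_level))
    reactions <- list(reaction_spec("enzyme", substrates = "R", enzyme = "E",
                                    product = NA_character_, complex = "ER",
                                    lambda = params$lambda_E, mu = params$mu_E,
                                    nu = params$nu_E,
                                    deltas = c(params$delta, 0, 0)))
    network_spec(inputs = inputs, genes = list(gene), reactions = reactions)
  }
}
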