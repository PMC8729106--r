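# Declarative network model: inputs, genes, bimolecular reactions.

#' Define a signalling input element
#'
#' An input is a species whose copy number follows a prescribed time course
#' and is not affected by the rest of the network.
#'
#' @param species species name produced by the input
#' @param profile one of \code{"constant"}, \code{"rectangular"},
#'   \code{"sinusoidal"}
#' @param amplitude amplitude in molecules (the constant level for
#'   \code{profile = "constant"})
#' @param baseline baseline level in molecules (rectangular/sinusoidal)
#' @param period period in seconds (rectangular/sinusoidal)
#' @param phase phase offset in seconds
#' @param duty on-fraction of a rectangular wave (default 0.5)
#' @return an object of class \code{input_spec}
#' @export
input_spec <- function(species, profile = c("constant", "rectangular", "sinusoidal"),
                       amplitude, baseline = 0, period = NA_real_,
                       phase = 0, duty = 0.5) {
  profile <- match.arg(profile)
  stopifnot(is.character(species), length(species) == 1L)
  structure(list(species = species, profile = profile, amplitude = amplitude,
                 baseline = baseline, period = period, phase = phase,
                 duty = duty),
            class = "input_spec")
}

#' Define a transcription-factor binding site
#'
#' @param tf species name of the transcription factor
#' @param lambda0 per-molecule arrival rate at the promoter
#'   (1/(s molecule)), > 0
#' @param mu dissociation rate (1/s), > 0
#' @param role \code{"activator"} or \code{"repressor"}
#' @return an object of class \code{tf_binding}
#' @export
tf_binding <- function(tf, lambda0, mu, role = c("activator", "repressor")) {
  role <- match.arg(role)
  structure(list(tf = tf, lambda0 = lambda0, mu = mu, role = role),
            class = "tf_binding")
}

#' Define a gene element
#'
#' A gene is a two-state promoter with a regulatory logic over its binding
#' sites, a product synthesis rate \code{nu} active while the promoter is
#' on, a product degradation rate \code{delta}, an optional chain of
#' deterministic rate-limiting processing steps (rates \code{betas}) between
#' initiation and mature product, and an optional fixed reporting delay of
#' \code{fixed_delay_steps} synchronization steps.
#'
#' @param product species name of the gene product
#' @param logic promoter logic: \code{"single"} (one activator),
#'   \code{"and"}, \code{"or"}, or \code{"constitutive"} (active unless a
#'   repressor is bound)
#' @param bindings list of \code{\link{tf_binding}} sites
#' @param nu product synthesis rate while on (molecules/s)
#' @param delta product degradation rate (1/s), > 0
#' @param betas rates of intermediate rate-limiting steps (1/s), possibly
#'   empty; must be pairwise distinct and distinct from \code{delta}
#' @param fixed_delay_steps integer >= 0, reporting delay in whole
#'   synchronization steps
#' @param init initial product abundance
#' @param init_on initial promoter state for stochastic scenarios
#' @return an object of class \code{gene_spec}
#' @export
gene_spec <- function(product, logic = c("single", "and", "or", "constitutive"),
                      bindings = list(), nu, delta, betas = numeric(0),
                      fixed_delay_steps = 0L, init = 0, init_on = FALSE) {
  logic <- match.arg(logic)
  structure(list(product = product, logic = logic, bindings = bindings,
                 nu = nu, delta = delta, betas = as.numeric(betas),
                 fixed_delay_steps = as.integer(fixed_delay_steps),
                 init = init, init_on = isTRUE(init_on)),
            class = "gene_spec")
}

#' Define a bimolecular reaction element
#'
#' Three elementary kinds are available: hetero-dimerization of two
#' species, homo-dimerization of one species, and transformation of a
#' substrate into a product catalysed by an enzyme.  More complex
#' biochemical reactions are built by chaining elements through shared
#' species.
#'
#' @param kind \code{"hetero_dimer"}, \code{"homo_dimer"} or \code{"enzyme"}
#' @param substrates character vector: two species (hetero), one (homo), or
#'   one substrate (enzyme)
#' @param enzyme enzyme species name (enzyme kind only)
#' @param product product species name (enzyme kind; \code{NA} makes the
#'   catalysed output a sink, i.e. enzymatic degradation)
#' @param complex species name for the complex/dimer (default derived from
#'   the substrate names)
#' @param lambda association rate (1/(s molecule))
#' @param mu dissociation rate of the complex (1/s)
#' @param nu catalytic rate (1/s, enzyme kind only)
#' @param deltas degradation rates: \code{c(d1, d2)} for the two monomers
#'   (hetero), \code{d1} (homo), \code{c(d_substrate, d_enzyme, d_product)}
#'   (enzyme)
#' @param init_complex initial complex abundance
#' @param init_product initial product abundance (enzyme kind)
#' @return an object of class \code{reaction_spec}
#' @export
reaction_spec <- function(kind = c("hetero_dimer", "homo_dimer", "enzyme"),
                          substrates, enzyme = NULL, product = NA_character_,
                          complex = NULL, lambda, mu, nu = 0, deltas,
                          init_complex = 0, init_product = 0) {
  kind <- match.arg(kind)
  if (is.null(complex))
    complex <- paste(c(substrates, enzyme), collapse = ":")
  structure(list(kind = kind, substrates = as.character(substrates),
                 enzyme = enzyme, product = product, complex = complex,
                 lambda = lambda, mu = mu, nu = nu,
                 deltas = as.numeric(deltas),
                 init_complex = init_complex, init_product = init_product),
            class = "reaction_spec")
}

#' Assemble a network specification
#'
#' @param inputs list of \code{\link{input_spec}}
#' @param genes list of \code{\link{gene_spec}}
#' @param reactions list of \code{\link{reaction_spec}}
#' @param species_init named numeric vector of initial abundances for
#'   species not produced by a gene or input (free monomer pools etc.);
#'   optional decay rates of such pools are taken from the reaction
#'   definitions that reference them
#' @return an object of class \code{network_spec}
#' @export
network_spec <- function(inputs = list(), genes = list(), reactions = list(),
                         species_init = numeric(0)) {
  spec <- structure(list(inputs = inputs, genes = genes,
                         reactions = reactions,
                         species_init = species_init),
                    class = "network_spec")
  spec
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network: %d input(s), %d gene(s), %d reaction(s)\n",
              length(x$inputs), length(x$genes), length(x$reactions)))
  cat("species:", paste(network_species(x)$name, collapse = ", "), "\n")
  invisible(x)
}

#' List all species of a network with their kind
#'
#' @param spec a \code{\link{network_spec}}
#' @return data.frame with columns \code{name} and \code{kind}
#'   (\code{input}, \code{gene_product}, \code{complex},
#'   \code{reaction_product}, \code{pool})
#' @export
network_species <- function(spec) {
  nm <- character(0); kd <- character(0)
  add <- function(n, k) {
    keep <- !(n %in% nm)
    nm <<- c(nm, n[keep]); kd <<- c(kd, rep(k, sum(keep)))
  }
  add(vapply(spec$inputs, `[[`, character(1), "species"), "input")
  add(vapply(spec$genes, `[[`, character(1), "product"), "gene_product")
  for (r in spec$reactions) {
    add(r$complex, "complex")
    if (r$kind == "enzyme" && !is.na(r$product)) add(r$product, "reaction_product")
  }
  # remaining reaction substrates/enzymes are free pools
  for (r in spec$reactions) {
    add(r$substrates, "pool")
    if (!is.null(r$enzyme)) add(r$enzyme, "pool")
  }
  add(names(spec$species_init), "pool")
  data.frame(name = nm, kind = kd, stringsAsFactors = FALSE)
}

#' Validate a network specification
#'
#' Checks every structural invariant of the model (positive rates, resolved
#' wiring, unique producers, promoter logic constraints) and returns a
#' character vector of human-readable diagnostics, one per violation.  An
#' empty vector means the network is well-formed.
#'
#' @param spec a \code{\link{network_spec}}
#' @return character vector of diagnostics (empty if valid)
#' @export
validate_network <- function(spec) {
  d <- character(0)
  say <- function(...) d <<- c(d, sprintf(...))
  sp <- tryCatch(network_species(spec), error = function(e) NULL)
  if (is.null(sp)) return("species table cannot be built")
  if (anyDuplicated(sp$name))
    say("duplicate species name: %s", sp$name[duplicated(sp$name)][1])

  producers <- c(vapply(spec$inputs, `[[`, character(1), "species"),
                 vapply(spec$genes, `[[`, character(1), "product"))
  if (anyDuplicated(producers))
    say("species produced by more than one element: %s",
        producers[duplicated(producers)][1])

  for (i in seq_along(spec$inputs)) {
    inp <- spec$inputs[[i]]
    if (!is.finite(inp$amplitude) || inp$amplitude < 0)
      say("input %s: amplitude must be >= 0", inp$species)
    if (inp$profile != "constant" && (!is.finite(inp$period) || inp$period <= 0))
      say("input %s: %s profile needs period > 0", inp$species, inp$profile)
  }

  for (g in spec$genes) {
    if (!is.finite(g$nu) || g$nu < 0) say("gene %s: nu must be >= 0", g$product)
    if (!is.finite(g$delta) || g$delta <= 0)
      say("gene %s: delta must be > 0", g$product)
    n_act <- sum(vapply(g$bindings, function(b) b$role == "activator", logical(1)))
    if (g$logic == "single" && n_act != 1L)
      say("gene %s: logic 'single' requires exactly one activator", g$product)
    if (g$logic %in% c("and", "or") && n_act == 0L)
      say("gene %s: logic '%s' requires at least one activator", g$product, g$logic)
    if (g$logic == "constitutive" && n_act > 0L)
      say("gene %s: constitutive promoter cannot have activators", g$product)
    for (b in g$bindings) {
      if (!(b$tf %in% sp$name))
        say("gene %s: unresolved species %s", g$product, b$tf)
      if (!is.finite(b$lambda0) || b$lambda0 <= 0)
        say("gene %s: binding of %s needs lambda0 > 0", g$product, b$tf)
      if (!is.finite(b$mu) || b$mu <= 0)
        say("gene %s: binding of %s needs mu > 0", g$product, b$tf)
    }
    if (length(g$betas)) {
      if (any(g$betas <= 0)) say("gene %s: all betas must be > 0", g$product)
      r <- c(g$betas, g$delta)
      if (min(abs(diff(sort(r))) / max(r)) < 1e-9)
        say("gene %s: processing rates (betas, delta) must be pairwise distinct; perturb equal rates by ~1e-6", g$product)
    }
    if (g$fixed_delay_steps < 0) say("gene %s: fixed_delay_steps must be >= 0", g$product)
  }

  for (r in spec$reactions) {
    if (any(!is.finite(c(r$lambda, r$mu, r$nu, r$deltas))) ||
        any(c(r$lambda, r$mu, r$nu, r$deltas) < 0))
      say("reaction %s: all rates must be finite and >= 0", r$complex)
    nsub <- length(r$substrates)
    if (r$kind == "hetero_dimer" && (nsub != 2L || length(r$deltas) != 2L))
      say("reaction %s: hetero_dimer needs 2 substrates and 2 deltas", r$complex)
    if (r$kind == "homo_dimer" && (nsub != 1L || length(r$deltas) != 1L))
      say("reaction %s: homo_dimer needs 1 substrate and 1 delta", r$complex)
    if (r$kind == "enzyme") {
      if (nsub != 1L || is.null(r$enzyme) || length(r$deltas) != 3L)
        say("reaction %s: enzyme needs 1 substrate, an enzyme and 3 deltas", r$complex)
      if (!is.na(r$product) && r$product %in% r$substrates)
        say("reaction %s: product must differ from substrate", r$complex)
    }
    for (s in c(r$substrates, r$enzyme))
      if (!(s %in% sp$name)) say("reaction %s: unresolved species %s", r$complex, s)
  }
  d
}

#' Describe a gene knockout
#'
#' @param gene product species name of the gene to knock out
#' @param residual_nu residual synthesis rate after knockdown (default 0,
#'   a full knockout)
#' @return an object of class \code{knockout_spec}
#' @export
knockout_spec <- function(gene, residual_nu = 0) {
  stopifnot(residual_nu >= 0)
  structure(list(gene = gene, residual_nu = residual_nu),
            class = "knockout_spec")
}

#' Apply a knockout to a network
#'
#' Returns a copy of the network in which the knocked-out gene's synthesis
#' rate is replaced by the residual rate; everything else is untouched.
#'
#' @param spec a \code{\link{network_spec}}
#' @param ko a \code{\link{knockout_spec}}
#' @return a new \code{network_spec}
#' @export
apply_knockout <- function(spec, ko) {
  stopifnot(inherits(spec, "network_spec"), inherits(ko, "knockout_spec"))
  idx <- which(vapply(spec$genes, `[[`, character(1), "product") == ko$gene)
  if (length(idx) != 1L)
    stop(sprintf("unknown gene '%s'", ko$gene))
  if (ko$residual_nu > spec$genes[[idx]]$nu)
    stop(sprintf("residual_nu exceeds original nu of gene '%s'", ko$gene))
  spec$genes[[idx]]$nu <- ko$residual_nu
  spec
}

#' Simulation configuration
#'
#' @param dt synchronization time step (s)
#' @param t_end total simulated time (s)
#' @param scenario 1 (deterministic), 2 (stochastic promoter switching) or
#'   3 (switching plus stochastic birth/death of products)
#' @param seed integer RNG seed
#' @param record_every record every k-th synchronization step
#' @return an object of class \code{sim_config}
#' @export
sim_config <- function(dt, t_end, scenario = 1L, seed = 1L, record_every = 1L) {
  stopifnot(dt > 0, t_end >= dt, scenario %in% 1:3, record_every >= 1)
  structure(list(dt = dt, t_end = t_end, scenario = as.integer(scenario),
                 seed = as.integer(seed), record_every = as.integer(record_every)),
            class = "sim_config")
}
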