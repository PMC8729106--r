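# Inference of promoter equilibrium constants and network topology from
# steady-state expression measurements with a recurrent-network delta
# rule.
#
# Each gene is a perceptron-like unit with steady-state response
#   F_j(x) = nu_j * p_on_j(x) - delta_j * x_j = 0,
# where p_on_j combines OR-logic activation (per-edge occupancies
# K x/(1 + K x), plus constant basal/input sites) with competitive
# repression (each repressor scales the effective on-rate by
# 1/(1 + K x)).  Only the equilibrium constants K = lambda0/mu of
# gene-gene edges are trained; production and degradation rates stay
# fixed.  One adjoint solve with the Jacobian transpose per condition
# yields the gradient for every parameter.

# --- internal trainable representation -------------------------------------

# Extract the gene-gene edge table and fixed quantities from a spec whose
# genes all use OR logic (activators) plus competitive repression.
.trainable <- function(spec) {
  gene_names <- vapply(spec$genes, `[[`, character(1), "product")
  N <- length(gene_names)
  input_names <- vapply(spec$inputs, `[[`, character(1), "species")
  edges <- data.frame(j = integer(0), i = integer(0), role = character(0),
                      K = numeric(0), mu = numeric(0))
  basal <- vector("list", N)   # per-gene list of constant (K, role, tf)
  for (j in seq_len(N)) {
    g <- spec$genes[[j]]
    if (g$logic != "or")
      stop("trainable networks must use OR-logic promoters")
    for (b in g$bindings) {
      i <- match(b$tf, gene_names)
      if (is.na(i)) {
        if (!(b$tf %in% input_names))
          stop(sprintf("binding of unknown species %s", b$tf))
        basal[[j]] <- c(basal[[j]], list(list(tf = b$tf, K = b$lambda0 / b$mu,
                                              role = b$role)))
      } else {
        edges <- rbind(edges, data.frame(j = j, i = i, role = b$role,
                                         K = b$lambda0 / b$mu, mu = b$mu))
      }
    }
  }
  list(genes = gene_names, N = N,
       nu = vapply(spec$genes, `[[`, numeric(1), "nu"),
       delta = vapply(spec$genes, `[[`, numeric(1), "delta"),
       edges = edges, basal = basal,
       input_levels = stats::setNames(
         vapply(spec$inputs, `[[`, numeric(1), "amplitude"), input_names))
}

# p_on for every gene given gene-product levels x; returns the pieces
# needed by the derivative assembly:
#   P   = product of activator-site off-probabilities (incl. basal sites)
#   rho = product of repressor factors 1/(1 + K x)
#   p_on = rho (1-P) / (rho (1-P) + P)
.p_on_pieces <- function(tr, x, nu_scale = NULL) {
  N <- tr$N
  P <- rep(1, N); rho <- rep(1, N)
  for (j in seq_len(N)) {
    for (b in tr$basal[[j]]) {
      occ <- b$K * tr$input_levels[[b$tf]]
      if (b$role == "activator") P[j] <- P[j] / (1 + occ)
      else rho[j] <- rho[j] / (1 + occ)
    }
  }
  e <- tr$edges
  for (r in seq_len(nrow(e))) {
    occ <- e$K[r] * x[e$i[r]]
    if (e$role[r] == "activator") P[e$j[r]] <- P[e$j[r]] / (1 + occ)
    else rho[e$j[r]] <- rho[e$j[r]] / (1 + occ)
  }
  D <- rho * (1 - P) + P
  list(P = P, rho = rho, D = D, p_on = rho * (1 - P) / D)
}

#' Steady-state expression of a trainable network
#'
#' Runs the deterministic (scenario 1) per-gene update map to convergence:
#' every gene repeatedly applies its closed-form solution with the other
#' genes' levels frozen, exactly as in the synchronized engine, until all
#' residual time derivatives satisfy \code{|F_j| < tol * max(1, x_j)}.
#'
#' @param spec a \code{\link{network_spec}} whose dynamic elements are
#'   OR-logic genes and constant inputs
#' @param condition optional \code{\link{knockout_spec}} (or list of them)
#'   applied before solving
#' @param tol convergence tolerance on the residual derivative
#' @param max_iter maximum update sweeps
#' @param x0 optional warm start
#' @return named vector of steady-state gene-product levels
#' @export
steady_state <- function(spec, condition = NULL, tol = 1e-8,
                         max_iter = 50000L, x0 = NULL) {
  gene_names <- vapply(spec$genes, `[[`, character(1), "product")
  cond <- .parse_condition(condition, gene_names)
  if (inherits(condition, "knockout_spec")) condition <- list(condition)
  if (is.list(condition) && !is.null(condition$knockouts))
    condition <- condition$knockouts
  if (length(cond$ko_idx))
    for (ko in condition)
      if (inherits(ko, "knockout_spec")) spec <- apply_knockout(spec, ko)
  tr <- .trainable(spec)
  for (nm in names(cond$inputs)) tr$input_levels[[nm]] <- cond$inputs[[nm]]
  .steady_state_tr(tr, tol, max_iter, x0)
}

.steady_state_tr <- function(tr, tol = 1e-8, max_iter = 50000L, x0 = NULL) {
  N <- tr$N
  x <- if (is.null(x0)) tr$nu / tr$delta * 0.5 else as.numeric(x0)
  # damped exact per-gene step: relaxation factor e^(-delta dt) ~ 0.2
  dt <- 1.6 / max(tr$delta)
  e <- exp(-tr$delta * dt)
  for (it in seq_len(max_iter)) {
    p <- .p_on_pieces(tr, x)$p_on
    xs <- p * tr$nu / tr$delta
    x_new <- x * e + xs * (1 - e)
    x <- x_new
    Fres <- tr$nu * p - tr$delta * x
    if (max(abs(Fres) / pmax(1, x)) < tol) {
      names(x) <- tr$genes
      return(x)
    }
  }
  stop("steady_state did not converge; last state: ",
       paste(sprintf("%.4g", x), collapse = ", "))
}

#' Analytic steady-state derivatives of a trainable network
#'
#' Assembles the Jacobian \code{L[j,k] = dF_j/dx_k} and the parameter
#' sensitivities \code{dF_j/dK} for every trainable gene-gene equilibrium
#' constant, evaluated at the state \code{x}.
#'
#' @param spec trainable \code{\link{network_spec}}
#' @param x steady-state expression vector
#' @param knocked optional integer indices of knocked-out genes (their
#'   synthesis term is absent)
#' @return list with \code{L} (N x N), \code{dF_dphi} (N x n_edges) and
#'   \code{edges} (the edge table defining the parameter order)
#' @export
local_derivatives <- function(spec, x, knocked = integer(0)) {
  tr <- .trainable(spec)
  .local_derivatives_tr(tr, x, knocked)
}

.local_derivatives_tr <- function(tr, x, knocked = integer(0)) {
  N <- tr$N
  pc <- .p_on_pieces(tr, x)
  nu <- tr$nu
  nu[knocked] <- 0
  # d p_on / dP and / drho  (D = rho(1-P) + P; the cross terms collapse)
  dpdP <- -pc$rho / pc$D^2
  dpdr <- (1 - pc$P) * pc$P / pc$D^2
  L <- diag(-tr$delta, N)
  e <- tr$edges
  nE <- nrow(e)
  dF <- matrix(0, N, nE)
  for (r in seq_len(nE)) {
    j <- e$j[r]; i <- e$i[r]; K <- e$K[r]
    occ1 <- 1 + K * x[i]
    if (e$role[r] == "activator") {
      # dP/dx_i = -P K / occ1 ; dP/dK = -P x_i / occ1
      L[j, i] <- L[j, i] + nu[j] * dpdP[j] * (-pc$P[j] * K / occ1)
      dF[j, r] <- nu[j] * dpdP[j] * (-pc$P[j] * x[i] / occ1)
    } else {
      L[j, i] <- L[j, i] + nu[j] * dpdr[j] * (-pc$rho[j] * K / occ1)
      dF[j, r] <- nu[j] * dpdr[j] * (-pc$rho[j] * x[i] / occ1)
    }
  }
  if (kappa(L) > 1e12) stop("singular steady-state Jacobian")
  list(L = L, dF_dphi = dF, edges = e)
}

#' Adjoint solve for the delta rule
#'
#' Solves \code{t(L) z = x - T}; the single solve serves the gradient of
#' every trainable parameter.
#'
#' @param L steady-state Jacobian
#' @param residual vector \code{x - T}
#' @return adjoint vector \code{z}
#' @export
adjoint_solve <- function(L, residual) {
  solve(t(L), residual)
}

#' One delta-rule parameter update
#'
#' \code{delta_phi = eta * (z \%*\% dF_dphi)}; the updated parameters are
#' projected onto \code{phi >= 0}.
#'
#' @param phi current parameter vector
#' @param eta step-size scale
#' @param z adjoint vector from \code{\link{adjoint_solve}}
#' @param dF_dphi sensitivity matrix
#' @return updated parameter vector
#' @export
gradient_step <- function(phi, eta, z, dF_dphi) {
  dphi <- eta * as.numeric(crossprod(z, dF_dphi))
  if (any(!is.finite(dphi))) stop("non-finite parameter update")
  pmax(phi + dphi, 0)
}

#' Training state
#'
#' @param eta initial step-size scale (adapted by backtracking during
#'   training); \code{NULL} picks a conservative default from the data
#' @param bound absolute loss bound for stopping; \code{NULL} uses the
#'   relative floor \code{1e-6 * sum(T^2)}, deep enough that equilibrium
#'   constants are resolved at the 1e-4 pruning threshold
#' @param max_iter iteration cap
#' @return an object of class \code{train_state}
#' @export
train_state <- function(eta = NULL, bound = NULL, max_iter = 2000L) {
  structure(list(eta = eta, bound = bound, max_iter = as.integer(max_iter)),
            class = "train_state")
}

#' Assemble a training set
#'
#' @param conditions list of conditions; each condition is \code{NULL}
#'   (baseline), a \code{\link{knockout_spec}} or a list of them
#' @param targets matrix conditions x measured species of steady-state
#'   levels
#' @return an object of class \code{training_set}
#' @export
training_set <- function(conditions, targets) {
  stopifnot(length(conditions) == nrow(targets), all(targets >= 0))
  structure(list(conditions = conditions, targets = targets),
            class = "training_set")
}

# Normalize a condition: NULL (baseline), a knockout_spec, a list of
# knockout_specs, or a list with elements `knockouts` and/or `inputs`
# (named numeric of input levels).
.parse_condition <- function(condition, gene_names) {
  kos <- list(); inputs <- numeric(0)
  if (inherits(condition, "knockout_spec")) {
    kos <- list(condition)
  } else if (is.list(condition) && length(condition)) {
    if (!is.null(names(condition)) &&
        any(names(condition) %in% c("knockouts", "inputs"))) {
      kos <- condition$knockouts %||% list()
      inputs <- condition$inputs %||% numeric(0)
    } else {
      kos <- condition
    }
  }
  list(ko_idx = vapply(kos, function(k) match(k$gene, gene_names),
                       integer(1)),
       inputs = inputs)
}

# indices of knocked-out genes for a condition
.ko_idx <- function(condition, gene_names) {
  .parse_condition(condition, gene_names)$ko_idx
}

#' Train a network on steady-state measurements
#'
#' Minimizes \code{W = 1/2 sum (x - T)^2} over the gene-gene equilibrium
#' constants by iterating: solve every condition's steady state, assemble
#' the analytic derivatives, one adjoint solve per condition, then a
#' delta-rule update with backtracking step-size control.  Stops when the
#' loss drops below the bound or the iteration cap is hit.
#'
#' @param spec_init starting network (typically fully connected)
#' @param data a \code{\link{training_set}}
#' @param state a \code{\link{train_state}}
#' @param verbose print loss every 50 iterations
#' @return an object of class \code{train_result}: list with
#'   \code{spec} (network with inferred constants), \code{edges}
#'   (edge table with inferred K), \code{K_act}, \code{K_rep}
#'   (N x N matrices), \code{topology} (logical adjacency, pruned at
#'   1e-4), \code{loss_history}, \code{W}, \code{converged}
#' @export
train <- function(spec_init, data, state = train_state(), verbose = FALSE) {
  stopifnot(inherits(data, "training_set"))
  tr <- .trainable(spec_init)
  N <- tr$N
  ncond <- length(data$conditions)
  Tm <- data$targets
  stopifnot(ncol(Tm) == N)

  cond_list <- lapply(data$conditions, .parse_condition,
                      gene_names = tr$genes)
  ko_list <- lapply(cond_list, `[[`, "ko_idx")
  b <- state$bound %||% (1e-6 * sum(Tm^2))
  eta <- state$eta %||% (0.1 / max(tr$nu / tr$delta)^2)

  phi <- tr$edges$K
  loss_of <- function(phi_try, warm) {
    tr2 <- tr; tr2$edges$K <- phi_try
    W <- 0
    xs <- vector("list", ncond)
    for (cc in seq_len(ncond)) {
      trc <- tr2
      trc$nu[ko_list[[cc]]] <- 0
      for (nm in names(cond_list[[cc]]$inputs))
        trc$input_levels[[nm]] <- cond_list[[cc]]$inputs[[nm]]
      x <- .steady_state_tr(trc, x0 = warm[[cc]])
      xs[[cc]] <- x
      W <- W + 0.5 * sum((x - Tm[cc, ])^2)
    }
    list(W = W, xs = xs)
  }

  warm <- vector("list", ncond)
  cur <- loss_of(phi, warm)
  W <- cur$W
  loss_history <- W
  best <- W
  converged <- W < b

  it <- 0L
  while (!converged && it < state$max_iter) {
    it <- it + 1L
    # gradient via one adjoint solve per condition
    g <- numeric(length(phi))
    tr2 <- tr; tr2$edges$K <- phi
    for (cc in seq_len(ncond)) {
      trc <- tr2
      ko <- ko_list[[cc]]
      trc$nu[ko] <- 0
      for (nm in names(cond_list[[cc]]$inputs))
        trc$input_levels[[nm]] <- cond_list[[cc]]$inputs[[nm]]
      x <- cur$xs[[cc]]
      der <- .local_derivatives_tr(trc, x, knocked = ko)
      z <- adjoint_solve(der$L, x - Tm[cc, ])
      g <- g + as.numeric(crossprod(z, der$dF_dphi))
    }
    # backtracking on the summed loss
    accepted <- FALSE
    for (half in 0:40) {
      phi_try <- pmax(phi + eta * g, 0)
      cand <- loss_of(phi_try, cur$xs)
      if (cand$W < W) {
        phi <- phi_try; cur <- cand; W <- cand$W
        eta <- eta * 1.5
        accepted <- TRUE
        break
      }
      eta <- eta / 2
    }
    loss_history <- c(loss_history, W)
    best <- min(best, W)
    if (!accepted) break                       # stuck at a local flat spot
    if (W > 10 * best + 1e-12)
      stop("training diverged; loss history: ",
           paste(sprintf("%.3g", utils::tail(loss_history, 10)), collapse = ", "))
    if (verbose && it %% 50 == 0)
      message(sprintf("iter %d: W = %.6g (eta %.3g)", it, W, eta))
    converged <- W < b
  }

  # rebuild result structures
  edges <- tr$edges; edges$K <- phi
  K_act <- matrix(0, N, N, dimnames = list(tr$genes, tr$genes))
  K_rep <- K_act
  for (r in seq_len(nrow(edges))) {
    if (edges$role[r] == "activator") K_act[edges$j[r], edges$i[r]] <- edges$K[r]
    else K_rep[edges$j[r], edges$i[r]] <- edges$K[r]
  }
  spec_out <- spec_init
  for (j in seq_len(N)) {
    for (bi in seq_along(spec_out$genes[[j]]$bindings)) {
      bnd <- spec_out$genes[[j]]$bindings[[bi]]
      i <- match(bnd$tf, tr$genes)
      if (!is.na(i)) {
        K <- if (bnd$role == "activator") K_act[j, i] else K_rep[j, i]
        spec_out$genes[[j]]$bindings[[bi]]$lambda0 <- K * bnd$mu
      }
    }
  }
  structure(list(spec = spec_out, edges = edges, K_act = K_act, K_rep = K_rep,
                 topology = (pmax(K_act, K_rep) > 1e-4),
                 loss_history = loss_history, W = W,
                 converged = converged, bound = b),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("trained network: %d iterations, final W = %.4g (bound %.4g, %s)\n",
              length(x$loss_history) - 1L, x$W, x$bound,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("edges above the 1e-4 pruning threshold: %d\n", sum(x$topology)))
  invisible(x)
}

# --- benchmark -------------------------------------------------------------

#' Generate a randomized ground-truth network
#'
#' Starts from the fully connected digraph on \code{n_genes} genes
#' (\code{N (N-1)} ordered pairs), deletes each connection independently
#' with probability \code{p_delete}, draws each surviving equilibrium
#' constant log-uniformly from \code{k_range} and assigns the edge an
#' activating or repressing role.  Every gene additionally carries a weak
#' constitutive basal activator site so that expression never collapses
#' to zero.
#'
#' @param n_genes number of genes (>= 2)
#' @param p_delete per-edge deletion probability in [0, 1)
#' @param k_range range of equilibrium constants (log-uniform)
#' @param seed RNG seed
#' @param p_activator probability that a surviving edge activates
#' @param nu,delta fixed synthesis and degradation rates (known during
#'   inference)
#' @param mu fixed TF dissociation rate defining K = lambda0/mu
#' @param basal_k equilibrium constant of the constitutive basal site
#' @return a \code{\link{network_spec}}
#' @export
generate_ground_truth <- function(n_genes, p_delete = 0.5,
                                  k_range = c(1e-3, 1e-2), seed = 1L,
                                  p_activator = 0.5, nu = 1, delta = 0.01,
                                  mu = 1, basal_k = 0.25) {
  stopifnot(n_genes >= 2, p_delete >= 0, p_delete < 1)
  set.seed(seed)
  gene_names <- sprintf("g%d", seq_len(n_genes))
  pairs <- expand.grid(i = seq_len(n_genes), j = seq_len(n_genes))
  pairs <- pairs[pairs$i != pairs$j, ]
  keep <- stats::runif(nrow(pairs)) >= p_delete
  K <- exp(stats::runif(nrow(pairs), log(k_range[1]), log(k_range[2])))
  # every ordered pair carries a regulatory sign, deleted or not, so a
  # training network can start fully connected with known signs
  role <- ifelse(stats::runif(nrow(pairs)) < p_activator,
                 "activator", "repressor")
  roles <- matrix(NA_character_, n_genes, n_genes,
                  dimnames = list(gene_names, gene_names))
  roles[cbind(pairs$j, pairs$i)] <- role
  genes <- lapply(seq_len(n_genes), function(j) {
    bnd <- list(tf_binding("basal", lambda0 = basal_k * mu, mu = mu,
                           role = "activator"))
    sel <- which(keep & pairs$j == j)
    for (r in sel)
      bnd <- c(bnd, list(tf_binding(gene_names[pairs$i[r]],
                                    lambda0 = K[r] * mu, mu = mu,
                                    role = role[r])))
    gene_spec(gene_names[j], logic = "or", bindings = bnd,
              nu = nu, delta = delta)
  })
  spec <- network_spec(
    inputs = list(input_spec("basal", "constant", amplitude = 1)),
    genes = genes)
  attr(spec, "roles") <- roles
  spec
}

#' Fully connected starting network for training
#'
#' Instantiates one binding per ordered gene pair at a common initial
#' equilibrium constant; training drives unneeded constants towards zero.
#' The regulatory sign of each potential connection is taken as known:
#' either from a roles matrix (as attached by
#' \code{\link{generate_ground_truth}}) or uniformly activating.  With
#' \code{signs_known = FALSE} both an activating and a repressing binding
#' are instantiated per pair instead, leaving the signs to be sorted out
#' by training (twice the parameters, and with N^2 knockout measurements
#' generally under-determined).
#'
#' @param n_genes number of genes
#' @param init_k initial equilibrium constant of every edge
#' @param roles character matrix (target x source) of edge signs; default
#'   all \code{"activator"}
#' @param signs_known instantiate one signed binding per pair (default)
#'   or both signs
#' @inheritParams generate_ground_truth
#' @return a \code{\link{network_spec}}
#' @export
fully_connected_network <- function(n_genes, init_k = 1e-3, roles = NULL,
                                    signs_known = TRUE, nu = 1,
                                    delta = 0.01, mu = 1, basal_k = 0.25) {
  gene_names <- sprintf("g%d", seq_len(n_genes))
  if (is.null(roles))
    roles <- matrix("activator", n_genes, n_genes)
  genes <- lapply(seq_len(n_genes), function(j) {
    bnd <- list(tf_binding("basal", lambda0 = basal_k * mu, mu = mu,
                           role = "activator"))
    for (i in seq_len(n_genes)[-j]) {
      if (signs_known) {
        bnd <- c(bnd, list(tf_binding(gene_names[i], init_k * mu, mu,
                                      roles[j, i])))
      } else {
        bnd <- c(bnd,
                 list(tf_binding(gene_names[i], init_k * mu, mu, "activator"),
                      tf_binding(gene_names[i], init_k * mu, mu, "repressor")))
      }
    }
    gene_spec(gene_names[j], logic = "or", bindings = bnd,
              nu = nu, delta = delta)
  })
  network_spec(inputs = list(input_spec("basal", "constant", amplitude = 1)),
               genes = genes)
}

#' Single-gene-knockout training data from a ground-truth network
#'
#' Knocks out each gene in turn and records the steady-state levels of
#' all genes: N^2 measurements for N genes.
#'
#' @param truth a \code{\link{network_spec}}
#' @param residual_nu residual synthesis rate of the knocked-out gene
#' @return a \code{\link{training_set}}
#' @export
knockout_dataset <- function(truth, residual_nu = 0) {
  gene_names <- vapply(truth$genes, `[[`, character(1), "product")
  N <- length(gene_names)
  conditions <- lapply(gene_names, knockout_spec, residual_nu = residual_nu)
  targets <- matrix(NA_real_, N, N, dimnames = list(gene_names, gene_names))
  for (cc in seq_len(N))
    targets[cc, ] <- steady_state(truth, conditions[[cc]])
  training_set(conditions, targets)
}

#' Score an inferred topology against the ground truth
#'
#' A connection (ordered gene pair) counts as inferred when either of its
#' equilibrium constants exceeds the pruning threshold.  The true-positive
#' fraction is relative to the ground-truth connections, the headline
#' false-positive fraction relative to the pairs absent from the truth
#' (the fraction relative to all possible pairs is also reported).
#' Relative errors of the constants are computed on correctly recovered
#' connections using the true edge's role.
#'
#' @param result a \code{train_result}
#' @param truth the generating \code{\link{network_spec}}
#' @param threshold pruning threshold (default 1e-4)
#' @return list with \code{tp_frac}, \code{fp_frac}, \code{fp_frac_all},
#'   \code{rel_errors} and counts
#' @export
evaluate_topology <- function(result, truth, threshold = 1e-4) {
  tr <- .trainable(truth)
  N <- tr$N
  true_adj <- matrix(FALSE, N, N)
  for (r in seq_len(nrow(tr$edges)))
    true_adj[tr$edges$j[r], tr$edges$i[r]] <- TRUE
  called <- pmax(result$K_act, result$K_rep) > threshold
  diag(called) <- FALSE
  off <- !diag(TRUE, N)
  tp <- sum(called & true_adj)
  fp <- sum(called & !true_adj & off)
  n_true <- sum(true_adj)
  n_absent <- sum(!true_adj & off)
  rel <- numeric(0)
  for (r in seq_len(nrow(tr$edges))) {
    j <- tr$edges$j[r]; i <- tr$edges$i[r]
    if (!called[j, i]) next
    K_inf <- if (tr$edges$role[r] == "activator") result$K_act[j, i]
             else result$K_rep[j, i]
    rel <- c(rel, abs(K_inf - tr$edges$K[r]) / tr$edges$K[r])
  }
  list(tp_frac = if (n_true) tp / n_true else NA_real_,
       fp_frac = if (n_absent) fp / n_absent else NA_real_,
       fp_frac_all = fp / sum(off),
       rel_errors = rel,
       n_true = n_true, n_absent = n_absent, tp = tp, fp = fp)
}

#' Run the randomized knockout-inference benchmark
#'
#' For each of \code{n_networks} seeds: generate a random ground truth,
#' simulate its N^2 knockout measurements, train a fully connected
#' network on them and score the recovered topology and constants.
#'
#' @param n_genes genes per network
#' @param p_delete edge deletion probability of the ground truth
#' @param n_networks number of independent networks
#' @param seed master seed
#' @param init_k starting equilibrium constant of the trained network
#' @param max_iter training iteration cap
#' @param ... further arguments to \code{\link{generate_ground_truth}}
#' @return data.frame with one row per network: tp_frac, fp_frac,
#'   mean_rel_error, final loss and iterations
#' @export
run_inference_benchmark <- function(n_genes = 5, p_delete = 0.5,
                                    n_networks = 4, seed = 1L,
                                    init_k = 1e-3, max_iter = 2000L, ...) {
  out <- data.frame()
  for (m in seq_len(n_networks)) {
    truth <- generate_ground_truth(n_genes, p_delete = p_delete,
                                   seed = seed + 7919L * m, ...)
    data <- knockout_dataset(truth)
    init <- fully_connected_network(n_genes, init_k = init_k,
                                    roles = attr(truth, "roles"))
    res <- train(init, data, train_state(max_iter = max_iter))
    sc <- evaluate_topology(res, truth)
    out <- rbind(out, data.frame(
      network = m, tp_frac = sc$tp_frac, fp_frac = sc$fp_frac,
      mean_rel_error = mean(sc$rel_errors),
      W = res$W, converged = res$converged,
      iterations = length(res$loss_history) - 1L))
  }
  out
}
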