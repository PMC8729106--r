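# Steady states, analytic gradients and the delta-rule training loop.

test_that("steady states solve the rate equations under any condition", {
  # one gene with only the basal site: p_on is constant
  net1 <- generate_ground_truth(2, p_delete = 0.999, seed = 3)
  x <- steady_state(net1)
  p_basal <- 0.25 / 1.25 # K 0.25, one copy -> occupancy/(1+occupancy)
  expect_equal(unname(x), rep(p_basal * 1 / 0.01, 2), tolerance = 1e-6)
  # cascade of regulation: residual derivative is tiny at the fix point
  truth <- generate_ground_truth(5, p_delete = 0.4, seed = 17)
  xs <- steady_state(truth)
  der <- local_derivatives(truth, xs)
  expect_true(all(is.finite(der$L)))
  # knocked-out gene sits at zero
  xko <- steady_state(truth, knockout_spec("g2"))
  expect_equal(unname(xko["g2"]), 0)
  expect_false(isTRUE(all.equal(unname(xko["g1"]), unname(xs["g1"]))))
})

test_that("analytic Jacobian and parameter sensitivities match finite differences", {
  for (sd in c(11, 29)) {
    truth <- generate_ground_truth(5, p_delete = 0.5, seed = sd)
    tr <- grnsync:::.trainable(truth)
    x <- steady_state(truth)
    der <- grnsync:::.local_derivatives_tr(tr, x)
    Ffun <- function(tr2, xx) {
      p <- grnsync:::.p_on_pieces(tr2, xx)$p_on
      tr2$nu * p - tr2$delta * xx
    }
    N <- tr$N
    for (k in seq_len(N)) {
      hh <- 1e-6 * max(1, abs(x[k]))
      xp <- x; xm <- x
      xp[k] <- xp[k] + hh; xm[k] <- xm[k] - hh
      fd <- (Ffun(tr, xp) - Ffun(tr, xm)) / (2 * hh)
      expect_lt(max(abs(der$L[, k] - fd)), 1e-4 * max(abs(fd), 1e-6))
    }
    for (r in seq_len(nrow(tr$edges))) {
      hh <- 1e-6 * tr$edges$K[r]
      trp <- tr; trm <- tr
      trp$edges$K[r] <- trp$edges$K[r] + hh
      trm$edges$K[r] <- trm$edges$K[r] - hh
      fd <- (Ffun(trp, x) - Ffun(trm, x)) / (2 * hh)
      expect_lt(max(abs(der$dF_dphi[, r] - fd)), 1e-4 * max(abs(fd)))
    }
  }
})

test_that("the adjoint solve serves every parameter with one linear system", {
  # diagonal Jacobian: componentwise division
  L <- diag(c(-2, -4, -5))
  res <- c(1, 2, 3)
  expect_equal(adjoint_solve(L, res), res / c(-2, -4, -5))
  # zero residual, zero adjoint, unchanged parameters
  expect_equal(adjoint_solve(L, c(0, 0, 0)), c(0, 0, 0))
  phi <- c(0.1, 0.2)
  expect_equal(gradient_step(phi, 0.5, c(0, 0, 0), matrix(1, 3, 2)), phi)
  # random well-conditioned system: residual check
  set.seed(12)
  L5 <- diag(5) * 3 + matrix(stats::rnorm(25, sd = 0.3), 5, 5)
  z <- adjoint_solve(L5, 1:5)
  expect_lt(max(abs(t(L5) %*% z - 1:5)), 1e-10)
  # projection to non-negative parameters
  expect_equal(gradient_step(c(0.1, 0.1), 1, c(-1), matrix(c(1, 0.05), 1, 2)),
               c(0, 0.05))
})

test_that("a delta-rule step decreases the loss for small enough eta", {
  truth <- generate_ground_truth(3, p_delete = 0.3, seed = 5)
  data <- knockout_dataset(truth)
  init <- fully_connected_network(3, init_k = 2e-3,
                                  roles = attr(truth, "roles"))
  st <- train_state(max_iter = 1L, bound = 0)
  res <- train(init, data, st)
  expect_lt(utils::tail(res$loss_history, 1), res$loss_history[1])
})

test_that("training recovers parameters and terminates on self-consistent data", {
  # input element + two genes measured under two input levels: gene 1 is
  # activated by the input and by gene 2's product; gene 2 by gene 1's
  mk <- function(K12, K21) network_spec(
    inputs = list(input_spec("basal", "constant", amplitude = 1),
                  input_spec("I", "constant", amplitude = 20)),
    genes = list(
      gene_spec("g1", "or",
                bindings = list(tf_binding("basal", 0.25, 1, "activator"),
                                tf_binding("I", 0.05, 1, "activator"),
                                tf_binding("g2", K12, 1, "activator")),
                nu = 1, delta = 0.01),
      gene_spec("g2", "or",
                bindings = list(tf_binding("basal", 0.25, 1, "activator"),
                                tf_binding("g1", K21, 1, "activator")),
                nu = 1, delta = 0.01)))
  truth <- mk(4e-3, 8e-3)
  conds <- list(list(inputs = c(I = 20)), list(inputs = c(I = 80)))
  targets <- do.call(rbind, lapply(conds, steady_state, spec = truth))
  data <- training_set(conds, targets)
  # truth as init: immediate convergence, no movement
  res0 <- train(truth, data, train_state(max_iter = 50))
  expect_true(res0$converged)
  expect_lte(length(res0$loss_history), 2)
  # constants mis-specified by a factor 10 are pulled back within 5%
  res <- train(mk(4e-2, 8e-2), data, train_state(max_iter = 4000))
  expect_true(res$converged)
  expect_lt(abs(res$K_act[1, 2] - 4e-3) / 4e-3, 0.05)
  expect_lt(abs(res$K_act[2, 1] - 8e-3) / 8e-3, 0.05)
})

test_that("ground-truth generation honours its statistical contract", {
  full <- generate_ground_truth(5, p_delete = 0, seed = 2)
  tr_full <- grnsync:::.trainable(full)
  expect_equal(nrow(tr_full$edges), 20)           # N (N-1)
  expect_true(all(tr_full$edges$K >= 1e-3 & tr_full$edges$K <= 1e-2))
  # deletion thins edges binomially
  set.seed(1)
  counts <- vapply(1:30, function(s)
    nrow(grnsync:::.trainable(
      generate_ground_truth(5, p_delete = 0.7, seed = 1000 + s))$edges),
    numeric(1))
  expect_lt(abs(mean(counts) - 20 * 0.3), 3 * sqrt(20 * 0.3 * 0.7 / 30))
  # a full role matrix is attached for sign-aware training
  expect_true(all(!is.na(attr(full, "roles")[!diag(5) == 1])))
})

test_that("knockout datasets have N^2 deterministic measurements", {
  truth <- generate_ground_truth(3, p_delete = 0.5, seed = 21)
  d1 <- knockout_dataset(truth)
  expect_equal(dim(d1$targets), c(3L, 3L))
  for (g in 1:3) expect_equal(unname(d1$targets[g, g]), 0)
  d2 <- knockout_dataset(generate_ground_truth(3, p_delete = 0.5, seed = 21))
  expect_identical(d1$targets, d2$targets)
})

test_that("topology scoring counts connections and errors correctly", {
  truth <- generate_ground_truth(4, p_delete = 0.5, seed = 33)
  tr <- grnsync:::.trainable(truth)
  # perfect result: rebuild K matrices from the truth itself
  K_act <- matrix(0, 4, 4); K_rep <- matrix(0, 4, 4)
  for (r in seq_len(nrow(tr$edges))) {
    if (tr$edges$role[r] == "activator")
      K_act[tr$edges$j[r], tr$edges$i[r]] <- tr$edges$K[r]
    else K_rep[tr$edges$j[r], tr$edges$i[r]] <- tr$edges$K[r]
  }
  perfect <- structure(list(K_act = K_act, K_rep = K_rep),
                       class = "train_result")
  sc <- evaluate_topology(perfect, truth)
  expect_equal(sc$tp_frac, 1)
  expect_equal(sc$fp_frac, 0)
  expect_equal(max(sc$rel_errors), 0)
  # empty result
  none <- structure(list(K_act = K_act * 0, K_rep = K_rep * 0),
                    class = "train_result")
  sc0 <- evaluate_topology(none, truth)
  expect_equal(sc0$tp_frac, 0)
  expect_equal(sc0$fp_frac, 0)
})
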