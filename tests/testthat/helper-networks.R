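# Small fixture builders shared across test files.

single_gene_net <- function(lambda0 = 0.01, mu = 1, nu = 0.5, delta = 0.01,
                            input = 100, ...) {
  network_spec(
    inputs = list(input_spec("A", "constant", amplitude = input)),
    genes = list(gene_spec("X", "single",
                           bindings = list(tf_binding("A", lambda0, mu,
                                                      "activator")),
                           nu = nu, delta = delta, ...)))
}

# always-on gene: constitutive promoter without repressors
constitutive_gene_net <- function(nu = 0.5, delta = 0.01, ...) {
  network_spec(genes = list(
    gene_spec("X", "constitutive", bindings = list(),
              nu = nu, delta = delta, ...)))
}

# stationary mean/var of one species over replicate seeded runs
replicate_stats <- function(fn, seeds) {
  m <- vapply(seeds, function(s) {
    st <- fn(s)
    c(st$mean, st$var)
  }, numeric(2))
  list(mean = mean(m[1, ]), se_mean = stats::sd(m[1, ]) / sqrt(ncol(m)),
       var = mean(m[2, ]), se_var = stats::sd(m[2, ]) / sqrt(ncol(m)))
}

# |a - b| within k combined standard errors
within_se <- function(a, b, se_a, se_b, k = 3) {
  abs(a - b) <= k * sqrt(se_a^2 + se_b^2) + 1e-12
}
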