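Package: grnsync
Title: Hybrid Stochastic-Deterministic Simulation and Inference of Gene
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates gene regulatory networks by advancing each network
    element (genes with two-state promoters, bimolecular reactions,
    signalling inputs) in isolation over a short synchronization interval
    using local analytical or stochastic solutions, then exchanging
    molecule numbers and fluxes network-wide.  Three nested scenarios add
    increasing stochastic detail: deterministic mean-field dynamics,
    stochastic promoter on/off switching, and discrete stochastic
    birth/death of gene products.  Includes exact Gillespie and global
    ODE reference solvers for validation, trajectory statistics
    (histograms, autocorrelation, power spectra, bimodality), and a
    recurrent-network delta-rule gradient method that infers promoter
    equilibrium constants and network topology from steady-state
    knockout expression measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    Rcpp,
    deSolve,
    graphics,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
NeedsCompilation: yes
Config/testthat/edition: 3
RoxygenNote: 7.3.3
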