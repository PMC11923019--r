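Package: hhsoc
Title: Stochastic Optimal Control for Desynchronizing Noisy Neural Oscillators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Energy-optimal phase-resetting control for noisy neural
    oscillators. Implements a reduced two-dimensional Hodgkin-Huxley neuron
    model, a backward-in-time solver for the stochastic
    Hamilton-Jacobi-Bellman equation (fifth-order WENO reconstruction with a
    local Lax-Friedrichs numerical Hamiltonian and an implicit tridiagonal
    treatment of the diffusion term), extraction of the saturated optimal
    feedback law from the value function, Honeycutt second-order stochastic
    Runge-Kutta integration of the controlled neuron SDE, and event-based
    desynchronization of populations of electrotonically coupled noisy
    neurons, with Monte-Carlo drivers comparing the energy consumption of
    stochastic and deterministic control policies on homogeneous,
    heterogeneous and sparse networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
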