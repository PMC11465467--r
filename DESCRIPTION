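Package: rpsse
Title: Radical-Pair Spin Dynamics with the Stochastic Schrodinger Equation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates spin-selective reaction yields of radical pairs by
    state-vector propagation under the stochastic Schrodinger equation.
    Spin systems with two electrons and arbitrary spin-1/2 and spin-1
    nuclei are assembled from Zeeman, hyperfine, exchange and dipolar
    interactions; reaction kinetics follow the Haberkorn scheme with
    spin-state-selective, possibly time-dependent, rate coefficients.
    Quantum yields are evaluated either directly (propagating every
    nuclear basis state) or by Monte-Carlo trace sampling with SU(Z)
    coherent states, with a tail correction that shortens the required
    integration time for symmetric rates. Time-dependent interactions
    can be driven analytically (harmonically modulated inter-radical
    distance) or fed from tensor trajectories such as those derived from
    molecular-dynamics simulations; an Ornstein-Uhlenbeck generator
    produces synthetic fluctuating tensors. A dense Liouville-von Neumann
    integrator serves as a reference solver for small systems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    deSolve,
    methods,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
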