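Package: evomanifold
Title: Closed-Loop Neuronal Image Evolution on Dual Generative Manifolds
Version: 0.1.0
Authors@R:
    person("Evomanifold", "Developers", email = "evomanifold@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how visually tuned neurons align with
    contrasting generative image manifolds. Provides two synthetic image
    generators with opposite priors (a flexible linear texture dictionary
    and a constrained parametric object scene), inhomogeneous-Poisson
    spiking neuron models with early and late temporal feature
    preferences, a CMA-ES optimizer driving paired closed-loop evolution
    threads, alignment metrics (hill-climbing success, normalized
    trajectories, Gaussian-process convergence times, per-generation win
    rates), peri-stimulus time histogram dynamics and attribution,
    pullback-metric Hessian tuning landscapes with distance-matched line
    search and bell/ramp tuning-curve classification, spatial attribution
    masks from local feature regressions, and session serialization with
    a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
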