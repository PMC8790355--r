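Package: sddfinite
Title: Synthesis-Diffusion-Degradation Morphogen Gradients on Finite Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact transient and steady-state solutions of the one-dimensional
    synthesis-diffusion-degradation (reaction-diffusion) morphogen model on
    finite and infinite domains, with absorbing (sink) or reflecting (no-flux)
    tissue-tip boundary conditions. Provides eigenfunction series evaluation of
    the transient gradients, gradient-shape statistics (the 10-percent decay
    position and the crossover tissue size separating finite- and
    infinite-domain regimes), mean and standard deviation of the time to reach
    steady state via the relaxation-function method, in-silico fluorescence
    recovery after photobleaching (FRAP) with characteristic-length fitting,
    finite- versus infinite-domain error maps, an independent Crank-Nicolson
    finite-difference solver used as a numerical oracle, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
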