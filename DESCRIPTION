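Package: cotuner
Title: Lateral Inhibition and Co-Tuning in a Fixed Cortical Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how the spatial spread of
    thalamic drive moves a fixed cortical circuit between lateral-inhibitory and
    co-tuned excitation/inhibition configurations. Implements a two-dimensional
    sheet of adaptive exponential integrate-and-fire pyramidal and fast-spiking
    cells with alpha-conductance synapses, Tsodyks-Markram short-term plasticity
    and Gaussian distance-dependent wiring; a reduced threshold-linear feedforward
    model of excitatory and inhibitory tuning widths; and a one-dimensional
    Wilson-Cowan-style spatial firing-rate model with Naka-Rushton transfer.
    Analysis helpers compute post-stimulus time histograms, radial conductance and
    spike-count profiles, half-width (FWHM) ratios, two-tone suppression curves,
    gain-slope summaries and stimulus-intensity response trajectories, all as
    tidy tibbles with ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
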