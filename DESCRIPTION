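Package: ionshift
Title: Ion-Based Hodgkin-Huxley Neuron Models, Bistability and Ionic
    Excitability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Minimal ion-based neuron models of the Hodgkin-Huxley family
    with dynamic intra- and extracellular ion concentrations, Na+/K+-ATPase
    pump models, Nernst or Goldman-Hodgkin-Katz membrane currents, optional
    chloride and gated channels, and diffusive coupling of extracellular
    potassium to a glial/vascular bath.  Provides stiff time integration of
    stimulation protocols with spike and depolarization-event detection,
    fixed-point location with linear stability analysis, pseudo-arclength
    continuation of equilibria in the maximal pump rate with limit-point and
    Hopf detection, two-parameter continuation over cell-geometry scalings,
    and scenario harnesses that map the bistability of physiological and
    free-energy-starved states and the excitability of ion homeostasis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
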