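Package: ttmyo
Title: Human Ventricular Cardiomyocyte Model with Restricted Extracellular Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic ODE model of a human ventricular cardiomyocyte in
    which the extracellular medium is resolved into a nine-shell t-tubular
    lumen, a single intercellular cleft layer and an infinite bulk reservoir,
    so that activity-dependent accumulation and depletion of Ca2+, K+ and Na+
    in the restricted spaces feeds back on sarcolemmal ion transport,
    the action potential and the cytosolic Ca2+ transient. Provides a compiled
    right-hand side integrated with stiff solvers, pacing and frequency-step
    protocols with clamp modes for the extracellular compartments, per-cycle
    metrics (APD50/APD90, Ca2+-transient integrals, net per-cycle Ca2+ flux
    per membrane pool, end-diastolic series, exponential time-constant fits)
    and tidy tabular results with plotting methods.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
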