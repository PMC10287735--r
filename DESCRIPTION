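Package: pulsepest
Title: Impulsive Pest-Epidemic Dynamics with Pulse Vaccination and
    Environmental Disinfection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a six-compartment pest epidemic driven by an
    environmental virus reservoir under periodic impulsive control: a fixed
    fraction of susceptibles is vaccinated and a fixed fraction of the
    free-living virus is destroyed at every pulse. Provides the hybrid
    (flow-plus-jump) integrator with a fixed-step verification oracle, the
    closed-form infection-free periodic orbit, every attractivity and
    permanence threshold the model admits (with explicit variants where the
    published formulas disagree), permanence floors, critical pulse periods
    and critical vaccination fractions, extinction/permanence regime
    classification, built-in benchmark scenarios and parameter sweeps.
    Trajectories, summaries and reports are tibbles; results have tidy(),
    glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
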