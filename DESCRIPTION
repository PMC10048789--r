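Package: safetysd
Title: System Dynamics Simulation of Safety Culture, Management and
    Unsafe Acts in Coal Mines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A deterministic stock-and-flow simulation of how an
    enterprise safety system drives (un)safe acts in coal mines. The
    model couples three organisational and individual layers -- safety
    culture, the safety management system (policy, organisational
    structure, procedures) and individual safety ability (knowledge,
    awareness, habits, psychology) -- through saturating uptake rates,
    first-order material delays and a negative behavioural feedback
    loop. Layer weights are estimated from accident-cause frequency
    records over the 24Model cause taxonomy, and a synthetic accident
    generator emulates such records as Poisson-multinomial draws.
    Scenario tools reproduce new-mine and production-mine experiments
    over construction-standard (AV) and initial-safety-level (HV)
    grids and rank the influence of layers and elements on safe acts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
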