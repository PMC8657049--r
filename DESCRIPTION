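Package: operisk
Title: Liver-Based Probabilistic Risk Assessment of Organophosphate Esters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic, liver-based health risk assessment of the
    organophosphate ester flame retardants triphenyl phosphate (TPHP) and
    tris(1,3-dichloro-2-propyl) phosphate (TDCPP) via dust ingestion. A
    seven-compartment, flow-limited physiologically based toxicokinetic
    (PBTK) model is solved analytically (with an ODE-integration oracle) for
    liver steady-state concentrations over seeded Monte Carlo virtual
    populations of children and adults. Reverse dosimetry converts in vitro
    hepatocyte AC50 bioactivity values to human equivalent dose (HED)
    distributions, which are compared with population-specific estimated
    daily intakes to give tiered margin-of-exposure (MOE) assessments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
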