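Package: minesd
Title: Stock-Flow System Dynamics of Coal-Mining-Area Environmental Management
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A discrete-time stock-flow system dynamics engine (levels, rates,
    auxiliaries, constants; fixed-step Euler integration) together with a
    five-subsystem model of the ecological environment of a coal mining area:
    air pollution, solid waste, water pollution, vegetation destruction and
    land damage stocks driven by monthly production constants and drained by
    treatment flows funded from a fixed environmental investment split by an
    allocation policy. Includes the system's signed causal loop diagram with
    elementary feedback-loop enumeration and polarity classification,
    allocation scenario experiments with an environmental quality assessment
    against the zero-investment baseline, one-at-a-time sensitivity analysis,
    plain-text configuration and result files, and a command-line interface.
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
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
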