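Package: psicascade
Title: Kinetics and Process Evaluation of the Two-Enzyme Rearrangement of
    UMP into Pseudouridine 5'-Phosphate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the kinetic analysis of the nucleosidase (PpnN and its
    R341A-Y347A variant, "RY") plus C-glycosidase (YeiN) cascade that
    rearranges uridine 5'-phosphate (UMP) into pseudouridine 5'-phosphate.
    Implements the Michaelis-Menten rate law with competitive product
    inhibition by D-ribose 5-phosphate, ODE models of single-enzyme UMP
    hydrolysis and of the coupled one-pot cascade, parameter estimation from
    initial rates and from progress curves (including single-parameter Ki
    fitting), a synthetic-data generator with a multiplicative noise model,
    and biocatalytic process metrics (yield, titer, space-time yield,
    mass-based total turnover number, E-factor, scale-up volume) with a
    route-comparison table checker.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
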