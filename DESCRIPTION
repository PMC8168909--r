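Package: trophos
Title: Proteome Allocation and the Rate-Affinity Trade-Off of Bacterial
    Nutrient Transport
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mechanistic models of bacterial nutrient uptake by
    phosphotransferase systems (PTS) and periplasmic-binding-protein
    dependent ABC transporters, embedded in a coarse-grained single-cell
    proteome allocation model. Solves the exact steady state of the
    four-step ABC transport scheme, its Michaelis-Menten approximation
    with binding-protein-dependent half-saturation, and a constrained
    multi-start maximisation of the steady-state exponential growth rate
    over proteome fractions, cell radius and periplasmic volume fraction.
    Reproduces the rate-affinity trade-off between copiotroph-like (PTS)
    and oligotroph-like (ABC) cells: growth-rate crossover along a
    nutrient gradient, emergent nanomolar effective half-saturation
    concentrations from micromolar binding-protein dissociation
    constants, surface-area-to-volume differentiation, and
    transport-to-metabolic capacity ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
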