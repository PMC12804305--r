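Package: biodistr
Title: Quantification of Ex Vivo Radiotracer Biodistribution Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for processing ex vivo biodistribution studies of
    radiolabeled tracers in rodent models. Converts weighed syringes,
    counting standards prepared from the injected formulation, and
    gamma-counter counts per minute into decay-corrected percent injected
    dose per gram, standardized uptake values, and target-to-background
    contrast ratios. Includes a radionuclide database with decay
    correction, whole-body effective-half-life fitting with one- and
    two-phase exponential models, Bateman-equation support for
    mother-daughter decay chains of alpha emitters, a seeded generator of
    complete synthetic studies for validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
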