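Package: meioquant
Title: Quantitative Analysis of Meiotic Crossover Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying meiotic crossover (CO) regulation in
    C. elegans germlines. Implements gamma-shape crossover-interference
    estimation from inter-focus or inter-CO distances, crossover mapping
    and ploidy classification in single backcross F2 embryos from
    strain-specific read counts in genomic windows, and 3D image
    quantification of synaptonemal-complex loading, focus detection and
    focus-to-chromosome-trace mapping. A synthetic-data generator with
    recorded ground truth makes every stage verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    minpack.lm,
    graphics,
    lmerTest,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
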