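Package: glycodyn
Title: Dynamic Model of Tumor-Cell Glycolysis, Respiration and
    Glycolytic-Intermediate Buffering
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A coarse-grained kinetic model of tumor-cell energy
    metabolism: a glycolytic head section (glucose transport, hexokinase,
    phosphofructokinase) under delayed feedback inhibition by
    phosphorylated glycolytic intermediates, a lumped tail section,
    oxidative phosphorylation, reversible lactate dehydrogenase, and
    ATP hydrolysis coupled to the adenine nucleotide pool. Reproduces the
    Warburg, Pasteur and Crabtree effects and the fast transients after
    glucose addition to glucose-depleted Ehrlich ascites tumor cells, and
    extends the cell model with cycling blood flow and radial
    oxygen/glucose diffusion (Krogh cylinder) to simulate
    glycolytic-intermediate buffering during cycling hypoxia in tissue,
    plus diffusion gradients in ascites fluid. Includes scenario/parameter
    file I/O, worksheet export, parameter estimation and bootstrap
    uncertainty analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
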