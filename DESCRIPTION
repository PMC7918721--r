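Package: ghostepr
Title: Nanodomain Decomposition of Membrane EPR Spectra by Multi-Run
    Evolutionary Fitting and GHOST Condensation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates first-derivative X-band EPR spectra of fast but
    restricted nitroxide spin probes in laterally heterogeneous membranes
    as superpositions of domain components, each described by an order
    parameter, rotational correlation time, polarity correction factors
    and a broadening constant.  Fits measured spectra with a hybrid
    evolutionary optimizer (real-coded genetic algorithm followed by
    Nelder-Mead refinement) repeated over many independent runs, condenses
    the resulting solution cloud into discrete domain groups (GHOST
    procedure: goodness-of-fit and density filtering, slice-wise group
    detection along the order-parameter axis), and compares domain
    parameters across experimental conditions with replicate-level t
    tests.  Includes a seeded synthetic-spectrum generator so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
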