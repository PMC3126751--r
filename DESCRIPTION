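Package: moietyfit
Title: Moiety-Based Deconvolution of Stable Isotope Mass Isotopologue Distributions
Version: 0.1.0
Authors@R:
    person("Moietyfit", "Developers", email = "moietyfit@example.org", role = c("aut", "cre"))
Description: Deconvolutes 13C mass isotopologue distributions of modular
    metabolites (such as UDP-GlcNAc) into the labeling fractions of their
    biosynthetic subunits under non-steady-state conditions. Provides a
    forward convolution model over user-defined moiety state spaces, natural
    abundance stripping and mole-fraction normalization of raw intensities, a
    hybrid simulated-annealing/genetic optimizer (GAIMS) with replicate
    statistics, AICc-based selection among variant labeling models, and
    exponential kinetic fitting of deconvoluted timecourses. A synthetic-data
    generator emulates FT-ICR-MS isotopologue timecourse experiments with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
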