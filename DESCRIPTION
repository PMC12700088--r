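Package: hifdyn
Title: Dynamic Modelling of HIF-1 and HIF-2 Driven Gene Activation in Hypoxia
Version: 0.1.0
Authors@R:
    person("hifdyn", "developers", email = "hifdyn@example.org",
           role = c("aut", "cre"))
Description: Kinetic modelling of the hypoxia transcriptional response in
    which both HIF-1alpha and HIF-2alpha compete for the constitutive beta
    subunit (HIF-1beta/ARNT) and the resulting heterodimers compete for two
    classes of hypoxia response elements (HRE) in promoter open chromatin.
    Provides the 15-species reaction network and its ODE right-hand side,
    a stiff-capable integrator, ELISA-based absolute-to-relative
    concentration scaling, two-step parameter estimation against hypoxia
    time-series data, HIF-1beta titration and per-gene induction prediction
    from HRE motif counts, a goodness-of-fit statistic for observed versus
    predicted induction, a seeded synthetic-data generator for parameter
    recovery studies, and a command-line interface with TSV/JSON input and
    output plus SBML Level 3 model export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
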