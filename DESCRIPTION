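Package: gliotrials
Title: Go-or-Grow Glioblastoma Growth Simulation and In Silico Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates glioblastoma multiforme growth and invasion on a 2-D
    brain grid with a go-or-grow phenotype switch: stationary proliferative
    cells convert to motile invasive cells under hypoxia, and invasive cells
    move by concentration-driven diffusion and by hypoxia-driven transport up
    the healthy-brain gradient.  An angiogenesis term raises the hypoxic
    threshold with local tumour density; setting it to zero emulates
    anti-angiogenic treatment.  The package converts simulated states into
    virtual magnetic-resonance readouts (FLAIR, high-density tumour, necrosis),
    labels radiologic progression patterns, and runs in-silico clinical trials
    with criterion titration, rate- and motility-reducing interventions,
    spatial mitotic-rate reduction maps (tumour-treating-fields style),
    Kaplan-Meier and log-rank survival analysis, and a population efficacy
    sweep with bi-exponential fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    survival,
    minpack.lm,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
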