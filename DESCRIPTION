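Package: purkinje2c
Title: Two-Compartment Cerebellar Purkinje Neuron Model with
    Dendritic-Tree Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Biophysical simulation of a two-compartment (soma + equivalent
    cylinder dendrite) cerebellar Purkinje neuron: Hodgkin-Huxley gated K+,
    Ca2+ and cation currents, a 13-state Markov resurgent Na+ channel, a
    Goldman-Hodgkin-Katz P-type Ca2+ flux, electrogenic Na+/K+ pumps and
    Na+/Ca2+ exchangers, and intracellular Ca2+/Na+ and extracellular K+
    concentration dynamics, integrated with a fixed 25-microsecond step.
    Includes the equivalent-cylinder dendritic-tree reduction (collapse,
    constant-volume re-lengthening, dendritic correction factor), in-silico
    protocols (Na+/K+ pump block ramp emulating alcohol, BK channel knockout,
    dendritic ERG insertion), spike detection and firing-state segmentation
    (tonic, burst, quiescent, depolarization block), SWC morphology input and
    CSV trace output, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
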