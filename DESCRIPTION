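Package: connectosim
Title: Stochastic Neuronal Population Dynamics on Weighted Structural Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates whole-brain neuronal population dynamics on weighted,
    symmetric structural connectomes. Provides linear-threshold, sigmoidal and
    dynamical mean-field (reduced Wong-Wang) population models integrated with
    an Euler-Maruyama scheme, a built-in 66-region cortical atlas over 998
    regions of interest, GraphML connectome input/output, an atlas-structured
    synthetic connectome generator, focal and diffuse lesion protocols,
    transient current injection emulating transcranial magnetic stimulation,
    global-coupling calibration at the edge of the low-firing-state
    bifurcation, windowed firing-rate summaries and lesion/stimulation
    difference maps, and weighted shortest-path tracing of efferent pathways.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
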