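Package: pearmedia
Title: Modelling and Optimization of Tissue Culture Media for Pear Rootstocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for response-surface modelling and evolutionary optimization
    of in vitro proliferation media for the pear rootstocks Pyrodwarf and
    OHF. Implements a six-factor Box-Behnken experimental design, symbolic
    regression by gene expression programming (Karva-encoded multigenic
    chromosomes, roulette-wheel selection with elitism, root relative squared
    error fitness), radial-basis-function network and multiple linear
    regression baselines, the four model-comparison statistics (RMSE, MARE,
    MBE, Pearson correlation), and a real-coded bound-constrained genetic
    algorithm for locating media compositions that maximize proliferation,
    shoot length and quality or minimize shoot-tip necrosis and
    vitrification. Ships the published per-medium growth data for both
    rootstocks and hard-coded transcriptions of the ten published gene
    expression programming equations, together with a replicate-level
    synthetic data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
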