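Package: tmfcsense
Title: Soil Microbial Fuel Cell Voltage Biosensing and Neuromorphic
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for soil-based terrestrial microbial fuel
    cell (tMFC) biosensors that detect anthropogenic soil contaminants
    from voltage time series. Provides a mixed-effects synthetic data
    generator for treatment-structured voltage traces, stability-window
    detection from grouped slopes, staggered (stride-1) window
    augmentation, four z-score standardization schemes, a software
    emulation of the NM500 neuromorphic chip's restricted-Coulomb-energy
    (RBF) and k-nearest-neighbour classifiers with
    Identified/Uncertain/Unknown confidence binning and four result
    interpreters, linear mixed-effects treatment modelling with
    likelihood-ratio/AIC/BIC comparison and Nakagawa-Schielzeth R2, and a
    scoring layer with General/Identified accuracy, model filters and a
    full settings grid.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Matrix,
    lme4,
    lmerTest,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
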