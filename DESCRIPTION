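Package: hypoxiaNMR
Title: NMR Metabolomics of Tumour Hypoxia: Simulation, Chemometrics,
    Classification and Pathway Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible re-analysis pipeline for 1H-NMR metabolomics of
    breast cancer cells under hypoxia and normoxia. Simulates frequency-domain
    spectra for a 17-metabolite panel from a peak-template library, implements
    spectral post-processing (reference alignment, TMSP scaling, water-region
    removal, asymmetric-least-squares baseline correction, robust-mean
    normalization, fixed-width binning), selects discriminating metabolites by
    PCA loading distance with paired t-test confirmation, computes signed
    median fold changes, evaluates per-time-point linear support vector
    machines with leave-one-out tuning, and builds a metabolome-transcriptome
    KEGG pathway network with shared-metabolite/enzyme edge weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    pracma,
    e1071,
    xml2,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
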