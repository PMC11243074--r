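Package: neuroraman
Title: Chemometric Assessment of Neuronal Activity from Single-Cell Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free assessment of neuronal activity from Raman
    micro-spectra of single neurons and ganglia. Provides a seedable synthetic
    spectrum generator with known band, ligand-effect and dose-response
    structure; spectrum input/output (two-column text, CSV matrices, a
    JCAMP-DX dialect) with sulfur-standard wavenumber calibration; the
    standard preprocessing chain (optional despiking, Savitzky-Golay
    smoothing, iterative polynomial baseline correction, crop and vector
    normalization); PCA and NIPALS PLS-DA with Mahalanobis nearest-centroid
    binomial classification, ROC/AUC and confusion metrics under fold-honest
    cross-validation; and dose-response statistics including delta-F/F
    calcium-trace summaries, responder fractions and a Williams-type
    step-down trend test with Monte-Carlo critical values.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2), methods, SummarizedExperiment
Imports: S4Vectors, stats, utils, tools, signal, e1071, jsonlite, yaml
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'calcium.R'
    'calibration.R'
    'dosestats.R'
    'evaluate.R'
    'geometry.R'
    'neuroraman-package.R'
    'pca.R'
    'pipeline.R'
    'plsda.R'
    'preprocess.R'
    'spectra-io.R'
    'synthgen.R'
    'utils.R'
    'williams.R'
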