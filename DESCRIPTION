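Package: zfscreen
Title: Automated Zebrafish Embryo Cardiotoxicity and Angiogenesis Screening Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image-analysis pipelines for high-throughput chemical screening
    on zebrafish embryos. Heart videos of fluorescent (cmlc2-driven GFP)
    embryonic hearts are turned into a beat frequency and a four-way
    cardiotoxicity call (no effect, bradycardia, 2:1 atrio-ventricular
    arrhythmia, cardiac arrest) by frequency-spectrum analysis of a
    Euclidean-distance motion signal; trunk fluorescence images of the
    vasculature (flk1/fli1-driven GFP) are quantified for anti-angiogenic
    effect by measuring the areas enclosed between the intersegmental
    vessels, the dorsal longitudinal anastomotic vessel and the axial
    vessels, and by counting total and complete intersegmental vessels.
    Includes seeded phantom generators with geometric ground truth for every
    analysis stage, the screening statistics layer (Mann-Whitney, Welch t,
    ANOVA with Monte-Carlo Dunnett adjustment, variable-slope four-parameter
    logistic IC50 fits, ROC thresholding, repeatability CV), and packaged
    validation tables with confusion summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'angio.R'
    'cardio.R'
    'config.R'
    'io.R'
    'morphology.R'
    'phantom.R'
    'plate.R'
    'stats.R'
    'validation.R'
    'zfscreen-package.R'
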