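Package: ProtostaneMS
Title: Annotation and MRM Quantification of Protostane Triterpenoids from
    LC-MS Peak Lists
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Qualitative and quantitative profiling of protostane
    triterpenoids (alisols) in Alismatis Rhizoma from liquid
    chromatography-mass spectrometry peak lists. Provides elemental-formula
    arithmetic and bounded CHO formula enumeration under ppm tolerance,
    neutral-loss annotation of QTOF fragment spectra, rule-based assignment
    of the seven protostane structural types, identification against a
    packaged 25-compound reference library, internal-standard MRM
    calibration and mg/g content back-calculation with LOD/LOQ estimation,
    analytical method-validation statistics (RSD, recovery), batch-level
    content summaries with origin-group comparison, and a synthetic-data
    generator that emulates the instrument with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: MassSpectrometry, Metabolomics, Annotation, Software
RoxygenNote: 7.3.3
Collate: 
    'ProtostaneMS-package.R'
    'ContentMatrix.R'
    'chem-formula.R'
    'neutral-losses.R'
    'feature.R'
    'annotate.R'
    'quant.R'
    'io.R'
    'simulate.R'
    'validate.R'
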