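Package: deltaBind
Title: OLS k-mer Models of Transcription Factor Binding and
    Single-Nucleotide Variant Effect Prediction from Protein-Binding
    Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains ordinary-least-squares models of transcription factor
    (TF) binding specificity on universal protein-binding microarray (uPBM)
    probe intensities, using reverse-complement-collapsed 6-mer counts as
    features, and uses the fitted coefficients together with their estimated
    covariance to predict how single-nucleotide variants change TF binding.
    Each variant is scored with a predicted change in log binding signal, a
    z-score and a P-value from a linear contrast of the regression
    coefficients, and wild-type/mutant sites are classified as bound,
    unbound or ambiguous from 8-mer E-scores. Supports VCF, ICGC simple
    somatic mutation, generic tabular and 17-bp sequence variant inputs,
    precomputed 12-mer prediction tables, and a synthetic uPBM data
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'pbmData.R'
    'bindingStatus.R'
    'kmerIndex.R'
    'featureMatrix.R'
    'olsFit.R'
    'crossValidate.R'
    'simulate.R'
    'variantEffect.R'
    'predictionTable.R'
    'modelIO.R'
    'variantIO.R'
    'report.R'
    'pipeline.R'
    'cli.R'
    'utils.R'
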