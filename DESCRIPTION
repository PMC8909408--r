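Package: peakRating
Title: Feature Rating and Curation for Untargeted LC-MS Peak Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens real features in aligned untargeted LC-MS metabolomics
    peak tables. Within co-eluting, intensity-correlated feature clusters it
    flags top-rated features (TRFs) by detecting the fixed m/z differences
    expected between adduct forms of one molecule, removes in-source fragments
    whose MS1 m/z reappears as an MS2 peak of a heavier cluster mate,
    classifies the surviving isolated quasi-molecular ions as second-rated
    features (SRFs), and selects the most intense TRF per adduct-correlation
    group for the final peak table. Includes a minimal upstream prefilter
    (internal-standard normalisation, blank and within-class RSD filters,
    Pearson/retention-time feature clustering), readers and writers for the
    MS-DIAL alignment-export dialect, and a synthetic peak-table generator
    with planted ground truth for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'adducts.R'
    'fragments.R'
    'io.R'
    'peakRating-package.R'
    'rater.R'
    'prefilter.R'
    'pipeline.R'
    'score.R'
    'simulate.R'
    'utils.R'
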