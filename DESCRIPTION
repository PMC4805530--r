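Package: scL1audit
Title: Auditing Single-Cell Somatic L1 Retrotransposition Call Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reanalysis toolkit for auditing single-cell somatic LINE-1 (L1)
    retrotransposition call sets produced from whole-genome-amplified single
    cells. Provides gold-standard germline insertion calibration, per-sample
    read-count histograms and two-component mixture modelling with EM,
    read-count threshold calibration, allelic-dropout sensitivity correction
    and chimera-adjusted somatic insertion rate estimation, junction-detection
    statistics, a rule engine classifying candidate contigs as amplification
    chimeras, single-cell amplification-uniformity QC (equal-read binning,
    MAPD, MDAD, Lorenz/Gini, Welch power spectral density, subsampling,
    sex-chromosome corrections), and a closed-form detection-theory calculator
    for bulk versus single-cell somatic mutation detection. A synthetic-data
    module generates call tables, coverage tracks and annotated candidate
    contigs with ground-truth labels so the whole workflow runs end-to-end
    without access to restricted datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
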