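Package: glycoforms
Title: Quantitative Analysis of Intact Glycopeptide Profiling Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of multiplexed intact glycopeptide
    quantification experiments: parsing and hierarchical classification of
    glycan compositions, database filtering rules, ingestion of open-search
    PSM exports, collapsing to unique glycopeptides, reporter-channel leak
    masking, normalization and protein-abundance correction (regression and
    ratio variants), moderated differential abundance, site
    microheterogeneity statistics, within-protein glycosylation-profile
    similarity with a permutation null, tissue-specificity scoring,
    surface-exposure classification, neural-gas clustering of kinetic
    profiles, glycoform solubility differentials, thermal-profile delta-AUC,
    and a synthetic-data generator with full ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
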