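Package: semarkr
Title: Stage-Specific Marker Gene Discovery for Somatic Embryogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering tissue- and stage-specific marker genes of
    plant somatic embryogenesis from bulk transcriptome FPKM tables and for
    verifying them by RT-qPCR. Implements rule-based differential-expression
    filtering (minimum-FPKM and fold-ratio criteria over six tissues), subset
    and overlap accounting, annotation coverage and candidate selection with
    E-value thresholds, standard-curve efficiency QC, Livak 2^-ddCt relative
    quantification with ANOVA/Tukey compact letter displays, hierarchical
    clustering of expression profiles, and a synthetic-data generator with
    planted ground truth so the whole pipeline can be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    grDevices,
    jsonlite,
    pheatmap,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
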