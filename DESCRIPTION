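Package: tmtpipe
Title: Multi-Batch TMT Proteomics Differential Expression Pipeline
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis pipeline for multi-batch isobaric TMT
    proteomics case-control studies. Implements master-pool reference
    normalization, per-protein median scaling, log2/z-score transforms,
    missing-value filtering, and parametric empirical-Bayes location-scale
    batch correction; quality-control metrics (QC coefficient of variation,
    signal-to-noise ratios, PCA batch-effect assessment); two complementary
    differential-expression procedures (SAM-style moderated t with
    permutation-based FDR, and bootstrap-ROC AUC statistics with a
    permutation-null q-value) together with their consensus intersection;
    gene-set overrepresentation against GMT collections; noncentral-t power
    and sample-size analysis; and a synthetic-data generator emulating the
    multi-batch 11-plex TMT design with planted effects, batch effects, and
    batch-level missingness, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sva,
    yaml
Config/testthat/edition: 3
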