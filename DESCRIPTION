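Package: siglip
Title: Gene-Signature Activity Scores and Targeted Lipidomics Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Per-sample pathway-activity scoring for bulk expression data and a
    post-acquisition processing chain for targeted lipidomics. Implements the
    androgen-receptor (AR) signaling score (Pearson correlation of a sample's
    log2 expression over a fixed AR-regulated gene set against a reference
    vector), the mTOR activation score (per-sample two-sample t statistic
    contrasting mTOR-activation up-regulated against down-regulated gene sets),
    gene-versus-score association statistics, delta-delta-Ct and densitometry
    quantification, and a pooled-QC lipidomics pipeline (LOWESS/spline signal
    drift correction, coefficient-of-variation filtering, dilution linearity,
    protein-content normalization, lipid-class aggregation and differential
    abundance). Seeded latent-factor simulators generate expression matrices
    and lipidomics injection sequences with known ground truth so that every
    stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
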