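Package: emapkit
Title: Scoring, Quality Control and Artifact Diagnostics for Epistatic
    Miniarray Profile Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative genetic interaction (E-MAP/SGA) screens:
    turns replicate double-mutant colony sizes into symmetrized, significance
    annotated S scores, computes genetic interaction profile correlations and
    their joint significance classification, compares screens run under two
    conditions (chemogenetic differential calls), and scans genome-ordered
    interaction matrices for contiguous chromosomal regions that uniformly
    interact with one distant gene, the signature of undeclared suppressor
    mutations carried by screen strains. Includes a synthetic screen generator
    with planted ground truth (multiplicative fitness, lognormal replicate
    noise, plate effects, noisy strains, condition-specific shifts and
    linkage-lost suppressors) for end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
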