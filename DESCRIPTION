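Package: lrloops
Title: Meta-Analysis of Coordinated Ligand-Receptor Expression in Paired
    Tumor/Normal Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate autocrine/paracrine signaling loops from
    compendia of paired tumor/normal expression datasets. Screens a
    ligand/receptor catalog for pairs whose expression is correlated within
    tumor or normal sample groups (Pearson correlation with Bonferroni
    correction), tests each gene for paired differential expression
    (paired t-test with Benjamini-Hochberg false discovery rate), votes
    genes as concordantly modulated across datasets, enumerates the
    reported ligand/receptor pairs with direction, and classifies
    tumor-versus-in-vitro direction concordance. Includes a seeded
    synthetic-data generator producing multi-platform paired compendia
    with planted correlated pairs and fold changes, so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
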