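Package: ddrsl
Title: DNA Damage Response Subtyping and Synthetic-Lethality Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pan-cancer analysis pipeline for DNA damage response (DDR)
    alterations in tumor cohorts. Computes single-sample gene set enrichment
    (ssGSEA) of DDR pathways, clusters tumors on their enrichment profiles,
    tests cluster-gene mutation co-occurrence and pairwise mutation mutual
    exclusivity with a hypergeometric model, scores candidate synthetic-lethal
    (SL) gene pairs with four p-value features fed to a Random Forest, and
    validates predictions against conditional essentiality in cell-line
    knockdown screens, disease-free survival, and drug-sensitivity screens,
    assembling the results into a gene-SL-drug association network. Ships a
    synthetic-cohort generator with planted cluster, mutual-exclusivity and SL
    structure so the whole pipeline is testable end to end without external
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
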