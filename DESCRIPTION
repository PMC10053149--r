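Package: omicsig
Title: Consensus Molecular-Signature Discovery and Drug Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-stage discovery of molecular signatures from multi-cohort
    transcriptomics: per-dataset differential expression with an empirical-Bayes
    moderated t-statistic, direction-wise intersection into consensus DEGs,
    topological hub-gene selection on a protein-protein interaction network
    (degree, betweenness, stress and bottleneck centralities), hypergeometric
    gene-set over-representation, degree-based ranking of transcription factors
    and miRNAs onto the key-gene set, and prioritization of candidate drugs
    from a receptor-by-drug binding-affinity matrix with cross-validation
    against an independent receptor panel. Includes seed-deterministic
    synthetic-data generators with recorded ground truth so every stage can be
    validated by planted-structure recovery.
License: MIT
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Encoding: UTF-8
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
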