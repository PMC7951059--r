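Package: MYCNimmune
Title: MYCN-Driven Immune Landscape Analysis and Prognostic Immune Scoring
        for Neuroblastoma Expression Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: A pipeline for dissecting how MYCN amplification reshapes the
        tumor immune landscape in bulk expression cohorts. Implements
        preranked gene-set enrichment with permutation-based FDR,
        reference-based immune-cell deconvolution with signature-matrix
        construction, a surface-protein immune interaction network built
        from annotation and interaction-score filters, signed weighted
        co-expression module detection with eigengenes and regulon
        inference, and a composite prognostic MYCN immune score that fuses
        L1-penalized logistic and Cox regression weights, with
        Kaplan-Meier/log-rank and multivariate Cox validation. A synthetic
        cohort simulator with planted ground truth makes every stage
        testable without access to the original patient cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, S4Vectors, SummarizedExperiment, limma,
        glmnet, survival, e1071, pracma, yaml, jsonlite
Suggests: testthat (>= 3.0.0), fgsea, mclust, withr, optparse, knitr,
        rmarkdown
biocViews: GeneExpression, Transcriptomics, ImmunoOncology, Survival,
        NetworkInference, GeneSetEnrichment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
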