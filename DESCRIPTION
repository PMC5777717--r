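Package: lncprop
Title: Network Propagation Prioritization of Disease-Associated lncRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate disease-associated long non-coding RNAs
    (lncRNAs) from paired lncRNA/miRNA expression data. Per disease, a
    competing-endogenous-RNA (ceRNA) lncRNA-lncRNA network is inferred by
    intersecting significant miRNA-lncRNA co-expression (Pearson correlation,
    Benjamini-Hochberg FDR) with a validated interaction prior and testing
    shared-miRNA overlaps with a hypergeometric test; known disease lncRNAs
    are propagated over the network by random walk with restart; per-disease
    scores are integrated across diseases through a disease phenotype
    similarity matrix. Includes leave-one-out cross-validation ROC/AUC
    evaluation with robustness controls (phenotype ablation and permutation,
    random non-disease seeds, disease-count subsampling, cross-disease-only
    prediction) and a synthetic multi-disease data generator with planted
    ceRNA modules.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
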