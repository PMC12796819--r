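Package: lfqminer
Title: Label-Free Quantification Proteomics Analysis and Gene-Set Mining
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless analysis pipeline for label-free quantification (LFQ)
    proteomics experiments quantified with MaxQuant. Parses proteinGroups.txt,
    removes decoy and contaminant entries, applies a per-condition
    missing-value threshold filter, imputes left-censored (MNAR) missing
    values, and tests all pairwise condition contrasts with an empirical-Bayes
    moderated t-test and Benjamini-Hochberg FDR control. Provides global
    visualisations (PCA on the most variable proteins, volcano plots, k-means
    clustered z-score heat maps), extraction of Reactome-style pathway gene
    sets and nuclear-receptor consensome target genes from the dataset with
    enrichment summaries, per-protein bar-plot data, a synthetic-data
    generator with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    pheatmap,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
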