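Package: attracmod
Title: Attractor Module Discovery in Condition-Specific Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies differential co-expression ("attractor") modules
    between two phenotypes. A confidence-filtered protein-protein
    interaction network is re-weighted per condition by the absolute
    Pearson correlation of the incident genes' expression, significant
    edges form per-condition destination networks, maximal cliques are
    mined and merged by weighted inter-connectivity into modules, modules
    are paired across conditions by Jaccard similarity of gene
    composition, and each pair is scored with the GSEA-ANOVA statistic: a
    Welch t-test comparing the module genes' one-way ANOVA F-statistics
    against the background gene population, with Benjamini-Hochberg
    control of the false discovery rate. A synthetic-data generator with
    planted differential modules supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    graphics,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
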