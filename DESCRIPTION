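Package: modulemir
Title: miRNA Regulator Discovery from Weighted Gene Co-Expression Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate regulator miRNAs of cancer-progression gene
    modules from paired mRNA/miRNA expression and clinical staging data.
    Implements signed weighted co-expression network construction with
    soft-threshold selection by scale-free topology fit, topological-overlap
    module detection with eigengene merging and module-membership (kME)
    filters, module-trait screening against ordinal stage/TNM codes,
    module-wise hypergeometric miRNA-target over-representation with
    Benjamini-Hochberg FDR control and a negative eigengene-correlation
    filter, per-sample gene-set variation scoring of selected target sets,
    and MCODE-style density clustering of protein-interaction graphs. A
    seeded synthetic-data generator with planted modules, trait effects and
    regulator miRNAs provides a ground-truth surface for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
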