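Package: holophage
Title: Integrative Phage-Host Prediction and Lifestyle Analysis for Sponge Holobionts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts bacterial hosts of environmental phages by combining
    three evidence channels (CRISPR spacer matching, integrated-prophage
    homology, shared tRNA genes), assembles the resulting bipartite
    infection network, and tests whether phage enrichment labels stratify
    across host niches with a label-randomization permutation test.
    Includes marker-gene plus composition-based temperate/lytic lifestyle
    calling with per-environment temperate:lytic abundance ratios, and
    prominence-based fluorescence spot quantification with control-driven
    threshold selection and Kruskal-Wallis/Dunn/Benjamini-Hochberg group
    comparison. A synthetic holobiont community generator with planted
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    Rcpp,
    rtracklayer,
    igraph,
    jsonlite,
    tiff,
    png,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
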