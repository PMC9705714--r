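Package: otuassembly
Title: Community Assembly Null Models and Multivariate Ecology for OTU Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the ecological processes that assemble microbial
    communities from 16S OTU/ASV count tables, a rooted phylogeny and sample
    metadata. Implements the phylogenetic null model (beta mean nearest taxon
    distance and its standardized effect size, betaNTI), the Raup-Crick null
    model on Bray-Curtis dissimilarity (RCbray), and the five-way
    classification of pairwise community turnover into heterogeneous and
    homogeneous selection, dispersal limitation, homogenizing dispersal and
    undominated processes. Also provides the surrounding analysis pipeline for
    seasonal marine survey designs: rarefaction, alpha diversity (Faith's PD,
    richness, Shannon, Pielou evenness), UniFrac and Bray-Curtis beta
    diversity, PCoA, ANOSIM, PERMANOVA, simple and partial Mantel tests, PCNM
    spatial eigenfunctions with forward selection and variation partitioning,
    seasonal-specific OTU detection (indicator analysis intersected with a
    negative-binomial likelihood-ratio test), TMM/CPM normalization, Spearman
    co-occurrence networks with greedy modularity modules, and a synthetic
    community generator with known ground-truth assembly processes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    picante,
    phyloseq,
    phytools,
    edgeR,
    igraph,
    MASS,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
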