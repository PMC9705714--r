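#' Alpha diversity: Faith's PD, richness, Shannon, Pielou evenness
#'
#' Computes the four indices used for month-wise diversity comparisons.
#' Shannon entropy is in bits (log2) by convention here, with a natural-log
#' option; Pielou evenness is H / log(richness) in the same base. Faith's
#' PD is the total branch length of the minimal subtree connecting a
#' sample's observed tips to the root (root path included, which matters on
#' unbalanced trees).
#'
#' @param x rarefied otu_table.
#' @param tree rooted phylo covering all taxa of `x`.
#' @param base logarithm base for Shannon/Pielou (default 2).
#' @return data.frame with columns `faith_pd`, `otu_richness`, `shannon`,
#'   `pielou_e`, one row per sample.
#' @export
alpha_diversity <- function(x, tree, base = 2) {
  check_tree_coverage(x, tree)
  if (any(colSums(x) == 0)) stop("sample with zero total reads")
  samp <- t(unclass(x))                       # samples x taxa for picante
  pd <- picante::pd(samp, tree, include.root = TRUE)
  p <- sweep(samp, 1, rowSums(samp), "/")
  shannon <- apply(p, 1, function(pi) { pi <- pi[pi > 0]; -sum(pi * log(pi, base)) })
  rich <- rowSums(samp > 0)
  even <- ifelse(rich > 1, shannon / log(rich, base), NA_real_)
  data.frame(faith_pd = pd$PD, otu_richness = rich, shannon = shannon,
             pielou_e = even, row.names = rownames(samp))
}

#' Bray-Curtis dissimilarity between samples
#'
#' BC(i,j) = 1 - 2 * sum_k min(x_ki, x_kj) / (sum_k x_ki + sum_k x_kj),
#' computed on counts (or any non-negative abundances); values in \[0, 1\].
#'
#' @param x otu_table (or non-negative taxa x samples matrix).
#' @return dist_matrix over samples.
#' @export
bray_curtis <- function(x) {
  if (any(colSums(x) == 0)) stop("Bray-Curtis undefined for all-zero samples")
  as_dist_matrix(as.matrix(vegan::vegdist(t(unclass(x)), method = "bray")))
}

#' UniFrac phylogenetic beta diversity
#'
#' Unweighted UniFrac is the fraction of branch length unique to exactly
#' one of the two samples' tip sets; weighted UniFrac sums branch lengths
#' weighted by the absolute difference in the subtree's relative abundance,
#' non-normalized by default (the QIIME-era "weighted_unifrac" convention).
#'
#' @param x otu_table. @param tree rooted phylo covering the taxa.
#' @param weighted logical; abundance-weighted variant.
#' @param normalized for the weighted variant, divide by the
#'   abundance-weighted tree depth so values fall in \[0, 1\].
#' @return dist_matrix over samples.
#' @export
unifrac <- function(x, tree, weighted = FALSE, normalized = FALSE) {
  check_tree_coverage(x, tree)
  tr <- ape::keep.tip(tree, taxon_ids(x))
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(unclass(x), taxa_are_rows = TRUE),
    phyloseq::phy_tree(tr))
  d <- phyloseq::UniFrac(ps, weighted = weighted, normalized = normalized)
  m <- as.matrix(d)[sample_ids(x), sample_ids(x)]
  as_dist_matrix(m)
}
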