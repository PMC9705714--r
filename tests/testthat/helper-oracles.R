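# Independent brute-force oracles for the phylogenetic metrics, written
# directly from their definitions (edge walks and double loops over tips),
# deliberately sharing no code with the package implementations.

random_small_tree <- function(n_tips, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_tips)
    tr$tip.label <- paste0("t", seq_len(n_tips))
    tr$edge.length <- round(tr$edge.length, 3) + 0.05
    tr
  })
}

random_small_table <- function(tree, n_samples, seed, max_count = 20) {
  withr::with_seed(seed, {
    n <- length(tree$tip.label)
    m <- matrix(rpois(n * n_samples, 3), n, n_samples,
                dimnames = list(tree$tip.label, paste0("s", seq_len(n_samples))))
    # guarantee non-empty samples
    for (j in seq_len(n_samples)) if (sum(m[, j]) == 0) m[sample(n, 1), j] <- 1
    as_otu_table(m)
  })
}

edge_tips_below <- function(tree) {
  # list over edges: tip labels descending from the edge's child node
  lapply(seq_len(nrow(tree$edge)), function(e) {
    child <- tree$edge[e, 2]
    if (child <= length(tree$tip.label)) return(tree$tip.label[child])
    tree$tip.label[phangorn::Descendants(tree, child, "tips")[[1]]]
  })
}

oracle_faith_pd <- function(tree, present) {
  below <- edge_tips_below(tree)
  keep <- vapply(below, function(tp) any(tp %in% present), TRUE)
  sum(tree$edge.length[keep])
}

oracle_uuf <- function(tree, present1, present2) {
  below <- edge_tips_below(tree)
  in1 <- vapply(below, function(tp) any(tp %in% present1), TRUE)
  in2 <- vapply(below, function(tp) any(tp %in% present2), TRUE)
  l <- tree$edge.length
  sum(l[xor(in1, in2)]) / sum(l[in1 | in2])
}

oracle_wuf <- function(tree, ab1, ab2) {
  # ab1/ab2: named absolute abundances; raw (non-normalized) weighted UniFrac
  p1 <- ab1 / sum(ab1); p2 <- ab2 / sum(ab2)
  below <- edge_tips_below(tree)
  s <- 0
  for (e in seq_along(below)) {
    tp <- below[[e]]
    s <- s + tree$edge.length[e] *
      abs(sum(p1[names(p1) %in% tp]) - sum(p2[names(p2) %in% tp]))
  }
  s
}

oracle_bray <- function(x1, x2) 1 - 2 * sum(pmin(x1, x2)) / (sum(x1) + sum(x2))

oracle_bmntd <- function(tree, x1, x2, weighted) {
  D <- ape::cophenetic.phylo(tree)
  t1 <- names(x1)[x1 > 0]; t2 <- names(x2)[x2 > 0]
  w1 <- if (weighted) x1[t1] / sum(x1[t1]) else rep(1 / length(t1), length(t1))
  w2 <- if (weighted) x2[t2] / sum(x2[t2]) else rep(1 / length(t2), length(t2))
  s1 <- 0
  for (i in seq_along(t1)) {
    dmin <- Inf
    for (j in seq_along(t2)) dmin <- min(dmin, D[t1[i], t2[j]])
    s1 <- s1 + w1[i] * dmin
  }
  s2 <- 0
  for (j in seq_along(t2)) {
    dmin <- Inf
    for (i in seq_along(t1)) dmin <- min(dmin, D[t2[j], t1[i]])
    s2 <- s2 + w2[j] * dmin
  }
  unname(0.5 * (s1 + s2))
}

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

toy_table <- function(counts, taxa = c("A", "B", "C")) {
  m <- matrix(counts, nrow = length(taxa),
              dimnames = list(taxa, paste0("s", seq_len(length(counts) / length(taxa)))))
  as_otu_table(m)
}

# exhaustive 120 permutations of 5 elements (for the Mantel enumeration oracle)
gtools_permutations_5 <- function() {
  p <- NULL
  for (a in 1:5) for (b in setdiff(1:5, a)) for (cc in setdiff(1:5, c(a, b)))
    for (d in setdiff(1:5, c(a, b, cc))) {
      e <- setdiff(1:5, c(a, b, cc, d))
      p <- rbind(p, c(a, b, cc, d, e))
    }
  p
}

# Communities drawn from the null models' own generating procedures, for
# calibration checks (observed scores should then be typical null draws).

# tip-shuffle null: membership and abundance assigned with no relation to
# the tree's tip positions
calib_table_bnti <- function(n_taxa, n_samples, seed, richness = 60,
                             reads = 26000) {
  withr::with_seed(seed, {
    occ <- stats::runif(n_taxa)
    ab <- stats::rlnorm(n_taxa, 0, 1.5)
    m <- sapply(seq_len(n_samples), function(j) {
      idx <- sample.int(n_taxa, richness, prob = occ)
      col <- numeric(n_taxa)
      col[idx] <- 1 + stats::rmultinom(1, reads - richness, ab[idx])[, 1]
      col
    })
    dimnames(m) <- list(paste0("otu", seq_len(n_taxa)),
                        paste0("s", seq_len(n_samples)))
    list(table = as_otu_table(m), occupancy = occ, abundance = ab)
  })
}

# Raup-Crick null: fixed per-sample richness/reads, membership ~ occupancy,
# fill ~ regional abundance — exactly the null's procedure
calib_table_rc <- function(n_taxa, n_samples, seed, richness = 60,
                           reads = 26000) {
  calib_table_bnti(n_taxa, n_samples, seed, richness, reads)
}
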