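#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For each pair of samples, the abundance-weighted (or presence-weighted)
#' mean of the patristic distance from every taxon in one community to its
#' nearest relative in the other, averaged over both directions:
#' betaMNTD(i,j) = 0.5 * (sum_k f_ki min_l d_kl + sum_l f_lj min_k d_lk).
#'
#' @param x otu_table. @param tree rooted phylo covering the taxa.
#' @param weighted `TRUE`: weights are per-sample relative abundances;
#'   `FALSE`: equal weights 1/richness over present taxa.
#' @param D optional precomputed patristic matrix over `taxon_ids(x)` (used
#'   internally by the null model to avoid re-traversal).
#' @return dist_matrix over samples (tree branch-length units).
#' @export
beta_mntd <- function(x, tree, weighted = TRUE, D = NULL) {
  if (is.null(D)) {
    check_tree_coverage(x, tree)
    D <- stats::cophenetic(ape::keep.tip(tree, taxon_ids(x)))[taxon_ids(x), taxon_ids(x)]
  }
  if (any(colSums(x) == 0)) stop("empty sample")
  F <- community_weights(x, weighted)
  members <- apply(unclass(x) > 0, 2, which, simplify = FALSE)
  bmntd_kernel(D, F, members)
}

community_weights <- function(x, weighted) {
  m <- unclass(x)
  if (weighted) sweep(m, 2, colSums(m), "/")
  else sweep((m > 0) * 1, 2, colSums(m > 0), "/")
}

bmntd_kernel <- function(D, F, members) {
  M <- nearest_taxon_min(D, unname(members))
  A <- crossprod(F, M)                    # A[i,j] = sum_k F[k,i] * M[k,j]
  out <- 0.5 * (A + t(A))
  dimnames(out) <- list(colnames(F), colnames(F))
  diag(out) <- 0
  as_dist_matrix(out)
}

#' betaNTI: standardized effect size of betaMNTD under tip shuffling
#'
#' The null model randomly shuffles taxon labels across the tips of the
#' phylogeny over the regional pool (all taxa in the table), recomputes
#' betaMNTD for every pair in each replicate, and standardizes the
#' observed value: betaNTI = (obs - null mean) / null SD. |betaNTI| > 2 is
#' the usual evidence for selection (heterogeneous if > +2, homogeneous if
#' < -2). The same shuffle is shared by all pairs within a replicate
#' (matrix-wise nulls), and shuffles permute the taxon-to-tip assignment,
#' which is applied to the precomputed patristic matrix rather than by
#' re-traversing the tree.
#'
#' @inheritParams beta_mntd
#' @param n_null null replicates (default 999; at least 99).
#' @param seed RNG seed.
#' @return list of class `pairwise_null`: `observed`, `null_mean`,
#'   `null_sd`, `score` (betaNTI; `NA` where the null SD is 0, flagged in
#'   `degenerate`), `n_null`, `seed`, `metric = "bNTI"`.
#' @export
beta_nti <- function(x, tree, weighted = TRUE, n_null = 999, seed = 1) {
  if (n_null < 99) stop("n_null must be at least 99")
  check_tree_coverage(x, tree)
  ids <- taxon_ids(x)
  D <- stats::cophenetic(ape::keep.tip(tree, ids))[ids, ids]
  F <- community_weights(x, weighted)
  members <- apply(unclass(x) > 0, 2, which, simplify = FALSE)
  obs <- bmntd_kernel(D, F, members)
  T <- length(ids)
  s <- ncol(x)
  sum1 <- matrix(0, s, s); sum2 <- matrix(0, s, s)
  withr::with_seed(seed, {
    for (r in seq_len(n_null)) {
      perm <- sample.int(T)
      nul <- unclass(bmntd_kernel(D[perm, perm, drop = FALSE], F, members))
      sum1 <- sum1 + nul
      sum2 <- sum2 + nul^2
    }
  })
  mu <- sum1 / n_null
  va <- (sum2 - n_null * mu^2) / (n_null - 1)
  va[va < 0] <- 0
  sdv <- sqrt(va)
  score <- (unclass(obs) - mu) / sdv
  degenerate <- sdv < 1e-12 & upper.tri(sdv)
  score[sdv < 1e-12] <- NA_real_
  diag(score) <- 0
  dimnames(mu) <- dimnames(sdv) <- dimnames(score) <- dimnames(obs)
  structure(list(observed = obs, null_mean = mu, null_sd = sdv,
                 score = score, degenerate = degenerate,
                 n_null = n_null, seed = seed, metric = "bNTI",
                 weighted = weighted),
            class = "pairwise_null")
}

#' @export
print.pairwise_null <- function(x, ...) {
  v <- x$score[upper.tri(x$score)]
  cat(sprintf("%s over %d samples (%d nulls, seed %d): score range [%.2f, %.2f]\n",
              x$metric, nrow(x$score), x$n_null, x$seed,
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

rc_null_community <- function(n_taxa, richness, reads, occ_prob, ab_prob) {
  idx <- sample.int(n_taxa, richness, replace = FALSE, prob = occ_prob)
  cnt <- numeric(n_taxa)
  cnt[idx] <- 1
  if (reads > richness)
    cnt[idx] <- cnt[idx] + stats::rmultinom(1, reads - richness, ab_prob[idx])[, 1]
  cnt
}

bc_pair <- function(a, b) 1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))

#' Raup-Crick null model on Bray-Curtis dissimilarity (RCbray)
#'
#' For each sample pair, null communities preserve each sample's observed
#' richness and total reads: taxon membership is drawn without replacement
#' with probability proportional to regional occupancy, each member gets
#' one read, and the remaining reads are distributed multinomially in
#' proportion to regional relative abundance. The observed Bray-Curtis
#' value is located in the null distribution and rescaled to \[-1, 1\]:
#' RCbray = 2 * (#\{null < obs\} + 0.5 #\{null = obs\}) / n_null - 1,
#' ties taking half weight so the score is symmetric under obs/null
#' exchange. |RCbray| > 0.95 flags dispersal-driven turnover.
#'
#' @param x rarefied otu_table. @param n_null null replicates (>= 99).
#' @param seed RNG seed.
#' @param pool_occupancy,pool_abundance optional regional-pool weights
#'   (per-taxon membership and read-fill probabilities); by default both
#'   are derived from `x` (occupancy = number of samples a taxon occurs
#'   in, abundance = its summed reads). Supplying them lets the null
#'   represent a regional pool larger than the table at hand.
#' @return `pairwise_null` list: `observed` (Bray-Curtis), `score`
#'   (RCbray), `n_null`, `seed`, `metric = "RCbray"`.
#' @export
raup_crick_bray <- function(x, n_null = 999, seed = 1,
                            pool_occupancy = NULL, pool_abundance = NULL) {
  if (n_null < 99) stop("n_null must be at least 99")
  m <- unclass(x)
  rich <- colSums(m > 0)
  if (any(rich == 0)) stop("sample with zero richness")
  reads <- colSums(m)
  occ <- if (is.null(pool_occupancy)) rowSums(m > 0) else pool_occupancy
  ab <- if (is.null(pool_abundance)) rowSums(m) else pool_abundance
  stopifnot(length(occ) == nrow(m), length(ab) == nrow(m))
  obs <- bray_curtis(x)
  s <- ncol(m)
  score <- matrix(0, s, s, dimnames = dimnames(obs))
  withr::with_seed(seed, {
    for (i in seq_len(s - 1)) for (j in (i + 1):s) {
      o <- obs[i, j]
      less <- 0; ties <- 0
      for (r in seq_len(n_null)) {
        bc <- bc_pair(
          rc_null_community(nrow(m), rich[i], reads[i], occ, ab),
          rc_null_community(nrow(m), rich[j], reads[j], occ, ab))
        if (bc < o) less <- less + 1 else if (bc == o) ties <- ties + 1
      }
      rc <- 2 * (less + 0.5 * ties) / n_null - 1
      score[i, j] <- score[j, i] <- max(-1, min(1, rc))
    }
  })
  structure(list(observed = obs, score = score, n_null = n_null, seed = seed,
                 metric = "RCbray"),
            class = "pairwise_null")
}

#' Classify pairwise community turnover into assembly processes
#'
#' Two-step rule: |betaNTI| > `bnti_threshold` assigns selection
#' (heterogeneous if positive, homogeneous if negative); otherwise RCbray
#' beyond +/- `rc_threshold` assigns dispersal limitation (positive) or
#' homogenizing dispersal (negative); remaining pairs are undominated.
#' Pairs with a missing betaNTI (degenerate null) are excluded and counted
#' in attribute `"skipped"`.
#'
#' @param bnti,rc `pairwise_null` results over the same samples.
#' @param bnti_threshold,rc_threshold classification cutoffs (2 and 0.95).
#' @return data.frame: sample_i, sample_j, bnti, rcbray, process.
#' @export
classify_processes <- function(bnti, rc, bnti_threshold = 2, rc_threshold = 0.95) {
  stopifnot(identical(dimnames(bnti$score), dimnames(rc$score)))
  ids <- rownames(bnti$score)
  pr <- t(utils::combn(length(ids), 2))
  b <- bnti$score[pr]
  r <- rc$score[pr]
  process <- ifelse(b > bnti_threshold, "heterogeneous selection",
             ifelse(b < -bnti_threshold, "homogeneous selection",
             ifelse(r > rc_threshold, "dispersal limitation",
             ifelse(r < -rc_threshold, "homogenizing dispersal",
                    "undominated"))))
  out <- data.frame(sample_i = ids[pr[, 1]], sample_j = ids[pr[, 2]],
                    bnti = b, rcbray = r, process = process)
  skipped <- sum(is.na(b))
  if (skipped > 0)
    message(skipped, " pair(s) skipped: degenerate betaNTI null")
  out <- out[!is.na(out$bnti), , drop = FALSE]
  attr(out, "skipped") <- skipped
  out
}

process_levels <- c("heterogeneous selection", "homogeneous selection",
                    "dispersal limitation", "homogenizing dispersal",
                    "undominated")

#' Summarize assembly processes by month stratum
#'
#' Percentages of each of the five processes among sample pairs, stratified
#' into within-month and between-month-pair comparisons (e.g. within-May,
#' May-Aug, ...). Empty strata are omitted with a warning.
#'
#' @param labels data.frame from [classify_processes()].
#' @param md metadata with a `month` column, row names covering the samples.
#' @return data.frame: stratum, process, percent, n_pairs.
#' @export
summarize_processes <- function(labels, md) {
  mi <- as.character(md[labels$sample_i, "month"])
  mj <- as.character(md[labels$sample_j, "month"])
  stratum <- ifelse(mi == mj, paste("within", mi),
                    paste(pmin(mi, mj), pmax(mi, mj), sep = "-"))
  out <- do.call(rbind, lapply(unique(stratum), function(st) {
    sub <- labels$process[stratum == st]
    tab <- table(factor(sub, levels = process_levels))
    data.frame(stratum = st, process = names(tab),
               percent = 100 * as.vector(tab) / length(sub),
               n_pairs = length(sub))
  }))
  rownames(out) <- NULL
  out
}
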