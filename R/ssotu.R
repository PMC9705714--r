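#' TMM normalization factors and CPM abundances
#'
#' `tmm_factors()` computes trimmed-mean-of-M scaling factors (30% trim on
#' M-values, 5% on A-values, reference = the sample whose upper quartile is
#' closest to the mean; factors normalized to geometric mean 1).
#' `cpm_abundance()` converts counts to counts-per-million of the
#' effective (factor-scaled) library size.
#'
#' @param x otu_table with at least 2 samples.
#' @return `tmm_factors`: named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(x) {
  if (ncol(x) < 2) stop("TMM needs at least 2 samples")
  dge <- edgeR::DGEList(counts = unclass(x))
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  stats::setNames(dge$samples$norm.factors, colnames(x))
}

#' @rdname tmm_factors
#' @param factors per-sample scaling factors (default all 1).
#' @return `cpm_abundance`: taxa x samples matrix of CPM values.
#' @export
cpm_abundance <- function(x, factors = NULL) {
  if (is.null(factors)) factors <- rep(1, ncol(x))
  if (any(factors <= 0)) stop("factors must be positive")
  eff <- colSums(x) * factors
  if (any(eff == 0)) stop("zero effective library size")
  sweep(unclass(x), 2, eff, "/") * 1e6
}

nb_loglik <- function(y, mu, phi) sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))

nb_fit <- function(y, X, offset, phi) {
  fam <- MASS::negative.binomial(theta = 1 / phi, link = "log")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam, offset = offset,
                   control = list(maxit = 100)))
  mu <- fit$fitted.values
  W <- mu / (1 + phi * mu)
  XtWX <- crossprod(X * sqrt(W))
  cr <- 0.5 * determinant(XtWX, logarithm = TRUE)$modulus
  list(ll = nb_loglik(y, mu, phi), cr = as.numeric(cr), mu = mu)
}

#' Negative-binomial likelihood-ratio test per OTU
#'
#' Per-OTU NB generalized linear model with log link and
#' log(effective library size) offset; full model = group factor, reduced
#' = intercept. Dispersion is a single common value estimated by
#' maximizing the Cox-Reid adjusted profile likelihood summed across OTUs
#' (a documented simplification of tagwise empirical-Bayes shrinkage — it
#' changes individual p-values slightly); per-OTU maximum likelihood is
#' available via `dispersion = "tagwise"`. The LRT statistic 2*(ll_full -
#' ll_reduced) is referred to chi-square with (groups - 1) df, with BH
#' adjustment across OTUs. All-zero OTUs are excluded.
#'
#' @param x otu_table. @param grouping factor-like, one level per sample.
#' @param factors TMM factors (default computed from `x`).
#' @param dispersion "common" (default) or "tagwise".
#' @return data.frame: otu_id, lrt, p, p_adj, dispersion, max_group (group
#'   with highest mean CPM).
#' @export
nb_lrt <- function(x, grouping, factors = NULL,
                   dispersion = c("common", "tagwise")) {
  dispersion <- match.arg(dispersion)
  grouping <- droplevels(as.factor(grouping))
  if (nlevels(grouping) < 2) stop("need at least 2 groups")
  if (any(table(grouping) < 2)) stop("every group needs at least 2 samples")
  if (is.null(factors)) factors <- tmm_factors(x)
  m <- unclass(x)
  nz <- rowSums(m) > 0
  if (!all(nz)) message(sum(!nz), " all-zero OTU(s) excluded")
  m <- m[nz, , drop = FALSE]
  off <- log(colSums(x) * factors)
  X1 <- stats::model.matrix(~grouping)
  X0 <- matrix(1, ncol(m), 1)
  apl_sum <- function(lphi) {
    phi <- exp(lphi)
    sum(vapply(seq_len(nrow(m)), function(g) {
      f <- nb_fit(m[g, ], X1, off, phi)
      f$ll - f$cr
    }, 0))
  }
  if (dispersion == "common") {
    opt <- stats::optimize(apl_sum, interval = log(c(1e-4, 5)), maximum = TRUE)
    phis <- rep(exp(opt$maximum), nrow(m))
  } else {
    phis <- vapply(seq_len(nrow(m)), function(g) {
      o <- stats::optimize(function(lp) nb_fit(m[g, ], X1, off, exp(lp))$ll,
                           interval = log(c(1e-4, 5)), maximum = TRUE)
      exp(o$maximum)
    }, 0)
  }
  lrt <- vapply(seq_len(nrow(m)), function(g) {
    ll1 <- nb_fit(m[g, ], X1, off, phis[g])$ll
    ll0 <- nb_fit(m[g, ], X0, off, phis[g])$ll
    max(0, 2 * (ll1 - ll0))
  }, 0)
  p <- stats::pchisq(lrt, df = nlevels(grouping) - 1, lower.tail = FALSE)
  cpm <- sweep(m, 2, exp(off), "/") * 1e6   # full-library effective sizes
  gm <- sapply(levels(grouping), function(g)
    rowMeans(cpm[, grouping == g, drop = FALSE]))
  data.frame(otu_id = rownames(m), lrt = lrt, p = p,
             p_adj = stats::p.adjust(p, "BH"),
             dispersion = phis,
             max_group = levels(grouping)[max.col(gm, ties.method = "first")])
}

#' Correlation-based indicator species analysis
#'
#' Per OTU, the point-biserial correlation between its (CPM) abundance and
#' each group's membership indicator; the best group is the one with
#' maximal r, and significance comes from permuting sample labels with the
#' maximum-r statistic. Constant OTUs are excluded.
#'
#' @param cpm taxa x samples abundance matrix (TMM-CPM recommended).
#' @param grouping factor-like group labels per sample.
#' @param n_perm label permutations (default 999). @param seed RNG seed.
#' @return data.frame: otu_id, r (max point-biserial), best_group, p.
#' @export
indicator_analysis <- function(cpm, grouping, n_perm = 999, seed = 1) {
  grouping <- droplevels(as.factor(grouping))
  if (nlevels(grouping) < 2) stop("need at least 2 groups")
  keep <- apply(cpm, 1, stats::sd) > 0
  if (!all(keep)) message(sum(!keep), " constant OTU(s) excluded")
  cpm <- cpm[keep, , drop = FALSE]
  ind <- stats::model.matrix(~ grouping - 1)
  colnames(ind) <- levels(grouping)
  X <- t(cpm)                              # samples x OTUs
  robs <- stats::cor(X, ind)               # OTUs x groups
  best <- max.col(robs, ties.method = "first")
  rmax <- robs[cbind(seq_len(nrow(robs)), best)]
  exceed <- rep(0L, nrow(robs))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      rp <- stats::cor(X, ind[sample.int(nrow(ind)), , drop = FALSE])
      exceed <- exceed + (apply(rp, 1, max) >= rmax)
    }
  })
  data.frame(otu_id = rownames(cpm), r = rmax,
             best_group = colnames(robs)[best],
             p = (exceed + 1) / (n_perm + 1))
}

#' Call seasonal-specific OTUs (ssOTUs)
#'
#' An OTU is an ssOTU when the indicator analysis and the NB
#' likelihood-ratio test are both significant AND agree on the season:
#' the indicator's best group must equal the LRT's highest-mean group.
#' Disagreeing OTUs are rejected (counted in attribute `"disagreements"`).
#'
#' @param indicator data.frame from [indicator_analysis()].
#' @param lrt data.frame from [nb_lrt()].
#' @param alpha_ind indicator permutation p cutoff (default 0.05).
#' @param alpha_lrt BH-adjusted LRT p cutoff (default 0.05).
#' @return data.frame: otu_id, indicator_r, indicator_p, lrt, lrt_p_adj,
#'   season, is_ssotu.
#' @export
call_ssotus <- function(indicator, lrt, alpha_ind = 0.05, alpha_lrt = 0.05) {
  mg <- merge(indicator, lrt, by = "otu_id", suffixes = c("_ind", "_lrt"))
  sig <- mg$p_ind <= alpha_ind & mg$p_adj <= alpha_lrt
  agree <- mg$best_group == mg$max_group
  out <- data.frame(otu_id = mg$otu_id, indicator_r = mg$r,
                    indicator_p = mg$p_ind, lrt = mg$lrt,
                    lrt_p_adj = mg$p_adj,
                    season = ifelse(sig & agree, mg$best_group, NA),
                    is_ssotu = sig & agree)
  attr(out, "disagreements") <- sum(sig & !agree)
  if (!any(out$is_ssotu)) warning("no ssOTU called")
  out[order(out$otu_id), ]
}

#' Spearman co-occurrence network
#'
#' Nodes are OTUs; an edge joins two OTUs when their Spearman rank
#' correlation across samples strictly exceeds `rho_min` AND its
#' two-tailed p (t approximation on mid-ranks) is below `p_max` — the
#' conventional rho > 0.7, p < 0.001 rule. Only positive correlations
#' form edges; isolated nodes are retained.
#'
#' @param cpm taxa x samples abundance matrix (pre-filtered, TMM-CPM).
#' @param rho_min,p_max edge thresholds.
#' @return igraph graph with edge attributes `rho`, `p`.
#' @export
build_network <- function(cpm, rho_min = 0.7, p_max = 0.001) {
  n <- ncol(cpm)
  if (n < 3) stop("need at least 3 samples for correlation p-values")
  rho <- stats::cor(t(cpm), method = "spearman")
  tt <- rho * sqrt((n - 2) / pmax(1e-300, 1 - rho^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  adj <- (rho > rho_min) & (p < p_max)
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = nrow(cpm), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rownames(cpm))
  if (nrow(idx) > 0) {
    g <- igraph::add_edges(g, t(idx))
    g <- igraph::set_edge_attr(g, "rho", value = rho[idx])
    g <- igraph::set_edge_attr(g, "p", value = p[idx])
  }
  g
}

#' Greedy modularity modules of a co-occurrence network
#'
#' Fast-greedy agglomerative modularity maximization on the unweighted
#' edge set. An edgeless network yields one module per node with Q = 0.
#'
#' @param g igraph graph from [build_network()].
#' @return list: `membership` (named integer vector), `modularity`.
#' @export
detect_modules <- function(g) {
  if (igraph::ecount(g) == 0) {
    memb <- stats::setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name)
    return(list(membership = memb, modularity = 0))
  }
  cl <- igraph::cluster_fast_greedy(g)
  memb <- igraph::membership(cl)
  Q <- igraph::modularity(cl)
  if (Q <= 1e-12) {
    # tie-break: when no partition beats Q = 0 (e.g. a single clique), the
    # connected components are the canonical deterministic answer
    memb <- igraph::components(g)$membership
    Q <- igraph::modularity(g, memb)
  }
  list(membership = stats::setNames(as.integer(memb), igraph::V(g)$name),
       modularity = Q)
}

#' Regression of module cumulative abundance on environment
#'
#' For each module, the per-sample cumulative CPM of its member OTUs is
#' regressed (OLS) on each environmental variable; slope, R^2 and the
#' two-tailed p of the slope are reported. Constant variables are skipped.
#'
#' @param membership named module assignment from [detect_modules()].
#' @param cpm taxa x samples CPM matrix.
#' @param md metadata (sample row names matching `colnames(cpm)`).
#' @param vars environmental columns.
#' @return data.frame: module, variable, slope, r2, p.
#' @export
module_env_regression <- function(membership, cpm, md, vars) {
  md <- md[colnames(cpm), , drop = FALSE]
  out <- list()
  for (mod in sort(unique(membership))) {
    otus <- names(membership)[membership == mod]
    ab <- colSums(cpm[otus, , drop = FALSE])
    for (v in vars) {
      xv <- md[[v]]
      if (stats::sd(xv) == 0) next
      fit <- stats::lm(ab ~ xv)
      sm <- summary(fit)
      out[[length(out) + 1]] <- data.frame(
        module = mod, variable = v,
        slope = stats::coef(fit)[2],
        r2 = sm$r.squared,
        p = sm$coefficients[2, 4])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
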