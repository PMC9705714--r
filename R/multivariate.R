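#' Principal component analysis of environmental variables
#'
#' Eigendecomposition of the correlation matrix of z-scored variables,
#' with biplot loadings — the standard ordination for heterogeneous
#' physico-chemical variables.
#'
#' @param md metadata data.frame. @param vars numeric columns to use.
#' @return list: `scores` (samples x PCs), `loadings`, `eigenvalues`,
#'   `proportion` (variance explained per axis).
#' @export
pca_environment <- function(md, vars) {
  m <- as.matrix(md[, vars, drop = FALSE])
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) stop("constant variable(s): ",
                          paste(vars[sds == 0], collapse = ", "))
  if (nrow(m) < 3) stop("need at least 3 samples")
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  list(scores = pc$x, loadings = pc$rotation, eigenvalues = ev,
       proportion = ev / sum(ev))
}

#' Principal coordinates analysis (PCoA)
#'
#' Gower double-centering and eigendecomposition of a distance matrix.
#' Negative eigenvalues (from non-Euclidean distances such as Bray-Curtis)
#' are reported, never silently corrected.
#'
#' @param d dist_matrix.
#' @return list: `coordinates` (axes for positive eigenvalues),
#'   `eigenvalues` (all, sorted descending), `proportion` (of the sum of
#'   positive eigenvalues), `negative_eigenvalues`.
#' @export
pcoa <- function(d) {
  w <- vegan::wcmdscale(stats::as.dist(d), eig = TRUE)
  ev <- w$eig
  pos <- ev[ev > 0]
  list(coordinates = w$points, eigenvalues = ev,
       proportion = pos / sum(pos),
       negative_eigenvalues = ev[ev < 0])
}

perm_result <- function(statistic, value, n_perm, p, seed, extra = list()) {
  stopifnot(p > 0, p <= 1)
  c(list(statistic = statistic, value = value, n_perm = n_perm,
         p = p, seed = seed), extra)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether between-group distances exceed within-group
#' distances; R in \[-1, 1\], p by label permutation.
#'
#' @param d dist_matrix. @param grouping factor-like, one label per id of `d`.
#' @param n_perm permutations (default 999). @param seed RNG seed.
#' @return list with `statistic = "ANOSIM R"`, `value`, `p`, `n_perm`, `seed`.
#' @export
anosim_test <- function(d, grouping, n_perm = 999, seed = 1) {
  grouping <- as.factor(grouping)
  if (nlevels(droplevels(grouping)) < 2) stop("need at least 2 groups")
  if (any(table(grouping) < 2)) stop("every group needs at least 2 samples")
  fit <- withr::with_seed(seed,
    vegan::anosim(stats::as.dist(d), grouping, permutations = n_perm))
  perm_result("ANOSIM R", fit$statistic, n_perm, fit$signif, seed)
}

#' PERMANOVA (ADONIS) on a distance matrix
#'
#' Permutational multivariate ANOVA: pseudo-F from the Gower-centered
#' partition of squared distances; reports both F and R^2 =
#' SS_among/SS_total.
#'
#' @inheritParams anosim_test
#' @return list with `value` = R^2, `F`, `p`, `n_perm`, `seed`.
#' @export
permanova_test <- function(d, grouping, n_perm = 999, seed = 1) {
  grouping <- as.factor(grouping)
  if (nlevels(droplevels(grouping)) < 2) stop("need at least 2 groups")
  if (any(table(grouping) < 2)) stop("every group needs at least 2 samples")
  df <- data.frame(group = grouping)
  fit <- withr::with_seed(seed,
    vegan::adonis2(stats::as.dist(d) ~ group, data = df, permutations = n_perm))
  perm_result("PERMANOVA R2", fit$R2[1], n_perm, fit$`Pr(>F)`[1], seed,
              extra = list(F = fit$F[1]))
}

#' Mantel and partial Mantel tests
#'
#' Correlation between the lower triangles of two distance matrices, with
#' a one-tailed (positive association) permutation p-value obtained by
#' simultaneous row/column shuffling of the second matrix — the convention
#' of distance-decay tables. The partial variant computes
#' r(d1, d2 | d_control) via the first-order partial correlation.
#'
#' @param d1,d2 dist_matrix with matching ids.
#' @param method "spearman" (default) or "pearson".
#' @param n_perm permutations. @param seed RNG seed.
#' @return list with `value` = r, `p`, `n_perm`, `seed`.
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        n_perm = 999, seed = 1) {
  method <- match.arg(method)
  if (!identical(dist_ids(d1), dist_ids(d2))) stop("distance matrix ids differ")
  if (nrow(d1) < 4) stop("need at least 4 samples")
  fit <- withr::with_seed(seed,
    vegan::mantel(stats::as.dist(d1), stats::as.dist(d2), method = method,
                  permutations = n_perm))
  perm_result(paste("Mantel r", method), fit$statistic, n_perm, fit$signif, seed)
}

#' @rdname mantel_test
#' @param d_control distance matrix whose effect is partialled out.
#' @export
partial_mantel_test <- function(d1, d2, d_control,
                                method = c("spearman", "pearson"),
                                n_perm = 999, seed = 1) {
  method <- match.arg(method)
  if (!identical(dist_ids(d1), dist_ids(d2)) ||
      !identical(dist_ids(d1), dist_ids(d_control)))
    stop("distance matrix ids differ")
  r13 <- stats::cor(dist_vec(d1), dist_vec(d_control), method = method)
  r23 <- stats::cor(dist_vec(d2), dist_vec(d_control), method = method)
  if (abs(r13) >= 1 - 1e-12 || abs(r23) >= 1 - 1e-12)
    stop("control matrix perfectly correlated with an input; partial r degenerate")
  fit <- withr::with_seed(seed,
    vegan::mantel.partial(stats::as.dist(d1), stats::as.dist(d2),
                          stats::as.dist(d_control), method = method,
                          permutations = n_perm))
  perm_result(paste("partial Mantel r", method), fit$statistic, n_perm,
              fit$signif, seed)
}

#' Binary temporal control matrix
#'
#' 0 for pairs sampled in the same month, 1 otherwise — the weakest-
#' assumption control matrix for partial Mantel tests of temporal effects.
#'
#' @param md metadata with a `month` column (sample row names).
#' @return dist_matrix.
#' @export
temporal_control_matrix <- function(md) {
  if (!"month" %in% colnames(md)) stop("metadata needs a month column")
  if (anyNA(md$month)) stop("missing month label")
  m <- outer(md$month, md$month, FUN = "!=") * 1
  dimnames(m) <- list(rownames(md), rownames(md))
  as_dist_matrix(m)
}

#' PCNM spatial eigenfunctions
#'
#' Principal coordinates of neighbour matrices: the geographic distance
#' matrix is truncated at the largest minimum-spanning-tree edge (values
#' above it replaced by 4x the threshold), double-centered, and the
#' eigenvectors with positive eigenvalues returned as spatial predictors.
#'
#' @param geo dist_matrix of geographic distances.
#' @return list: `vectors` (samples x eigenfunctions, columns `PCNM1`..),
#'   `values` (positive eigenvalues), `threshold`.
#' @export
pcnm_vectors <- function(geo) {
  if (max(geo) == 0) stop("all samples at one location")
  p <- vegan::pcnm(stats::as.dist(geo))
  v <- p$vectors
  rownames(v) <- dist_ids(geo)
  list(vectors = v, values = p$values[p$values > 1e-12], threshold = p$threshold)
}

#' Forward selection of explanatory variables for a distance response
#'
#' Double-stopping forward selection on distance-based RDA: candidates are
#' added while their permutation p-value is at most `alpha` AND the
#' cumulative adjusted R^2 stays below the global model's adjusted R^2 —
#' the standard guard against inflated selections. An empty selection is a
#' legal result.
#'
#' @param response dist_matrix.
#' @param candidates data.frame/matrix of standardized candidate variables.
#' @param alpha inclusion threshold (default 0.05).
#' @param n_perm permutations per step. @param seed RNG seed.
#' @return list: `selected` (ordered names), `adj_r2` (of the selected
#'   model; 0 if empty), `global_adj_r2`.
#' @export
forward_select <- function(response, candidates, alpha = 0.05,
                           n_perm = 999, seed = 1) {
  df <- as.data.frame(candidates)
  if (nrow(df) != nrow(response)) stop("candidate rows must match response ids")
  dd <- stats::as.dist(response)
  m0 <- vegan::dbrda(dd ~ 1, data = df)
  m1 <- vegan::dbrda(dd ~ ., data = df)
  global <- vegan::RsquareAdj(m1)$adj.r.squared
  sel <- withr::with_seed(seed, suppressMessages(
    vegan::ordiR2step(m0, scope = stats::formula(m1), Pin = alpha,
                      R2scope = TRUE, permutations = n_perm, trace = FALSE)))
  terms <- attr(stats::terms(stats::formula(sel)), "term.labels")
  adj <- if (length(terms) == 0) 0 else vegan::RsquareAdj(sel)$adj.r.squared
  list(selected = terms, adj_r2 = adj, global_adj_r2 = global)
}

db_adj_r2 <- function(dd, X, cols) {
  if (length(cols) == 0) return(0)
  vegan::RsquareAdj(vegan::dbrda(dd ~ ., data = X[, cols, drop = FALSE]))$adj.r.squared
}

#' Variation partitioning over environmental, trend and spatial sets
#'
#' Decomposes the adjusted R^2 of a distance-based RDA into the pure and
#' shared fractions of up to three explanatory sets (environment, linear
#' longitude/latitude trend, PCNM spatial eigenfunctions) by
#' inclusion-exclusion over the seven set combinations. Negative fractions
#' are retained internally; a `display` vector applies the usual
#' truncate-at-zero presentation. Per-set conditional (partial) p-values
#' come from permutation tests with the other sets as conditions.
#'
#' @param response dist_matrix.
#' @param env,trend,pcnm data.frames of (forward-selected) variables; any
#'   may be empty (`NULL` or zero columns).
#' @param n_perm permutations for the conditional tests. @param seed seed.
#' @return list of class `vpa_result`: `fractions` (named: pure_env,
#'   pure_trend, pure_pcnm, env_trend, trend_pcnm, env_pcnm,
#'   env_trend_pcnm, residual), `display`, `total_adj_r2`, `p_values`,
#'   `testable`, `sets`.
#' @export
variance_partition <- function(response, env = NULL, trend = NULL, pcnm = NULL,
                               n_perm = 999, seed = 1) {
  dd <- stats::as.dist(response)
  n <- nrow(response)
  sets <- list(env = env, trend = trend, pcnm = pcnm)
  sets <- lapply(sets, function(s) {
    if (is.null(s) || NCOL(s) == 0) NULL else as.data.frame(s)
  })
  sizes <- vapply(sets, function(s) if (is.null(s)) 0L else ncol(s), 0L)
  if (any(sizes >= n - 1)) stop("an explanatory set has >= n-1 variables")
  if (all(sizes == 0))
    return(structure(list(testable = FALSE, fractions = NULL,
                          note = "no testable model: all selections empty"),
                     class = "vpa_result"))
  X <- do.call(cbind, sets[sizes > 0])
  colnames(X) <- unlist(lapply(names(sets)[sizes > 0], function(nm)
    paste(nm, colnames(sets[[nm]]), sep = ".")))
  cols <- lapply(names(sets), function(nm)
    if (sizes[nm] > 0) paste(nm, colnames(sets[[nm]]), sep = ".") else character(0))
  names(cols) <- names(sets)

  RE <- db_adj_r2(dd, X, cols$env)
  RT <- db_adj_r2(dd, X, cols$trend)
  RP <- db_adj_r2(dd, X, cols$pcnm)
  RET  <- db_adj_r2(dd, X, c(cols$env, cols$trend))
  REP  <- db_adj_r2(dd, X, c(cols$env, cols$pcnm))
  RTP  <- db_adj_r2(dd, X, c(cols$trend, cols$pcnm))
  RETP <- db_adj_r2(dd, X, c(cols$env, cols$trend, cols$pcnm))

  a <- RETP - RTP            # pure env
  b <- RETP - REP            # pure trend
  c_ <- RETP - RET           # pure pcnm
  d <- REP + RTP - RP - RETP # env&trend joint
  e <- REP + RET - RE - RETP # trend&pcnm joint
  f <- RTP + RET - RT - RETP # env&pcnm joint
  g <- RETP - a - b - c_ - d - e - f
  fr <- c(pure_env = a, pure_trend = b, pure_pcnm = c_,
          env_trend = d, trend_pcnm = e, env_pcnm = f,
          env_trend_pcnm = g, residual = 1 - RETP)
  display <- pmax(fr, 0)

  # conditional Monte-Carlo p per non-empty set, other sets partialled out
  pvals <- withr::with_seed(seed, {
    sapply(names(sets), function(nm) {
      if (sizes[nm] == 0) return(NA_real_)
      own <- cols[[nm]]
      others <- unlist(cols[setdiff(names(sets), nm)])
      rhs <- paste(own, collapse = " + ")
      form <- if (length(others) > 0)
        stats::as.formula(paste("dd ~", rhs, "+ Condition(",
                                paste(others, collapse = " + "), ")"))
      else stats::as.formula(paste("dd ~", rhs))
      fit <- vegan::dbrda(form, data = X)
      an <- vegan::anova.cca(fit, permutations = n_perm)
      an$`Pr(>F)`[1]
    })
  })
  structure(list(testable = TRUE, fractions = fr, display = display,
                 total_adj_r2 = RETP, p_values = pvals,
                 sets = cols, n_perm = n_perm, seed = seed),
            class = "vpa_result")
}

#' @export
print.vpa_result <- function(x, ...) {
  if (!isTRUE(x$testable)) { cat("VPA:", x$note, "\n"); return(invisible(x)) }
  cat("Variation partitioning (adjusted R2 fractions):\n")
  print(round(x$fractions, 4))
  cat("total adjusted R2:", round(x$total_adj_r2, 4), "\n")
  invisible(x)
}

welch_p <- function(v1, v2) {
  if (stats::sd(v1) == 0 && stats::sd(v2) == 0)
    return(if (mean(v1) == mean(v2)) 1 else 0)
  stats::t.test(v1, v2)$p.value
}

duncan_p <- function(vals, grouping, g1, g2) {
  # Duncan's multiple range: studentized-range critical with protection
  # level (1-alpha)^(p-1); here converted to a p-value for the pair given
  # its span p in the mean ordering.
  fit <- stats::aov(vals ~ grouping)
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  dfr <- stats::df.residual(fit)
  means <- tapply(vals, grouping, mean)
  ns <- tapply(vals, grouping, length)
  ord <- names(sort(means, decreasing = TRUE))
  span <- abs(which(ord == g1) - which(ord == g2)) + 1
  nh <- 2 / (1 / ns[[g1]] + 1 / ns[[g2]])
  q <- abs(means[[g1]] - means[[g2]]) / sqrt(mse / nh)
  p_raw <- stats::ptukey(q, span, dfr, lower.tail = FALSE)
  1 - (1 - p_raw)^(1 / max(1, span - 1))
}

#' Compact-letter display of group differences
#'
#' All pairwise tests (Welch t by default, Duncan's multiple range on
#' request) followed by letter assignment: groups sharing a letter are not
#' significantly different at `alpha`. Letters are derived from the
#' maximal cliques of the not-significantly-different graph, ordered by
#' descending group mean — the familiar "a/b/c" table annotation.
#'
#' @param values numeric vector. @param grouping factor-like of same length.
#' @param alpha significance level (default 0.05).
#' @param method "welch" or "duncan".
#' @return data.frame: group, n, mean, sd, letters (ordered by descending
#'   mean).
#' @export
group_difference_letters <- function(values, grouping, alpha = 0.05,
                                     method = c("welch", "duncan")) {
  method <- match.arg(method)
  grouping <- droplevels(as.factor(grouping))
  if (nlevels(grouping) < 2) stop("need at least 2 groups")
  if (any(table(grouping) < 2)) stop("every group needs n >= 2")
  gs <- levels(grouping)
  means <- tapply(values, grouping, mean)
  ord <- gs[order(means, decreasing = TRUE)]
  k <- length(ord)
  nsd <- matrix(TRUE, k, k, dimnames = list(ord, ord))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    p <- if (method == "welch")
      welch_p(values[grouping == ord[i]], values[grouping == ord[j]])
    else duncan_p(values, grouping, ord[i], ord[j])
    nsd[i, j] <- nsd[j, i] <- (p > alpha)
  }
  g <- igraph::graph_from_adjacency_matrix(nsd, mode = "undirected", diag = FALSE)
  cl <- igraph::max_cliques(g)
  # order cliques by the best (highest-mean) member so 'a' goes to the top
  best <- vapply(cl, function(cc) min(match(names(cc), ord)), 0)
  cl <- cl[order(best)]
  lett <- stats::setNames(rep("", k), ord)
  for (ii in seq_along(cl)) {
    mem <- names(cl[[ii]])
    lett[mem] <- paste0(lett[mem], letters[ii])
  }
  lett <- vapply(lett, function(s) paste(sort(strsplit(s, "")[[1]]), collapse = ""), "")
  data.frame(group = ord,
             n = as.vector(table(grouping)[ord]),
             mean = as.vector(means[ord]),
             sd = as.vector(tapply(values, grouping, stats::sd)[ord]),
             letters = unname(lett[ord]))
}

#' Pearson correlations between alpha diversity and environment
#'
#' @param alpha data.frame from [alpha_diversity()].
#' @param md metadata (same sample row names). @param vars env columns.
#' @return data.frame: index, variable, r, p (two-tailed); constant
#'   variables reported with `NA`.
#' @export
alpha_env_correlation <- function(alpha, md, vars) {
  md <- md[rownames(alpha), , drop = FALSE]
  out <- expand.grid(index = colnames(alpha), variable = vars,
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    xv <- alpha[[out$index[i]]]; yv <- md[[out$variable[i]]]
    if (stats::sd(yv) == 0 || stats::sd(xv) == 0) next
    ct <- stats::cor.test(xv, yv, method = "pearson")
    out$r[i] <- unname(ct$estimate); out$p[i] <- ct$p.value
  }
  out
}
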