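md5 <- function(n = 10, k = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- as.data.frame(matrix(rnorm(n * k), n, k))
    rownames(m) <- paste0("s", seq_len(n))
    m
  })
}

test_that("environmental PCA: correlated pair, trace conservation, constant guard", {
  m <- md5(12, 2, 3)
  m$V2 <- 2 * m$V1 + 5                       # perfectly correlated
  pc <- pca_environment(m, c("V1", "V2"))
  expect_equal(pc$proportion[1], 1, tolerance = 1e-12)

  m4 <- md5(10, 4, 4)
  pc4 <- pca_environment(m4, colnames(m4))
  expect_equal(sum(pc4$eigenvalues), 4, tolerance = 1e-12)  # trace of corr matrix

  m4$V1 <- 1
  expect_error(pca_environment(m4, colnames(m4)), "V1")
})

test_that("PCoA recovers line geometry, conserves eigenvalue sum, reconstructs distances", {
  pos <- c(0, 1, 3, 6, 10)
  d <- as_dist_matrix(as.matrix(stats::dist(pos)) |>
                        (\(m) { dimnames(m) <- list(paste0("s", 1:5), paste0("s", 1:5)); m })())
  p <- pcoa(d)
  expect_equal(sum(p$eigenvalues > 1e-8), 1)       # one positive axis
  rec <- abs(diff(p$coordinates[, 1]))
  expect_equal(rec, diff(pos), tolerance = 1e-8, ignore_attr = TRUE)

  # eigenvalue sum equals the trace of the Gower-centered matrix
  withr::with_seed(8, {
    x <- matrix(rpois(60, 5) + 1, 10, 6,
                dimnames = list(paste0("o", 1:10), paste0("s", 1:6)))
  })
  bc <- bray_curtis(as_otu_table(x))
  pb <- pcoa(bc)
  A <- -0.5 * unclass(bc)^2
  G <- scale(t(scale(t(A), scale = FALSE)), scale = FALSE)
  expect_equal(sum(pb$eigenvalues), sum(diag(G)), tolerance = 1e-8)

  # full-dimensional coordinates reproduce Euclidean-part distances
  keep <- pb$eigenvalues > 1e-8
  if (sum(pb$eigenvalues < -1e-8) == 0) {
    rec <- as.matrix(stats::dist(pb$coordinates))
    expect_lt(max(abs(rec - unclass(bc))), 1e-8)
  }
})

test_that("ANOSIM: maximal separation gives R = 1; permutation null centers at 0; exhaustive p", {
  # two tight clusters far apart -> all between > all within -> R = 1
  xy <- rbind(matrix(rnorm(8, 0, .01), 4), matrix(rnorm(8, 10, .01), 4))
  rownames(xy) <- paste0("s", 1:8)
  d <- as_dist_matrix(as.matrix(dist(xy)))
  g <- rep(c("a", "b"), each = 4)
  r <- anosim_test(d, g, n_perm = 99, seed = 1)
  expect_equal(r$value, 1)
  expect_gte(r$p, 1 / 100)

  # random grouping: mean permuted R ~ 0 (use vegan's permutation dist)
  withr::with_seed(2, {
    d2 <- as_dist_matrix(as.matrix(dist(matrix(rnorm(20), 10))))
    g2 <- rep(c("a", "b"), 5)
  })
  fit <- withr::with_seed(3, vegan::anosim(stats::as.dist(d2), g2, permutations = 999))
  expect_lt(abs(mean(fit$perm)), 0.05)

  # 6 samples, 2 groups of 3: exhaustive label splits = choose(6,3)/2 = 10
  withr::with_seed(4, {
    d3 <- as.matrix(dist(matrix(rnorm(12), 6)))
    dimnames(d3) <- list(paste0("s", 1:6), paste0("s", 1:6))
  })
  d3 <- as_dist_matrix(d3)
  g3 <- rep(c("a", "b"), each = 3)
  obs <- anosim_test(d3, g3, n_perm = 9999, seed = 5)
  # exhaustive enumeration oracle
  anosim_R <- function(dm, gg) {
    rk <- rank(dm[lower.tri(dm)])
    within <- outer(gg, gg, "==")[lower.tri(dm)]
    (mean(rk[!within]) - mean(rk[within])) / (length(rk) / 2)
  }
  combs <- utils::combn(6, 3)
  Rs <- apply(combs, 2, function(idx) {
    gg <- rep("b", 6); gg[idx] <- "a"; anosim_R(unclass(d3), gg)
  })
  p_exact <- mean(Rs >= anosim_R(unclass(d3), g3) - 1e-12)
  expect_lt(abs(obs$p - p_exact), 0.02)
})

test_that("PERMANOVA equals classical one-way ANOVA on Euclidean 1-D data", {
  withr::with_seed(6, {
    y <- c(rnorm(5, 0), rnorm(5, 1), rnorm(5, 3))
    g <- rep(c("a", "b", "c"), each = 5)
  })
  d <- as.matrix(dist(y)); dimnames(d) <- list(paste0("s", 1:15), paste0("s", 1:15))
  pm <- permanova_test(as_dist_matrix(d), g, n_perm = 99, seed = 1)
  F_aov <- summary(stats::aov(y ~ g))[[1]]["g", "F value"]
  expect_equal(pm$F, F_aov, tolerance = 1e-10)

  # R2 = 1 when groups are internally identical but mutually distinct
  yy <- rep(c(0, 10), each = 3) + 1e-9 * seq_len(6)   # tiny jitter avoids 0 SS
  dd <- as.matrix(dist(rep(c(0, 10), each = 3)))
  dimnames(dd) <- list(paste0("s", 1:6), paste0("s", 1:6))
  pm2 <- permanova_test(as_dist_matrix(dd), rep(c("a", "b"), each = 3),
                        n_perm = 99, seed = 1)
  expect_equal(pm2$value, 1, tolerance = 1e-10)
})

test_that("Mantel: identity and monotone-transform give r = 1; exhaustive p on 5 samples", {
  withr::with_seed(7, {
    d1 <- as.matrix(dist(matrix(rnorm(10), 5)))
    dimnames(d1) <- list(paste0("s", 1:5), paste0("s", 1:5))
  })
  d1 <- as_dist_matrix(d1)
  expect_equal(mantel_test(d1, d1, "pearson", 99, 1)$value, 1)
  d2 <- as_dist_matrix(unclass(d1)^2)                  # increasing transform
  expect_equal(mantel_test(d1, d2, "spearman", 99, 1)$value, 1)

  withr::with_seed(8, {
    e <- as.matrix(dist(matrix(rnorm(10), 5)))
    dimnames(e) <- dimnames(unclass(d1))
  })
  e <- as_dist_matrix(e)
  obs <- mantel_test(d1, e, "pearson", n_perm = 99999, seed = 9)
  # exhaustive: all 120 row/column permutations of e
  perms <- gtools_permutations_5()
  r_of <- function(pp) {
    ep <- unclass(e)[pp, pp]
    stats::cor(dist_vec(d1), ep[lower.tri(ep)])
  }
  r_all <- apply(perms, 1, r_of)
  r_obs <- stats::cor(dist_vec(d1), dist_vec(e))
  p_exact <- mean(r_all >= r_obs - 1e-12)
  expect_lt(abs(obs$p - p_exact), 0.01)
})

test_that("partial Mantel: closed form on hand-built matrices; self-control gives ~0", {
  mk <- function(v) {
    m <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
    m[lower.tri(m)] <- v
    as_dist_matrix(m + t(m))
  }
  a <- mk(c(1, 2, 3, 2.5, 3.5, 1.5)); b <- mk(c(1.2, 1.8, 3.2, 2.2, 3.1, 1.9))
  cmat <- mk(c(2, 1, 2.5, 3, 1.2, 2.2))
  r12 <- cor(dist_vec(a), dist_vec(b)); r13 <- cor(dist_vec(a), dist_vec(cmat))
  r23 <- cor(dist_vec(b), dist_vec(cmat))
  closed <- (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
  pm <- partial_mantel_test(a, b, cmat, "pearson", 99, 1)
  expect_equal(pm$value, closed, tolerance = 1e-10)

  # exact self-control is degenerate (0/0) and must error;
  # near-self-control drives the partial r to ~0
  expect_error(partial_mantel_test(a, b, b, "pearson", 99, 1), "degenerate")
  withr::with_seed(31, {
    base <- matrix(rnorm(60), 30)
    dB <- as.matrix(dist(base)); dA <- as.matrix(dist(base + rnorm(60, 0, 1)))
    ids <- paste0("s", 1:30)
    dimnames(dA) <- dimnames(dB) <- list(ids, ids)
    dCn <- dB + matrix(0.02 * abs(rnorm(900)), 30); dCn <- (dCn + t(dCn)) / 2
    diag(dCn) <- 0
  })
  pm0 <- partial_mantel_test(as_dist_matrix(dA), as_dist_matrix(dB),
                             as_dist_matrix(dCn), "pearson", 99, 1)
  expect_lt(abs(pm0$value), 0.15)
})

test_that("partial Mantel approaches simple Mantel under an independent control", {
  withr::with_seed(10, {
    base <- matrix(rnorm(40), 20)
    d1 <- as.matrix(dist(base)); d2 <- as.matrix(dist(base + rnorm(40, 0, .5)))
    dc <- as.matrix(dist(matrix(rnorm(40), 20)))
    ids <- paste0("s", 1:20)
    dimnames(d1) <- dimnames(d2) <- dimnames(dc) <- list(ids, ids)
  })
  simple <- mantel_test(as_dist_matrix(d1), as_dist_matrix(d2), "pearson", 99, 1)$value
  partial <- partial_mantel_test(as_dist_matrix(d1), as_dist_matrix(d2),
                                 as_dist_matrix(dc), "pearson", 99, 1)$value
  expect_lt(abs(simple - partial), 0.1)
})

test_that("temporal control matrix counts month mismatches", {
  md <- data.frame(month = rep("May", 4), row.names = paste0("s", 1:4))
  expect_true(all(temporal_control_matrix(md) == 0))
  md2 <- data.frame(month = rep(c("May", "Aug", "Oct"), each = 4),
                    row.names = paste0("s", 1:12))
  tc <- temporal_control_matrix(md2)
  frac1 <- mean(dist_vec(tc))
  expect_equal(frac1, 1 - 3 * choose(4, 2) / choose(12, 2))
  md2$month[1] <- NA
  expect_error(temporal_control_matrix(md2), "month")
})

test_that("PCNM eigenfunctions: transect structure, rank bound, scale equivariance", {
  xy <- data.frame(longitude = seq(0, 9), latitude = rep(0, 10),
                   row.names = paste0("s", 1:10))
  gd <- geo_distance(xy)
  p <- pcnm_vectors(gd)
  expect_lte(ncol(p$vectors), 9)
  # first eigenfunction is sinusoid-like: one sign change along the transect
  v1 <- p$vectors[, 1]
  expect_equal(sum(diff(sign(v1)) != 0), 1)

  gd2 <- as_dist_matrix(unclass(gd) * 2)
  p2 <- pcnm_vectors(gd2)
  expect_equal(p2$threshold, 2 * p$threshold)
  expect_equal(abs(stats::cor(p$vectors[, 1], p2$vectors[, 1])), 1, tolerance = 1e-8)

  same <- data.frame(longitude = rep(1, 5), latitude = rep(1, 5),
                     row.names = paste0("s", 1:5))
  expect_error(pcnm_vectors(geo_distance(same)), "location")
})

test_that("forward selection recovers a planted predictor and guards against noise", {
  withr::with_seed(11, {
    n <- 30
    cand <- as.data.frame(scale(matrix(rnorm(n * 5), n, 5)))
    rownames(cand) <- paste0("s", 1:n)
    resp_coord <- cand$V3 + rnorm(n, 0, 0.05)
    d <- as.matrix(dist(resp_coord)); dimnames(d) <- list(rownames(cand), rownames(cand))
  })
  fs <- forward_select(as_dist_matrix(d), cand, alpha = 0.05, n_perm = 199, seed = 2)
  expect_equal(fs$selected[1], "V3")
  expect_lte(length(fs$selected), 2)

  # duplicated column is never selected twice
  cand2 <- cand; cand2$V3dup <- cand$V3
  fs2 <- forward_select(as_dist_matrix(d), cand2, alpha = 0.05, n_perm = 199, seed = 2)
  expect_lte(sum(fs2$selected %in% c("V3", "V3dup")), 1)

  # pure noise response -> mostly empty selections
  empties <- 0
  for (s in 1:10) {
    withr::with_seed(100 + s, {
      dn <- as.matrix(dist(rnorm(20)))
      dimnames(dn) <- list(paste0("s", 1:20), paste0("s", 1:20))
      cn <- as.data.frame(scale(matrix(rnorm(20 * 4), 20, 4)))
      rownames(cn) <- paste0("s", 1:20)
    })
    fsn <- forward_select(as_dist_matrix(dn), cn, alpha = 0.05, n_perm = 199, seed = s)
    if (length(fsn$selected) == 0) empties <- empties + 1
  }
  expect_gte(empties, 9)
})

test_that("variation partitioning: algebraic identity, planted orthogonal design, empty sets", {
  withr::with_seed(12, {
    n <- 24
    env <- as.data.frame(scale(matrix(rnorm(n * 2), n, 2)))
    trend <- as.data.frame(scale(matrix(rnorm(n * 2), n, 2)))
    pcnm <- as.data.frame(scale(matrix(rnorm(n * 2), n, 2)))
    rownames(env) <- rownames(trend) <- rownames(pcnm) <- paste0("s", 1:n)
    resp <- as.matrix(dist(matrix(rnorm(n * 3), n, 3)))
    dimnames(resp) <- list(rownames(env), rownames(env))
  })
  vp <- variance_partition(as_dist_matrix(resp), env, trend, pcnm,
                           n_perm = 99, seed = 3)
  expect_true(vp$testable)
  expect_lt(abs(sum(vp$fractions[1:7]) - vp$total_adj_r2), 1e-10)
  expect_equal(unname(vp$display), unname(pmax(vp$fractions, 0)))

  # cross-check the seven fractions against vegan::varpart
  ref <- vegan::varpart(stats::as.dist(resp), env, trend, pcnm)
  expect_equal(unname(vp$fractions[1:7]),
               ref$part$indfract$Adj.R.square[1:7], tolerance = 1e-8)

  # planted: response generated from env only; trend/pcnm independent noise
  withr::with_seed(13, {
    sig <- as.data.frame(scale(matrix(rnorm(24 * 2), 24, 2)))
    rownames(sig) <- paste0("s", 1:24)
    respE <- as.matrix(dist(as.matrix(sig) %*% c(1, 1)))
    dimnames(respE) <- list(rownames(sig), rownames(sig))
  })
  vpE <- variance_partition(as_dist_matrix(respE), sig, trend, pcnm,
                            n_perm = 99, seed = 4)
  expect_gt(vpE$fractions["pure_env"], 0.9 * vpE$total_adj_r2)
  expect_lt(max(abs(vpE$fractions[c("pure_trend", "pure_pcnm")])), 0.05)

  # all-empty selections -> flagged untestable
  vp0 <- variance_partition(as_dist_matrix(resp))
  expect_false(vp0$testable)
})

test_that("letter groupings: shared letter iff not significantly different", {
  withr::with_seed(14, {
    vals <- c(rnorm(8, 0, .1), rnorm(8, 10, .1), rnorm(8, 20, .1))
    g <- rep(c("g1", "g2", "g3"), each = 8)
  })
  lt <- group_difference_letters(vals, g)
  expect_equal(lt$letters, c("a", "b", "c"))
  expect_equal(lt$group, c("g3", "g2", "g1"))    # ordered by descending mean

  same <- rep(c(5, 5.0001, 4.9999, 5), 3)
  gs <- rep(c("g1", "g2", "g3"), each = 4)
  lt2 <- group_difference_letters(same, gs)
  expect_true(all(lt2$letters == "a"))

  # Duncan engine runs and agrees on the clear-cut case
  ltd <- group_difference_letters(vals, g, method = "duncan")
  expect_equal(ltd$letters, c("a", "b", "c"))
  expect_error(group_difference_letters(c(1, 2), c("a", "b")), "groups|n >= 2")
})

test_that("letter patterns are stable across seeds for large effects at survey-like n", {
  pats <- sapply(1:5, function(s) {
    withr::with_seed(s, {
      vals <- c(rnorm(24, 58.3, 5), rnorm(84, 68.0, 5), rnorm(84, 44.4, 5))
      g <- rep(c("May", "Aug", "Oct"), c(24, 84, 84))
    })
    paste(group_difference_letters(vals, g)$letters, collapse = "")
  })
  expect_true(all(pats == "abc"))
})

test_that("alpha-environment Pearson correlations", {
  withr::with_seed(15, {
    alpha <- data.frame(faith_pd = rnorm(20, 50, 5), row.names = paste0("s", 1:20))
    md <- data.frame(Temp = alpha$faith_pd,        # identical -> r = 1
                     DO = rnorm(20), Const = rep(1, 20),
                     row.names = paste0("s", 1:20))
  })
  ct <- alpha_env_correlation(alpha, md, c("Temp", "DO", "Const"))
  expect_equal(ct$r[ct$variable == "Temp"], 1, tolerance = 1e-12)
  expect_true(is.na(ct$r[ct$variable == "Const"]))

  # hand-computed 5-point Pearson r
  a5 <- data.frame(shannon = c(1, 2, 3, 4, 5), row.names = paste0("s", 1:5))
  m5 <- data.frame(Temp = c(2, 1, 4, 3, 6), row.names = paste0("s", 1:5))
  byhand <- sum((a5$shannon - 3) * (m5$Temp - 3.2)) /
    sqrt(sum((a5$shannon - 3)^2) * sum((m5$Temp - 3.2)^2))
  ct5 <- alpha_env_correlation(a5, m5, "Temp")
  expect_equal(ct5$r, byhand, tolerance = 1e-12)

  # null calibration: independent pairs at n = 100 keep |r| small
  hits <- 0
  for (s in 1:20) {
    withr::with_seed(200 + s, {
      aa <- data.frame(shannon = rnorm(100), row.names = paste0("s", 1:100))
      mm <- data.frame(Temp = rnorm(100), row.names = paste0("s", 1:100))
    })
    if (abs(alpha_env_correlation(aa, mm, "Temp")$r) < 0.3) hits <- hits + 1
  }
  expect_gte(hits, 19)
})
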