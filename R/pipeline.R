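#' Configuration of a full analysis run
#'
#' Collects every constant the end-to-end analysis uses: rarefaction depth
#' (26,000 reads), null/permutation replicate counts (999), the
#' classification thresholds (betaNTI +/-2, RCbray +/-0.95), the network
#' edge rule (rho > 0.7, p < 0.001), the pooled relative-abundance filter
#' (> 0.01%) and the master seed every stage's RNG stream derives from.
#'
#' @param table,tree,metadata in-memory inputs (otu_table, phylo,
#'   data.frame) or paths to TSV/Newick/TSV files.
#' @param out_dir output directory for report tables and the manifest.
#' @param rarefaction_depth reads per sample (default 26000).
#' @param n_null null replicates for betaNTI/RCbray (default 999).
#' @param n_perm permutations for ANOSIM/PERMANOVA/Mantel/VPA (default 999).
#' @param bnti_threshold,rc_threshold process-classification cutoffs.
#' @param rho_min,p_max co-occurrence edge thresholds.
#' @param abundance_threshold pooled relative-abundance filter (default 1e-4).
#' @param env_vars metadata columns used as environmental variables
#'   (default: all numeric columns except coordinates/replicate).
#' @param weighted_bnti use abundance-weighted betaMNTD for classification
#'   (default `FALSE`, the unweighted convention).
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(table, tree, metadata, out_dir = tempfile("otuassembly_"),
                       rarefaction_depth = 26000, n_null = 999, n_perm = 999,
                       bnti_threshold = 2, rc_threshold = 0.95,
                       rho_min = 0.7, p_max = 0.001,
                       abundance_threshold = 1e-4, env_vars = NULL,
                       weighted_bnti = FALSE, seed = 1) {
  stopifnot(rarefaction_depth >= 1, n_null >= 99, n_perm >= 1,
            bnti_threshold > 0, rc_threshold > 0, rc_threshold <= 1,
            rho_min >= 0, rho_min < 1, p_max > 0, p_max <= 1,
            abundance_threshold >= 0, abundance_threshold < 1)
  if (is.character(table)) table <- read_otu_table(table)
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  structure(as.list(environment()), class = "run_config")
}

stage_seed <- function(cf, k) (cf$seed * 131L + k) %% .Machine$integer.max

#' Run the full seasonal community analysis
#'
#' Orchestrates the whole pipeline on one dataset: rarefaction and
#' abundance filtering; alpha diversity with month letter groupings;
#' Bray-Curtis/UniFrac distances with PCoA, ANOSIM and PERMANOVA by month;
#' simple and partial Mantel tables against environmental, geographic and
#' temporal distances; PCNM + forward selection + variation partitioning;
#' betaNTI and RCbray null models with process classification and
#' month-stratum summaries; ssOTU detection, co-occurrence network,
#' modules and module-environment regressions. All tables are written as
#' TSV under `config$out_dir` together with a JSON manifest (config,
#' derived stage seeds, config hash) that makes the run exactly
#' repeatable. With a single month, temporal stages are skipped with
#' notices.
#'
#' @param config [run_config()].
#' @return invisibly, a list with every stage result plus `manifest`.
#' @export
run_full_analysis <- function(config) {
  cf <- config
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  md <- cf$metadata
  months <- unique(md$month)
  multi_month <- length(months) > 1

  # --- data model -----------------------------------------------------
  rar <- rarefy_table(cf$table, depth = cf$rarefaction_depth,
                      seed = stage_seed(cf, 1))
  md <- md[sample_ids(rar), , drop = FALSE]
  flt <- filter_by_abundance(rar, cf$abundance_threshold)
  if (is.null(cf$env_vars)) {
    num <- vapply(md, is.numeric, TRUE)
    cf$env_vars <- setdiff(colnames(md)[num],
                           c("longitude", "latitude", "replicate"))
  }

  # --- diversity ------------------------------------------------------
  alpha <- alpha_diversity(rar, cf$tree)
  letters_tab <- if (multi_month)
    do.call(rbind, lapply(colnames(alpha), function(ix) {
      lt <- group_difference_letters(alpha[[ix]], md$month)
      cbind(index = ix, lt)
    })) else NULL
  bc  <- bray_curtis(rar)
  uuf <- unifrac(rar, cf$tree, weighted = FALSE)
  wuf <- unifrac(rar, cf$tree, weighted = TRUE, normalized = FALSE)
  ord <- pcoa(uuf)

  # --- multivariate ---------------------------------------------------
  anosim_res <- permanova_res <- NULL
  if (multi_month) {
    anosim_res <- anosim_test(uuf, md$month, cf$n_perm, stage_seed(cf, 2))
    permanova_res <- permanova_test(uuf, md$month, cf$n_perm, stage_seed(cf, 3))
  } else message("single month: ANOSIM/PERMANOVA by month skipped")
  env_d <- env_distance(md, cf$env_vars)
  geo_d <- geo_distance(md)
  mantel_rows <- lapply(c(cf$env_vars, "Env", "Geo"), function(v) {
    dv <- switch(v, Env = env_d, Geo = geo_d,
                 env_distance(md, v, standardize = FALSE))
    row <- mantel_test(uuf, dv, "spearman", cf$n_perm, stage_seed(cf, 4))
    out <- data.frame(variable = v, r = row$value, p = row$p)
    if (multi_month) {
      tc <- temporal_control_matrix(md)
      pm <- partial_mantel_test(uuf, dv, tc, "spearman", cf$n_perm,
                                stage_seed(cf, 5))
      out$r_temporal <- pm$value; out$p_temporal <- pm$p
    }
    out
  })
  mantel_tab <- do.call(rbind, mantel_rows)

  pc <- pcnm_vectors(geo_d)
  env_sc <- as.data.frame(scale(md[, cf$env_vars, drop = FALSE]))
  trend <- as.data.frame(scale(md[, c("longitude", "latitude")]))
  fs_env   <- forward_select(uuf, env_sc, n_perm = cf$n_perm,
                             seed = stage_seed(cf, 6))
  fs_trend <- forward_select(uuf, trend, n_perm = cf$n_perm,
                             seed = stage_seed(cf, 7))
  fs_pcnm  <- forward_select(uuf, as.data.frame(pc$vectors),
                             n_perm = cf$n_perm, seed = stage_seed(cf, 8))
  vpa <- variance_partition(
    uuf,
    env   = env_sc[, fs_env$selected, drop = FALSE],
    trend = trend[, fs_trend$selected, drop = FALSE],
    pcnm  = as.data.frame(pc$vectors)[, fs_pcnm$selected, drop = FALSE],
    n_perm = cf$n_perm, seed = stage_seed(cf, 9))

  # --- assembly null models -------------------------------------------
  bnti <- beta_nti(flt, cf$tree, weighted = cf$weighted_bnti,
                   n_null = cf$n_null, seed = stage_seed(cf, 10))
  rc <- raup_crick_bray(flt, n_null = cf$n_null, seed = stage_seed(cf, 11))
  procs <- classify_processes(bnti, rc, cf$bnti_threshold, cf$rc_threshold)
  proc_summary <- summarize_processes(procs, md)

  # --- ssOTU + network ------------------------------------------------
  ssotu <- network <- modules <- modreg <- NULL
  if (multi_month) {
    fac <- tmm_factors(flt)
    cpm <- cpm_abundance(flt, fac)
    ind <- indicator_analysis(cpm, md$month, n_perm = cf$n_perm,
                              seed = stage_seed(cf, 12))
    lrt <- nb_lrt(flt, md$month, factors = fac)
    ssotu <- call_ssotus(ind, lrt)
    network <- build_network(cpm, cf$rho_min, cf$p_max)
    modules <- detect_modules(network)
    modreg <- module_env_regression(modules$membership, cpm, md, cf$env_vars)
  } else message("single month: ssOTU detection skipped")

  # --- report bundle ---------------------------------------------------
  w <- function(df, f) if (!is.null(df))
    utils::write.table(df, file.path(cf$out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(data.frame(sample_id = rownames(alpha), alpha), "alpha.tsv")
  w(letters_tab, "alpha_letters.tsv")
  write_dist_matrix(bc,  file.path(cf$out_dir, "bray_curtis.tsv"))
  write_dist_matrix(uuf, file.path(cf$out_dir, "unweighted_unifrac.tsv"))
  write_dist_matrix(wuf, file.path(cf$out_dir, "weighted_unifrac.tsv"))
  w(mantel_tab, "mantel.tsv")
  w(procs, "assembly_pairs.tsv")
  w(proc_summary, "assembly_summary.tsv")
  if (!is.null(ssotu)) w(ssotu, "ssotus.tsv")
  if (!is.null(modreg)) w(modreg, "module_env_regression.tsv")

  cfg_public <- cf[c("rarefaction_depth", "n_null", "n_perm",
                     "bnti_threshold", "rc_threshold", "rho_min", "p_max",
                     "abundance_threshold", "env_vars", "weighted_bnti", "seed")]
  cfg_file <- file.path(cf$out_dir, "config.json")
  jsonlite::write_json(cfg_public, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "otuassembly",
    version = as.character(utils::packageVersion("otuassembly")),
    config = cfg_public,
    config_hash = unname(tools::md5sum(cfg_file)),
    stage_seeds = stats::setNames(sapply(1:12, function(k) stage_seed(cf, k)),
                                  paste0("stage", 1:12)),
    n_samples = ncol(rar), n_taxa_filtered = nrow(flt),
    months = months, dropped_samples = attr(rar, "dropped"))
  jsonlite::write_json(manifest, file.path(cf$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(rarefied = rar, filtered = flt, alpha = alpha,
                 alpha_letters = letters_tab, bray_curtis = bc, uuf = uuf,
                 wuf = wuf, pcoa = ord, anosim = anosim_res,
                 permanova = permanova_res, mantel = mantel_tab,
                 forward_selection = list(env = fs_env, trend = fs_trend,
                                          pcnm = fs_pcnm),
                 vpa = vpa, bnti = bnti, rcbray = rc, processes = procs,
                 process_summary = proc_summary, ssotu = ssotu,
                 network = network, modules = modules,
                 module_regression = modreg, manifest = manifest))
}
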