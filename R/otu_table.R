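#' Construct and validate an OTU count table
#'
#' An `otu_table` is a non-negative integer matrix with taxa as rows and
#' samples as columns, with unique row and column names. It is the object
#' every downstream stage (diversity, null models, networks) consumes.
#'
#' @param counts numeric matrix, taxa x samples, with dimnames. Values must
#'   be non-negative integers (integer-valued doubles are accepted).
#' @return an object of class `otu_table`: the validated integer-valued
#'   matrix.
#' @export
as_otu_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("OTU table needs taxon row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer or negative count at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "double"
  class(counts) <- c("otu_table", class(counts))
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d taxa x %d samples, %s reads total\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

taxon_ids  <- function(x) rownames(x)
sample_ids <- function(x) colnames(x)

#' Read an OTU table from a tab-separated file
#'
#' Expects one header row of sample ids and a first column of taxon ids
#' (the dense export format of QIIME-era tools), or the transposed layout.
#'
#' @param path file path.
#' @param taxa_are_rows logical; set `FALSE` for a samples x taxa file.
#' @return an [as_otu_table()] object.
#' @export
read_otu_table <- function(path, taxa_are_rows = TRUE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  if (!taxa_are_rows) m <- t(m)
  as_otu_table(m)
}

#' Write an OTU table as TSV (taxa as rows)
#' @param x otu_table. @param path output path.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(otu_id = rownames(x), as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] that enforces the invariants the
#' null models need: a single rooted tree, non-negative branch lengths
#' (missing lengths are set to 0 with a warning).
#'
#' @param path Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (inherits(tr, "multiPhylo")) stop("file contains more than one tree")
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warning("missing branch lengths set to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  tr
}

#' Write a phylogeny to Newick
#' @param tree phylo. @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Check that a tree covers the taxa of a table
#'
#' @param x otu_table. @param tree phylo.
#' @return invisibly `TRUE`; errors listing missing taxa otherwise.
#' @export
check_tree_coverage <- function(x, tree) {
  missing <- setdiff(taxon_ids(x), tree$tip.label)
  if (length(missing) > 0)
    stop("taxa absent from the tree: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read sample metadata from TSV
#'
#' One row per sample; must contain at least the columns named in
#' `required`. Row names are taken from the first column.
#'
#' @param path TSV path.
#' @param required character; columns that must be present.
#' @return data.frame with sample ids as row names.
#' @export
read_metadata <- function(path, required = c("station", "month")) {
  md <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, comment.char = "")
  miss <- setdiff(required, colnames(md))
  if (length(miss) > 0) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  md
}

#' Write sample metadata as TSV
#' @param md data.frame with sample row names. @param path output path.
#' @export
write_metadata <- function(md, path) {
  df <- data.frame(sample_id = rownames(md), md, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy an OTU table to even depth
#'
#' Without-replacement (multivariate hypergeometric) subsampling of each
#' sample to exactly `depth` reads. Samples with fewer than `depth` total
#' reads are dropped with a message.
#'
#' @param x otu_table. @param depth integer target reads per sample.
#' @param seed integer RNG seed; rarefaction is reproducible under it.
#' @return rarefied otu_table; attribute `"dropped"` lists removed samples.
#' @export
rarefy_table <- function(x, depth = 26000, seed = 1) {
  if (!is.numeric(depth) || depth < 1) stop("depth must be >= 1")
  depth <- as.integer(depth)
  totals <- colSums(x)
  keep <- totals >= depth
  dropped <- colnames(x)[!keep]
  if (length(dropped) > 0)
    message("dropped ", length(dropped), " sample(s) below depth ", depth, ": ",
            paste(dropped, collapse = ", "))
  if (!any(keep)) stop("no sample reaches the rarefaction depth")
  m <- unclass(x)[, keep, drop = FALSE]
  out <- withr::with_seed(seed, {
    apply(m, 2, function(col) {
      if (sum(col) == depth) return(col)
      reads <- rep.int(seq_along(col), col)
      picked <- sample(reads, depth, replace = FALSE)
      tabulate(picked, nbins = length(col))
    })
  })
  rownames(out) <- rownames(m)
  res <- as_otu_table(out)
  attr(res, "dropped") <- dropped
  res
}

#' Filter taxa by overall (pooled) relative abundance
#'
#' Keeps taxa whose share of the grand total strictly exceeds `threshold`
#' (e.g. `1e-4` for the common "> 0.01%" rule). Taxon order is preserved.
#'
#' @param x otu_table. @param threshold fraction in \[0, 1).
#' @return filtered otu_table.
#' @export
filter_by_abundance <- function(x, threshold = 1e-4) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0,1)")
  frac <- rowSums(x) / sum(x)
  keep <- frac > threshold
  if (!any(keep)) warning("no taxon passes the abundance filter")
  as_otu_table(unclass(x)[keep, , drop = FALSE])
}
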