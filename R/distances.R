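#' Construct a validated distance matrix
#'
#' The shared currency of the ordination and permutation machinery: a
#' square, symmetric, zero-diagonal, non-negative matrix over sample (or
#' station) ids. Small asymmetries from floating point are symmetrized;
#' real violations error.
#'
#' @param m square numeric matrix with identical row/column names.
#' @return object of class `dist_matrix` (a matrix).
#' @export
as_dist_matrix <- function(m) {
  if (inherits(m, "dist")) m <- as.matrix(m)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m))) rownames(m) <- colnames(m)
  if (is.null(rownames(m))) stop("distance matrix needs ids")
  if (!identical(rownames(m), colnames(m))) stop("row/column ids differ")
  if (max(abs(m - t(m))) > 1e-8) stop("matrix is not symmetric")
  if (any(m < -1e-12)) stop("negative distances")
  m <- (m + t(m)) / 2
  m[m < 0] <- 0
  diag(m) <- 0
  class(m) <- c("dist_matrix", class(m))
  m
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("distance matrix over %d ids (mean off-diagonal %.4g)\n",
              nrow(x), mean(x[upper.tri(x)])))
  invisible(x)
}

dist_ids <- function(d) rownames(d)

#' Lower-triangle vector of a distance matrix
#' @param d dist_matrix. @return numeric vector (column-major lower triangle).
#' @export
dist_vec <- function(d) d[lower.tri(d)]

#' Euclidean distance over metadata columns
#'
#' Pairwise Euclidean distance across selected numeric metadata variables,
#' optionally z-scored first (the convention for heterogeneous
#' environmental variables). Missing values error unless column-mean
#' imputation is explicitly enabled.
#'
#' @param md metadata data.frame (sample row names).
#' @param vars character vector of column names.
#' @param standardize z-score each variable first (default `TRUE`).
#' @param impute_mean replace missing values by the column mean (default
#'   `FALSE`: fail fast, naming the sample and variable).
#' @return dist_matrix over samples.
#' @export
env_distance <- function(md, vars, standardize = TRUE, impute_mean = FALSE) {
  miss <- setdiff(vars, colnames(md))
  if (length(miss) > 0) stop("unknown variables: ", paste(miss, collapse = ", "))
  m <- as.matrix(md[, vars, drop = FALSE])
  if (!is.numeric(m)) stop("selected variables must be numeric")
  if (anyNA(m)) {
    if (!impute_mean) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("missing value for sample '%s', variable '%s'",
                   rownames(m)[bad[1]], vars[bad[2]]))
    }
    message("imputing missing environmental values by column means")
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mean(m[, j], na.rm = TRUE)
  }
  if (standardize) m <- scale(m)
  as_dist_matrix(as.matrix(stats::dist(m)))
}

#' Geographic distance between samples
#'
#' Euclidean distance on raw decimal-degree coordinates by default (the
#' "Geo" convention of distance-decay tables); `great_circle = TRUE`
#' switches to haversine distance in kilometres.
#'
#' @param md metadata with `longitude` and `latitude` columns.
#' @param great_circle use great-circle km instead of degree Euclidean.
#' @return dist_matrix over samples.
#' @export
geo_distance <- function(md, great_circle = FALSE) {
  if (!all(c("longitude", "latitude") %in% colnames(md)))
    stop("metadata needs longitude and latitude columns")
  xy <- as.matrix(md[, c("longitude", "latitude")])
  if (anyNA(xy) || any(!is.finite(xy))) stop("non-finite coordinates")
  if (!great_circle) return(as_dist_matrix(as.matrix(stats::dist(xy))))
  n <- nrow(xy)
  rad <- pi / 180
  lat <- xy[, 2] * rad; lon <- xy[, 1] * rad
  d <- matrix(0, n, n, dimnames = list(rownames(xy), rownames(xy)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    h <- sin((lat[j] - lat[i]) / 2)^2 +
      cos(lat[i]) * cos(lat[j]) * sin((lon[j] - lon[i]) / 2)^2
    d[i, j] <- d[j, i] <- 2 * 6371 * asin(min(1, sqrt(h)))
  }
  as_dist_matrix(d)
}

#' Write / read a square distance matrix as TSV
#'
#' Square tab-separated layout with an id header row and id first column
#' (the matrix dialect of QIIME-era tools).
#' @param d dist_matrix. @param path file path.
#' @export
write_dist_matrix <- function(d, path) {
  df <- data.frame(id = rownames(d), as.data.frame(unclass(d), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, comment.char = "")
  as_dist_matrix(as.matrix(df))
}
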