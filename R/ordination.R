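# Community-structure comparison: Euclidean distances between standardized
# profiles, complete-linkage hierarchical clustering, and PCA.

#' Euclidean distances between sample profiles
#'
#' `d(i, j) = sqrt(sum_bins (x_bi - x_bj)^2)` over standardized relative
#' abundances, samples as the entities.
#'
#' @param bm a standardized [binned_matrix] with at least two samples.
#' @return A `dist` object labelled by sample id.
#' @export
euclidean_distances <- function(bm) {
  stopifnot(inherits(bm, "binned_matrix"))
  if (!bm$standardized) {
    stop("contract violation: euclidean_distances requires a standardized ",
         "binned matrix", call. = FALSE)
  }
  if (ncol(bm$values) < 2L) {
    stop("at least 2 samples are required for a distance matrix",
         call. = FALSE)
  }
  stats::dist(t(bm$values), method = "euclidean")
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerates samples by iteratively merging the pair of clusters with
#' the smallest maximum inter-cluster distance; the recorded merge height
#' is that maximum, so heights are non-decreasing. Ties are broken
#' deterministically by the agglomeration order of [stats::hclust()].
#'
#' @param d a `dist` object (n >= 2), e.g. from [euclidean_distances()].
#' @return An `hclust` object; leaf labels are the sample ids.
#' @export
complete_linkage <- function(d) {
  stopifnot(inherits(d, "dist"))
  if (attr(d, "Size") < 2L) {
    stop("at least 2 samples are required for clustering", call. = FALSE)
  }
  stats::hclust(d, method = "complete")
}

#' Principal component analysis of standardized profiles
#'
#' Samples are the observations and bins the variables. Variables are
#' mean-centered but not variance-scaled (no further normalization beyond
#' the within-sample standardization already applied). The sign of each
#' component is fixed by convention — the largest-magnitude loading is made
#' positive — so results are deterministic.
#'
#' @param bm a standardized [binned_matrix] with at least two samples.
#' @return An object of class `trflp_pca`: list with `scores` (samples x
#'   components), `loadings` (bins x components), `variance` (per
#'   component) and `variance_explained_percent`.
#' @export
pca <- function(bm) {
  stopifnot(inherits(bm, "binned_matrix"))
  if (!bm$standardized) {
    stop("contract violation: pca requires a standardized binned matrix",
         call. = FALSE)
  }
  x <- t(bm$values)
  if (nrow(x) < 2L) stop("at least 2 samples are required for PCA",
                         call. = FALSE)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (sum(pr$sdev^2) <= 0) {
    stop("zero total variance: all sample profiles are identical",
         call. = FALSE)
  }
  # sign convention: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, k]))
    if (pr$rotation[i, k] < 0) {
      pr$rotation[, k] <- -pr$rotation[, k]
      pr$x[, k] <- -pr$x[, k]
    }
  }
  variance <- pr$sdev^2
  structure(list(scores = pr$x,
                 loadings = pr$rotation,
                 variance = variance,
                 variance_explained_percent = 100 * variance /
                   sum(variance)),
            class = "trflp_pca")
}

#' @export
print.trflp_pca <- function(x, ...) {
  k <- min(3L, length(x$variance))
  cat("PCA of", nrow(x$scores), "samples;",
      paste(sprintf("PC%d %.1f%%", seq_len(k),
                    x$variance_explained_percent[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}
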