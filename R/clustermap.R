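#' Row Z-score normalization
#'
#' Centers and scales each row to mean 0, SD 1 (sample SD, n - 1). Constant
#' rows cannot be scaled and are dropped with a warning.
#'
#' @param m numeric matrix (features x samples).
#' @return Z-scored matrix, possibly with fewer rows.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 1L, sd)
  keep <- sds > 0
  if (any(!keep))
    warning("dropping ", sum(!keep), " constant row(s): ",
            paste(head(rownames(m)[!keep], 5L), collapse = ", "))
  m <- m[keep, , drop = FALSE]
  (m - rowMeans(m)) / sds[keep]
}

#' Uncentered Pearson correlation
#'
#' The cosine-like similarity `sum(x * y) / sqrt(sum(x^2) * sum(y^2))`
#' (Pearson's correlation without mean-centering), the metric of the
#' classic Cluster 3.0 expression-clustering workflow. Clustering uses
#' `1 - similarity` as the distance.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return similarity in `[-1, 1]`.
#' @export
uncentered_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 2L) stop("need vectors of length >= 2")
  nx <- sum(x^2); ny <- sum(y^2)
  if (nx == 0 || ny == 0) stop("zero-norm vector in uncentered_pearson")
  sum(x * y) / sqrt(nx * ny)
}

# All-pairs uncentered Pearson distance over matrix rows, via crossprod.
uncentered_dist <- function(m) {
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) stop("zero-norm row(s) cannot be clustered")
  s <- tcrossprod(m / norms)
  s[s > 1] <- 1; s[s < -1] <- -1
  as.dist(1 - s)
}

#' Agglomerative clustering with uncentered Pearson distance
#'
#' Hierarchically clusters rows or columns of a profile matrix using
#' `1 - uncentered Pearson` as the distance, with average linkage by
#' default. Agglomeration is deterministic (stats::hclust's fixed
#' lowest-index merge order for ties).
#'
#' @param m numeric matrix (>= 2 items on the clustered axis).
#' @param axis "rows" or "cols".
#' @param linkage "average" (default), "complete" or "single".
#' @return an [stats::hclust] object; `$order` gives the leaf order.
#' @export
hcluster <- function(m, axis = c("rows", "cols"), linkage = "average") {
  axis <- match.arg(axis)
  m <- as.matrix(m)
  if (axis == "cols") m <- t(m)
  if (nrow(m) < 2L) stop("need >= 2 items to cluster")
  hclust(uncentered_dist(m), method = linkage)
}

#' Cluster an activity / expression profile matrix on both axes
#'
#' The standard workflow behind allele-activity and expression heatmaps:
#' optionally filter rows to the most variable quantile, Z-score rows, then
#' cluster rows and columns with uncentered Pearson / average linkage.
#'
#' @param m profile matrix (features x cell lines).
#' @param zscore apply [zscore_rows()] first (default TRUE).
#' @param var_quantile keep rows whose variance is above this quantile
#'   (default 0 = keep all); the variance filter runs before Z-scoring.
#' @param linkage linkage method.
#' @return list of class `dir_clustering`: `matrix` (processed, reordered),
#'   `row_hc`, `col_hc` ([stats::hclust] objects), `row_order`, `col_order`.
#' @export
cluster_profiles <- function(m, zscore = TRUE, var_quantile = 0,
                             linkage = "average") {
  m <- as.matrix(m)
  if (var_quantile > 0) {
    v <- apply(m, 1L, stats::var)
    m <- m[v >= stats::quantile(v, var_quantile), , drop = FALSE]
  }
  if (zscore) m <- zscore_rows(m)
  row_hc <- hcluster(m, "rows", linkage)
  col_hc <- hcluster(m, "cols", linkage)
  structure(list(matrix = m[row_hc$order, col_hc$order, drop = FALSE],
                 row_hc = row_hc, col_hc = col_hc,
                 row_order = row_hc$order, col_order = col_hc$order),
            class = "dir_clustering")
}

#' Write a clustering result as ordered TSV plus Newick dendrograms
#'
#' @param cl `dir_clustering` from [cluster_profiles()].
#' @param matrix_path ordered-matrix TSV path.
#' @param row_tree_path,col_tree_path optional Newick outputs (via
#'   [ape::write.tree()]).
#' @export
write_clustering <- function(cl, matrix_path, row_tree_path = NULL,
                             col_tree_path = NULL) {
  df <- data.frame(feature = rownames(cl$matrix), cl$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(row_tree_path))
    ape::write.tree(ape::as.phylo(cl$row_hc), row_tree_path)
  if (!is.null(col_tree_path))
    ape::write.tree(ape::as.phylo(cl$col_hc), col_tree_path)
  invisible(matrix_path)
}

#' Top-split membership of a column dendrogram
#'
#' Utility for checking planted two-block structure: cuts the tree into two
#' clusters at the top merge.
#'
#' @param hc [stats::hclust] object.
#' @return integer vector of cluster labels (1/2) in input item order.
#' @export
top_split <- function(hc) {
  unname(cutree(hc, k = 2L))
}
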