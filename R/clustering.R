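#' Log base 150 transform of expression scores
#'
#' Expression scores are mapped to \code{log150(x) = ln(x) / ln(150)} so
#' that the normal-tissue ceiling (150) maps to 1. Scores below 1 (including
#' 0) are clipped to 1 before the log, avoiding divergence at zero for the
#' positive, right-skewed signal scale.
#'
#' @param x non-negative score(s); \code{NA} passes through.
#' @export
log150_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("scores must be non-negative")
  log(pmax(x, 1)) / log(150)
}

#' City-block distance with pairwise-complete observations
#'
#' Mean absolute difference over jointly observed components. Using the
#' mean (rather than the sum) keeps distances comparable between vector
#' pairs with different missingness patterns.
#'
#' @param a,b numeric vectors of equal length; \code{NA} entries are
#'   skipped pairwise.
#' @export
cityblock_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no jointly observed components")
  mean(abs(a[ok] - b[ok]))
}

#' Correlation distance with pairwise-complete observations
#'
#' One minus the Pearson correlation over jointly observed components
#' (\code{centered = TRUE}), or one minus the uncentered cosine similarity
#' (\code{centered = FALSE}).
#'
#' @param a,b numeric vectors of equal length.
#' @param centered use centered Pearson correlation (default) or the
#'   uncentered cosine variant.
#' @export
correlation_distance <- function(a, b, centered = TRUE) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) stop("need at least two jointly observed components")
  a <- a[ok]; b <- b[ok]
  if (centered) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("zero variance over the jointly observed components; ",
           "consider centered = FALSE or removing constant items")
    1 - stats::cor(a, b)
  } else {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0)
      stop("zero norm over the jointly observed components")
    1 - sum(a * b) / (na * nb)
  }
}

#' Pairwise distance matrix over the rows of a matrix
#'
#' @param x numeric matrix (items in rows); may contain \code{NA}.
#' @param metric \code{"cityblock"} or \code{"correlation"}.
#' @param centered passed to \code{\link{correlation_distance}}.
#' @return symmetric numeric matrix with zero diagonal, row/col names from
#'   \code{x}, and a \code{"metric"} attribute.
#' @export
pairwise_distances <- function(x, metric = c("cityblock", "correlation"),
                               centered = TRUE) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  f <- switch(metric,
              cityblock = cityblock_distance,
              correlation = function(a, b)
                correlation_distance(a, b, centered = centered))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- f(x[i, ], x[j, ])
  attr(d, "metric") <- metric
  d
}

#' Average-linkage (UPGMA) agglomerative clustering
#'
#' Repeatedly merges the closest pair of clusters, with the inter-cluster
#' distance updated as the size-weighted mean
#' \code{d(C, A+B) = (|A| d(C,A) + |B| d(C,B)) / (|A| + |B|)} (exact group
#' average). Ties are broken deterministically by the smallest (index,
#' index) pair, where leaves carry their input index and merged clusters
#' are indexed in order of creation. Returns a standard \code{hclust}
#' object so that \code{plot()}, \code{\link[stats]{cutree}} and tree
#' exports apply.
#'
#' @param d symmetric distance matrix (e.g. \code{\link{pairwise_distances}})
#'   or a \code{\link[stats]{dist}} object.
#' @return object of class \code{hclust} with \code{method = "average"}.
#' @export
average_linkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least two items to cluster")
  if (anyNA(d)) stop("distance matrix contains missing values")
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0))
    stop("`d` must be symmetric with zero diagonal")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # active clusters keyed by creation index: leaves 1..n, merges n+1..2n-1
  active <- seq_len(n)
  size <- rep(1L, n)
  code <- -seq_len(n)            # hclust coding: -leaf or +merge step
  D <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    m <- length(active)
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_len(m - 1)) for (jj in (ii + 1):m) {
      dij <- D[ii, jj]
      if (dij < bestd) { bestd <- dij; best <- c(ii, jj) }
    }
    # active[] stays sorted by creation index, so the first strict
    # minimum found IS the smallest (index, index) tie-break pair
    ii <- best[1]; jj <- best[2]
    height[s] <- bestd
    merge[s, ] <- sort(c(code[ii], code[jj]))
    new_row <- (size[ii] * D[ii, ] + size[jj] * D[jj, ]) /
      (size[ii] + size[jj])
    keep <- setdiff(seq_len(m), c(ii, jj))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], new_row[keep]),
               c(new_row[keep], 0))
    active <- c(active[keep], n + s)
    size <- c(size[keep], size[ii] + size[jj])
    code <- c(code[keep], s)
  }
  # leaf order: recurse, earlier-created child on the left
  leaves <- function(x) {
    if (x < 0) return(-x)
    c(leaves(merge[x, 1]), leaves(merge[x, 2]))
  }
  structure(list(merge = merge, height = height,
                 order = leaves(n - 1L), labels = labels,
                 method = "average",
                 dist.method = attr(d, "metric") %||% "unknown",
                 call = match.call()),
            class = "hclust")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cut a dendrogram into k clusters
#'
#' Labels induced by removing the k-1 highest merges (equivalent to
#' \code{\link[stats]{cutree}} for the monotone average-linkage trees
#' produced here).
#'
#' @param dendrogram an \code{hclust} object.
#' @param k number of clusters, \code{1 <= k <= n}.
#' @return integer cluster labels named by leaf label.
#' @export
cut_tree <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$order)
  if (k < 1 || k > n) stop("k must lie in 1..", n)
  stats::cutree(dendrogram, k = k)
}

#' Two-way hierarchical clustering of a data matrix
#'
#' Clusters rows and columns independently with their own metrics
#' (city-block for samples/cases and correlation for antibodies/markers, by
#' default), optionally applying the log-base-150 transform first
#' (expression mode), and reorders the matrix by both leaf orders.
#'
#' @param x numeric matrix (rows = samples/cases, columns =
#'   antibodies/markers); may contain \code{NA}.
#' @param row_metric,col_metric distance metrics, \code{"cityblock"} or
#'   \code{"correlation"}.
#' @param transform \code{"none"} or \code{"log150"}.
#' @param centered passed to the correlation distance.
#' @return list with \code{row_dendrogram}, \code{col_dendrogram} (both
#'   \code{hclust}) and \code{matrix} (input reordered by both leaf
#'   orders, after any transform).
#' @export
two_way_cluster <- function(x, row_metric = "cityblock",
                            col_metric = "correlation",
                            transform = c("none", "log150"),
                            centered = TRUE) {
  transform <- match.arg(transform)
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("matrix must be at least 2 x 2")
  if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("col", seq_len(ncol(x)))
  all_na_row <- rowSums(!is.na(x)) == 0
  if (any(all_na_row))
    stop("row(s) with no observed values: ",
         paste(rownames(x)[all_na_row], collapse = ", "))
  all_na_col <- colSums(!is.na(x)) == 0
  if (any(all_na_col))
    stop("column(s) with no observed values: ",
         paste(colnames(x)[all_na_col], collapse = ", "))
  if (transform == "log150") x <- log150_transform(x)
  rd <- average_linkage(pairwise_distances(x, row_metric,
                                           centered = centered))
  cd <- average_linkage(pairwise_distances(t(x), col_metric,
                                           centered = centered))
  list(row_dendrogram = rd, col_dendrogram = cd,
       matrix = x[rd$order, cd$order, drop = FALSE])
}

#' Write a dendrogram as a Newick tree
#'
#' Branch lengths are derived from merge heights (each child branch spans
#' the height difference between a node and its child).
#'
#' @param dendrogram an \code{hclust} object.
#' @param path output file.
#' @export
write_newick <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "hclust"))
  ape::write.tree(ape::as.phylo(dendrogram), file = path)
  invisible(path)
}

#' Write a clustered data table with row/column tree files
#'
#' Exports the reordered matrix from \code{\link{two_way_cluster}} in the
#' tab-delimited clustered-table convention used by TreeView-style viewers:
#' a \code{.cdt} table whose rows and columns follow the dendrogram leaf
#' orders plus \code{.gtr} / \code{.atr} files listing the row and column
#' merges (node id, children, height).
#'
#' @param tw result of \code{\link{two_way_cluster}}.
#' @param basename output path without extension.
#' @return invisibly, the three file paths written.
#' @export
write_clustered_table <- function(tw, basename) {
  write_tree_file <- function(hc, prefix, path) {
    nodes <- data.frame(
      node = paste0("NODE", seq_along(hc$height), "X"),
      left = ifelse(hc$merge[, 1] < 0,
                    paste0(prefix, -hc$merge[, 1], "X"),
                    paste0("NODE", hc$merge[, 1], "X")),
      right = ifelse(hc$merge[, 2] < 0,
                     paste0(prefix, -hc$merge[, 2], "X"),
                     paste0("NODE", hc$merge[, 2], "X")),
      height = hc$height)
    utils::write.table(nodes, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  gtr <- paste0(basename, ".gtr")
  atr <- paste0(basename, ".atr")
  cdt <- paste0(basename, ".cdt")
  rhc <- tw$row_dendrogram; chc <- tw$col_dendrogram
  write_tree_file(rhc, "GENE", gtr)
  write_tree_file(chc, "ARRY", atr)
  m <- tw$matrix
  gid <- paste0("GENE", rhc$order, "X")
  header <- c("GID", "UNIQID", "NAME", colnames(m))
  aid <- c("AID", "", "", paste0("ARRY", chc$order, "X"))
  body <- cbind(gid, rownames(m), rownames(m),
                matrix(as.character(m), nrow = nrow(m)))
  con <- file(cdt, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(paste(aid, collapse = "\t"), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(cdt = cdt, gtr = gtr, atr = atr))
}
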