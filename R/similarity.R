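#' Pearson correlation matrix between samples
#'
#' Correlations are computed over all genes on raw FPKM values, the
#' convention used for sample-level QC heat maps; expression filters are
#' applied only to the clustering heat map, not here.
#'
#' @param em an `expression_matrix` with at least two samples.
#' @return Symmetric correlation matrix over samples with unit diagonal.
#' @export
pearson_matrix <- function(em) {
  m <- if (inherits(em, "expression_matrix")) em$fpkm else as.matrix(em)
  if (ncol(m) < 2) stopf("at least two samples are required")
  v <- apply(m, 2, stats::var)
  flat <- colnames(m)[v == 0]
  if (length(flat))
    stopf("sample '%s' has zero variance; correlation undefined", flat[1])
  stats::cor(m, method = "pearson")
}

#' Manhattan distances of a log-transformed expression matrix
#'
#' Pairwise L1 distances between genes (rows) or samples (columns) of an
#' already log-transformed matrix, as used for expression clustering.
#'
#' @param t numeric matrix of log10-transformed FPKM values (see
#'   [log_transform()]).
#' @param axis `"genes"` (rows) or `"samples"` (columns).
#' @return A `dist` object.
#' @export
manhattan_log_distance <- function(t, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  m <- as.matrix(t)
  if (axis == "samples") m <- t(m)
  stats::dist(m, method = "manhattan")
}

#' Agglomerative hierarchical clustering with group-average or Ward linkage
#'
#' Wraps agglomerative clustering with the two linkages used for
#' expression heat maps: the group average method (UPGMA) for genes and
#' Ward's method for samples. Returns the merge history in a
#' `linkage_result` that also keeps the underlying `hclust` object for
#' dendrogram plotting.
#'
#' @param d a `dist` object or a symmetric matrix with zero diagonal.
#' @param method `"group_average"` or `"ward"`.
#' @return An object of class `linkage_result` with fields `merge`
#'   (standard hclust merge matrix), `height`, `order` (leaf order),
#'   `labels`, `method` and `hclust`.
#' @export
hcluster <- function(d, method = c("group_average", "ward")) {
  method <- match.arg(method)
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (nrow(m) != ncol(m)) stopf("distance matrix must be square")
    if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
      stopf("distance matrix must be symmetric")
    if (any(diag(m) != 0)) stopf("distance matrix must have zero diagonal")
    d <- stats::as.dist(m)
  }
  hc <- stats::hclust(d, method = switch(method,
                                         group_average = "average",
                                         ward = "ward.D2"))
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, method = method, hclust = hc),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("linkage_result: %d leaves, %s linkage\n",
              length(x$height) + 1L, x$method))
  invisible(x)
}

#' Newick serialization of a linkage result
#'
#' Writes the merge tree in nested-parenthesis (Newick) form with merge
#' heights as internal-node labels removed and branch lengths derived
#' from heights (each child branch spans the height difference to its
#' parent merge).
#'
#' @param lr a `linkage_result`.
#' @return A single Newick string terminated by ";".
#' @export
linkage_newick <- function(lr) {
  stopifnot(inherits(lr, "linkage_result"))
  merge <- lr$merge; height <- lr$height
  labels <- lr$labels %||% as.character(seq_len(nrow(merge) + 1))
  node <- function(i) {
    # leaves are negative indices; merges positive
    if (i < 0) list(str = labels[-i], h = 0)
    else {
      a <- node(merge[i, 1]); b <- node(merge[i, 2])
      list(str = sprintf("(%s:%g,%s:%g)", a$str, height[i] - a$h,
                         b$str, height[i] - b$h),
           h = height[i])
    }
  }
  paste0(node(nrow(merge))$str, ";")
}

#' Per-gene z-score normalization for heat-map coloration
#'
#' Centers each gene row and scales it to unit uncorrected (divisor n)
#' standard deviation; rows with zero spread map to all-zeros rather
#' than NaN.
#'
#' @param t numeric matrix (genes x samples), typically log10 FPKM.
#' @return Matrix of the same shape with row means 0 and row SDs 1
#'   (uncorrected) except for constant rows.
#' @export
normalize_for_heatmap <- function(t) {
  m <- as.matrix(t)
  if (ncol(m) < 2) stopf("at least two samples per gene are required")
  mu <- rowMeans(m)
  centred <- m - mu
  sd_n <- sqrt(rowMeans(centred^2))
  out <- centred / ifelse(sd_n == 0, 1, sd_n)
  out[sd_n == 0, ] <- 0
  out
}
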