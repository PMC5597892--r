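## PCA of high-expression genes and hierarchical clustering of DEGs.
## Samples are the observations (the plotted points); genes are variables.

#' PCA of an expression matrix
#'
#' Samples are observations and genes variables; the matrix is column-mean
#' centred and, by default, not scaled. Optionally restrict to genes whose
#' maximum FPKM exceeds a threshold before decomposing.
#'
#' @param x FPKM matrix (genes x samples) or `SummarizedExperiment` with
#'   assay `fpkm`.
#' @param genes Optional gene subset.
#' @param minMaxFpkm If not `NULL`, keep genes with row-max FPKM strictly
#'   above this value (applied after `genes`).
#' @param scale. Scale variables to unit variance; default `FALSE`.
#' @return A list of class `serpentomePca` with `scores` (samples x PCs),
#'   `proportionVariance`, `loadings` (genes x PCs), `sdev` and `nGenes`.
#' @export
runPca <- function(x, genes = NULL, minMaxFpkm = NULL, scale. = FALSE) {
  mat <- if (is(x, "SummarizedExperiment")) assay(x, "fpkm") else as.matrix(x)
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
  if (!is.null(minMaxFpkm))
    mat <- mat[apply(mat, 1L, max) > minMaxFpkm, , drop = FALSE]
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    .stopf("runPca: need at least 2 genes and 2 samples")
  obs <- t(mat)
  if (all(apply(obs, 2L, sd) == 0))
    .stopf("runPca: matrix is constant, no variance to decompose")
  p <- prcomp(obs, center = TRUE, scale. = scale.)
  structure(list(scores = p$x,
                 proportionVariance = p$sdev^2 / sum(p$sdev^2),
                 loadings = p$rotation,
                 sdev = p$sdev,
                 nGenes = nrow(mat)),
            class = "serpentomePca")
}

#' @export
print.serpentomePca <- function(x, ...) {
  pv <- round(100 * x$proportionVariance[seq_len(min(3L, length(x$proportionVariance)))])
  cat(sprintf("PCA of %d genes x %d samples; PC1-%d: %s%% of variance\n",
              x$nGenes, nrow(x$scores), length(pv),
              paste(pv, collapse = "/")))
  invisible(x)
}

#' Spearman-correlation distance between matrix rows
#'
#' `d(i, j) = 1 - rho_s(i, j)` where `rho_s` is the Pearson correlation of
#' (average-tie) ranks. Constant rows have undefined correlation and raise
#' an error naming the offending rows.
#'
#' @param mat Numeric matrix; distances are between rows.
#' @return A symmetric distance matrix with zero diagonal, values in
#'   `[0, 2]`.
#' @export
spearmanDistance <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) .stopf("spearmanDistance: need >= 2 columns")
  const <- apply(mat, 1L, function(r) all(r == r[1L]))
  if (any(const))
    .stopf("spearmanDistance: constant row(s), correlation undefined: %s",
           paste(head(rownames(mat)[const] %||% which(const), 5L), collapse = ", "))
  d <- 1 - cor(t(mat), method = "spearman")
  diag(d) <- 0
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Thin validated wrapper around `hclust(method = "average")`: the distance
#' between two clusters is the unweighted mean over all cross-cluster pairs.
#'
#' @param d Symmetric distance matrix with zero diagonal, or a `dist`.
#' @return An `hclust` object (merge history, heights, leaf order).
#' @export
averageLinkage <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
      .stopf("averageLinkage: distance matrix must be symmetric")
    if (any(abs(diag(d)) > 1e-12))
      .stopf("averageLinkage: diagonal must be zero")
    d <- as.dist(d)
  }
  hclust(d, method = "average")
}

#' Heat-map-ready ordered matrix
#'
#' Log2-transforms and median-centres the selected genes, then orders rows
#' by the dendrogram's leaf order (and columns by `sampleOrder` if given).
#'
#' @param x FPKM matrix or `SummarizedExperiment` with assay `fpkm`.
#' @param genes Gene subset (typically strict DEGs).
#' @param dendro `hclust` over `genes` (labels must match), or `NULL` to
#'   cluster here with Spearman distance and average linkage.
#' @param sampleOrder Optional column order.
#' @param eps Pseudocount for the log transform; default 1.
#' @return The ordered, centred matrix.
#' @export
heatmapMatrix <- function(x, genes, dendro = NULL, sampleOrder = NULL,
                          eps = 1) {
  centred <- log2MedianCenter(x, genes = genes, eps = eps)
  if (is.null(dendro)) dendro <- averageLinkage(spearmanDistance(centred))
  leaves <- if (!is.null(dendro$labels)) dendro$labels[dendro$order] else dendro$order
  if (!setequal(leaves, rownames(centred)))
    .stopf("heatmapMatrix: dendrogram leaves do not match gene subset")
  out <- centred[leaves, , drop = FALSE]
  if (!is.null(sampleOrder)) out <- out[, sampleOrder, drop = FALSE]
  out
}
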