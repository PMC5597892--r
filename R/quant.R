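## Gene-level quantification. The gene model follows the representative-
## transcript convention: a gene's length is its longest transcript's length,
## and its fragment count is the sum over member transcripts.

#' Aggregate transcript counts to gene level
#'
#' @param se Transcript-level `SummarizedExperiment` from [readCountTable()].
#' @return A gene-level `SummarizedExperiment` (rows ordered by `gene_id`)
#'   with rowData `length_nt` (longest member transcript) and
#'   `n_transcripts`; `metadata(se)$geneModels` holds the gene models
#'   (`gene_id`, `representative_length_nt`, `member_transcripts`,
#'   semicolon-separated).
#' @export
aggregateToGenes <- function(se) {
  rd <- rowData(se)
  if (is.null(rd$gene_id)) .stopf("aggregateToGenes: rowData lacks gene_id")
  gene <- as.character(rd$gene_id)
  counts <- assay(se, "counts")
  agg <- rowsum(counts, group = gene, reorder = TRUE)
  ord <- order(gene)
  len <- vapply(split(rd$length_nt, gene), max, numeric(1))
  members <- vapply(split(rownames(se), gene),
                    function(x) paste(x, collapse = ";"), character(1))
  ntx <- vapply(split(rd$length_nt, gene), length, integer(1))
  gids <- rownames(agg)
  out <- SummarizedExperiment(
    assays = list(counts = agg),
    rowData = DataFrame(gene_id = gids,
                        length_nt = as.integer(len[gids]),
                        n_transcripts = ntx[gids],
                        row.names = gids),
    colData = colData(se))
  metadata(out)$geneModels <- data.frame(
    gene_id = gids,
    representative_length_nt = as.integer(len[gids]),
    member_transcripts = members[gids],
    stringsAsFactors = FALSE)
  out
}

#' FPKM normalisation
#'
#' `FPKM[g, s] = counts[g, s] * 1e9 / (length_nt[g] * N[s])` where `N[s]` is
#' the per-sample total mapped fragment count. By default `N` is the column
#' sum of the gene-level table; an explicit named vector (e.g. aligner
#' totals) overrides it.
#'
#' @param se Gene-level `SummarizedExperiment` (see [aggregateToGenes()]).
#' @param totals Optional named numeric vector of per-sample totals; names
#'   must cover all samples and values must be positive.
#' @return A `SummarizedExperiment` with assay `fpkm`; the totals used are
#'   kept in `metadata()$totals`.
#' @export
computeFpkm <- function(se, totals = NULL) {
  counts <- assay(se, "counts")
  len <- rowData(se)$length_nt
  if (is.null(len)) .stopf("computeFpkm: rowData lacks length_nt")
  if (is.null(totals)) {
    totals <- colSums(counts)
  } else {
    if (is.null(names(totals)) || !all(colnames(counts) %in% names(totals)))
      .stopf("computeFpkm: totals must be named for every sample")
    totals <- totals[colnames(counts)]
  }
  if (any(totals <= 0)) .stopf("computeFpkm: totals must be positive")
  fpkm <- sweep(counts * 1e9 / len, 2L, totals, "/")
  out <- SummarizedExperiment(assays = list(fpkm = fpkm),
                              rowData = rowData(se), colData = colData(se))
  metadata(out)$totals <- totals
  out
}

#' Log2 transform and median-centre expression rows
#'
#' Heat-map normalisation: `log2(FPKM + eps)` followed by subtraction of each
#' gene's row median, so every row has median zero.
#'
#' @param x An FPKM matrix or a `SummarizedExperiment` with assay `fpkm`.
#' @param genes Optional gene subset (default: all rows).
#' @param eps Pseudocount added before the log; default 1.
#' @return A centred numeric matrix.
#' @export
log2MedianCenter <- function(x, genes = NULL, eps = 1) {
  mat <- if (is(x, "SummarizedExperiment")) assay(x, "fpkm") else as.matrix(x)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(mat))
    if (length(missing) > 0L)
      .stopf("log2MedianCenter: gene(s) not in matrix: %s",
             paste(head(missing, 5L), collapse = ", "))
    mat <- mat[genes, , drop = FALSE]
  }
  if (nrow(mat) == 0L) .stopf("log2MedianCenter: empty gene subset")
  lg <- log2(mat + eps)
  lg - apply(lg, 1L, median)
}

#' Select genes by row-maximum FPKM
#'
#' @param x FPKM matrix or `SummarizedExperiment` with assay `fpkm`.
#' @param threshold Non-negative FPKM threshold.
#' @param strict If `TRUE` (default) the row maximum must exceed the
#'   threshold; if `FALSE`, meeting it suffices.
#' @return Character vector of selected gene ids.
#' @export
filterByMaxFpkm <- function(x, threshold, strict = TRUE) {
  if (threshold < 0) .stopf("filterByMaxFpkm: threshold must be >= 0")
  mat <- if (is(x, "SummarizedExperiment")) assay(x, "fpkm") else as.matrix(x)
  mx <- apply(mat, 1L, max)
  keep <- if (strict) mx > threshold else mx >= threshold
  rownames(mat)[keep]
}
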