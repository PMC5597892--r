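## GO over-representation by Fisher's exact test (one-sided hypergeometric
## tail), BH-FDR control, most-specific-term reduction over an is_a/part_of
## DAG, and KEGG-style colour-file export of trend classes.

## annotation (data.frame gene_id/go_terms or named list term -> genes)
## -> named list term -> gene ids
.termGeneList <- function(annotation) {
  if (is.list(annotation) && !is.data.frame(annotation)) return(annotation)
  .checkColumns(annotation, c("gene_id", "go_terms"), "annotation")
  has <- nzchar(annotation$go_terms)
  terms <- strsplit(annotation$go_terms[has], ";", fixed = TRUE)
  split(rep(annotation$gene_id[has], lengths(terms)), unlist(terms))
}

.annotationGenes <- function(annotation) {
  if (is.data.frame(annotation)) return(annotation$gene_id)
  unique(unlist(annotation, use.names = FALSE))
}

#' GO over-representation by Fisher's exact test
#'
#' For each term annotated to at least one test-set gene, computes the
#' one-sided (over-representation) hypergeometric tail
#' `p = P(X >= k)` for `k` test-set genes carrying the term out of `n`,
#' against `K` carriers in the reference universe of `N` genes. By default
#' the test set stays inside the reference when forming the table (test vs
#' whole reference); `exclusive = TRUE` tests test vs rest.
#'
#' @param testSet Character vector of gene ids, a subset of the reference.
#' @param annotation Reference annotation: data.frame (`gene_id`,
#'   `go_terms` semicolon-separated) or a named list `term -> gene ids`.
#' @param universe Optional explicit reference gene universe; defaults to
#'   the annotation's genes.
#' @param exclusive Report the 2x2 table as test-vs-rest (carriers and
#'   universe counted outside the test set). The exact one-sided p is
#'   unchanged: both tables condition on the same margins.
#' @return A `data.frame` with `term`, `k`, `n`, `K`, `N`, `p`, `q`
#'   (BH-adjusted), sorted by `p`. Terms with `k = 0` are omitted.
#' @export
fisherEnrichment <- function(testSet, annotation, universe = NULL,
                             exclusive = FALSE) {
  if (length(testSet) == 0L) .stopf("fisherEnrichment: empty test set")
  testSet <- unique(testSet)
  if (is.null(universe)) universe <- unique(.annotationGenes(annotation))
  out <- setdiff(testSet, universe)
  if (length(out) > 0L)
    .stopf("fisherEnrichment: test gene(s) outside reference: %s",
           paste(head(out, 5L), collapse = ", "))
  tg <- .termGeneList(annotation)
  tg <- lapply(tg, function(g) intersect(unique(g), universe))
  N <- length(universe)
  n <- length(testSet)
  K <- lengths(tg)
  k <- vapply(tg, function(g) length(intersect(g, testSet)), integer(1))
  keep <- k >= 1L
  if (!any(keep))
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  K <- K[keep]; k <- k[keep]
  ## One-sided tail P(X >= k), X ~ Hypergeom(N, K, n). The test-vs-rest
  ## table [k, n-k; K-k, (N-n)-(K-k)] conditions on the same margins
  ## (n, N-n) x (K, N-K), so its exact one-sided p is identical; the
  ## `exclusive` switch therefore only changes the reported K and N.
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  Krep <- if (exclusive) K - k else K
  Nrep <- if (exclusive) N - n else N
  res <- data.frame(term = names(tg)[keep], k = k, n = n, K = Krep, N = Nrep,
                    p = pmin(p, 1), q = adjustFdr(pmin(p, 1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  res[order(res$p, res$term), , drop = FALSE]
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR adjustment; adjusted values are monotone non-decreasing in p.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values (same length/order as `p`).
#' @export
adjustFdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    .stopf("adjustFdr: p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Reduce significant terms to the most specific ones
#'
#' A significant term is most specific iff no other significant term is its
#' descendant under the transitive closure of the child -> parent edges.
#' Terms absent from the edge universe are treated as orphans (retained).
#'
#' @param significant Character vector of significant term ids.
#' @param edges Edge table (`child`, `parent`) as from
#'   [readOntologyEdges()].
#' @return A `data.frame` with `term` and logical `most_specific`.
#' @export
reduceToMostSpecific <- function(significant, edges) {
  significant <- unique(significant)
  if (length(significant) == 0L)
    return(data.frame(term = character(), most_specific = logical()))
  validateOntologyEdges(edges)
  if (nrow(edges) == 0L)
    return(data.frame(term = significant,
                      most_specific = rep(TRUE, length(significant)),
                      stringsAsFactors = FALSE))
  g <- graph_from_data_frame(edges[, c("child", "parent")], directed = TRUE)
  known <- intersect(significant, names(V(g)))
  ## ancestors of a term = all nodes reachable child -> parent
  ancestorsOf <- function(term) {
    setdiff(names(subcomponent(g, term, mode = "out")), term)
  }
  blocked <- unique(unlist(lapply(known, ancestorsOf)))
  data.frame(term = significant,
             most_specific = !(significant %in% blocked),
             stringsAsFactors = FALSE)
}

#' Export KEGG-style pathway colour files
#'
#' For each pathway, writes (or returns) two-column lines
#' `entry_label<TAB>hex` mapping each member gene's entry label to its
#' trend-class colour. Genes absent from the membership table are omitted.
#'
#' @param records Classification from [classifyTrends()] (needs `gene_id`
#'   and `hex`, or `class` from which colours are derived).
#' @param membership Pathway membership (`gene_id`, `pathway_id`,
#'   `entry_label`).
#' @param outDir Optional directory; if given, one `<pathway_id>.tsv` file
#'   per pathway is written.
#' @return Invisibly, a named list of per-pathway `data.frame`s
#'   (`entry_label`, `hex`).
#' @export
keggColorExport <- function(records, membership, outDir = NULL) {
  .checkColumns(records, "gene_id", "trend records")
  if (!"hex" %in% names(records)) {
    .checkColumns(records, "class", "trend records")
    records$hex <- assignColor(as.character(records$class))$hex
  }
  .checkColumns(membership, c("gene_id", "pathway_id", "entry_label"),
                "pathway membership")
  m <- merge(membership, records[, c("gene_id", "hex")], by = "gene_id")
  files <- split(m[, c("entry_label", "hex")], m$pathway_id)
  files <- lapply(files, function(df) {
    rownames(df) <- NULL
    df[order(df$entry_label), , drop = FALSE]
  })
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (pw in names(files)) {
      write.table(files[[pw]], file.path(outDir, paste0(pw, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
  }
  invisible(files)
}
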