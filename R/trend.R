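## Seven-class postprandial expression-trend classifier and its colour codes.
##
## A gene's FPKM triple (fasting, 24 h, 48 h) is classified by three gates:
##  (i)  expressed at all?        max FPKM over expr_min (default 10)
##  (ii) differentially expressed? any pairwise fold change over fc_min (4)
##  (iii) among non-DEGs, highly expressed? max FPKM over high_min (200)
## DEGs get a directional trend (up / down / up-then-down / down-then-up).
## All "over" comparisons are strict, matching the classification table's
## wording; the strict heat-map DEG selector uses >= instead.

TREND_CLASSES <- c("UP", "UP_THEN_DOWN", "DOWN", "DOWN_THEN_UP",
                   "HIGHLY_EXPRESSED", "MODERATELY_EXPRESSED",
                   "LOWLY_EXPRESSED")

.TREND_COLORS <- data.frame(
  class = TREND_CLASSES,
  color_name = c("Red", "Yellow", "Blue", "Brown",
                 "Purple", "Pink", "Dark grey"),
  hex = c("#FF0000", "#FFFF00", "#0000FF", "#A52A2A",
          "#800080", "#FFC0CB", "#A9A9A9"),
  stringsAsFactors = FALSE)

#' Colour codes of the seven expression-trend classes
#'
#' Upregulated genes are red, downregulated blue, up-then-down yellow,
#' down-then-up brown; among non-DEGs, highly expressed purple, moderately
#' expressed pink, lowly expressed dark grey.
#'
#' @return A `data.frame` with `class`, `color_name` and `hex`.
#' @export
trendColors <- function() .TREND_COLORS

#' Colour assigned to a trend class
#'
#' @param trend Character vector of trend class names.
#' @return A `data.frame` with `class`, `color_name`, `hex` (one row per
#'   input element).
#' @export
assignColor <- function(trend) {
  i <- match(trend, .TREND_COLORS$class)
  if (anyNA(i)) .stopf("assignColor: unknown trend class: %s",
                       paste(unique(trend[is.na(i)]), collapse = ", "))
  .TREND_COLORS[i, , drop = FALSE]
}

#' Pseudocounted fold change between two FPKM values
#'
#' `magnitude = (max(a, b) + eps) / (min(a, b) + eps)` (always >= 1) with
#' `direction = sign(b - a)`. The pseudocount makes the ratio defined at
#' zero and is small against the expressed-gene gate, so it cannot create
#' spurious DEGs among expressed genes.
#'
#' @param a,b Non-negative FPKM vectors (recycled).
#' @param eps Fold-change pseudocount in FPKM units; default 0.1.
#' @return A list with numeric `magnitude` and integer `direction`.
#' @export
foldChange <- function(a, b, eps = 0.1) {
  if (any(a < 0) || any(b < 0)) .stopf("foldChange: FPKM must be >= 0")
  if (eps <= 0) .stopf("foldChange: eps must be positive")
  list(magnitude = (pmax(a, b) + eps) / (pmin(a, b) + eps),
       direction = as.integer(sign(b - a)))
}

## vectorised classifier core; f0/f1/f2 are FPKM vectors over genes
.classifyTriples <- function(f0, f1, f2, exprMin = 10, highMin = 200,
                             fcMin = 4, eps = 0.1) {
  fc01 <- foldChange(f0, f1, eps)
  fc02 <- foldChange(f0, f2, eps)
  fc12 <- foldChange(f1, f2, eps)
  mag <- cbind(fc01$magnitude, fc02$magnitude, fc12$magnitude)
  dir <- cbind(fc01$direction, fc02$direction, fc12$direction)
  mx <- pmax(f0, f1, f2)

  sig <- mag > fcMin
  isDeg <- rowSums(sig) > 0L

  cls <- rep(NA_character_, length(f0))
  cls[mx <= exprMin] <- "LOWLY_EXPRESSED"
  open <- is.na(cls)

  ## non-DEG branch
  nd <- open & !isDeg
  cls[nd & mx > highMin] <- "HIGHLY_EXPRESSED"
  cls[nd & mx <= highMin] <- "MODERATELY_EXPRESSED"

  ## DEG branch: both consecutive transitions significant and opposed
  dg <- open & isDeg
  bothCons <- sig[, 1L] & sig[, 3L]
  updown <- dg & bothCons & dir[, 1L] == 1L & dir[, 3L] == -1L
  downup <- dg & bothCons & dir[, 1L] == -1L & dir[, 3L] == 1L
  cls[updown] <- "UP_THEN_DOWN"
  cls[downup] <- "DOWN_THEN_UP"

  ## otherwise: direction of the largest-magnitude significant comparison;
  ## ties broken by comparison order (f0,f1) > (f0,f2) > (f1,f2)
  rest <- dg & is.na(cls)
  ambiguous <- rep(FALSE, length(f0))
  if (any(rest)) {
    magR <- mag[rest, , drop = FALSE]
    sigR <- sig[rest, , drop = FALSE]
    dirR <- dir[rest, , drop = FALSE]
    magS <- magR
    magS[!sigR] <- -Inf
    pick <- max.col(magS, ties.method = "first")
    d <- dirR[cbind(seq_len(nrow(dirR)), pick)]
    cls[rest] <- ifelse(d == 1L, "UP", "DOWN")
    ## flag genes whose significant comparisons disagree in direction but do
    ## not form the consecutive up-down / down-up patterns
    nUp <- rowSums(sigR & dirR == 1L)
    nDn <- rowSums(sigR & dirR == -1L)
    ambiguous[rest] <- nUp > 0L & nDn > 0L
  }

  data.frame(f0 = f0, f1 = f1, f2 = f2,
             fc01 = fc01$magnitude, fc02 = fc02$magnitude,
             fc12 = fc12$magnitude,
             dir01 = dir[, 1L], dir02 = dir[, 2L], dir12 = dir[, 3L],
             max_fpkm = mx,
             class = factor(cls, levels = TREND_CLASSES),
             ambiguous = ambiguous,
             stringsAsFactors = FALSE)
}

#' Classify a single gene's expression trend
#'
#' @param f0,f1,f2 FPKM at fasting, 24 h and 48 h.
#' @param exprMin Expressed-gene gate (max FPKM must exceed it); default 10.
#' @param highMin Highly-expressed gate for non-DEGs; default 200.
#' @param fcMin Fold-change gate for differential expression; default 4.
#' @param eps Fold-change pseudocount; default 0.1.
#' @return A one-row `data.frame` with the FPKM triple, the three pairwise
#'   fold changes with directions, `max_fpkm`, the `class`, and an
#'   `ambiguous` flag raised when significant comparisons disagree in
#'   direction without forming a consecutive up-down / down-up pattern.
#' @export
classifyGene <- function(f0, f1, f2, exprMin = 10, highMin = 200,
                         fcMin = 4, eps = 0.1) {
  .classifyTriples(f0, f1, f2, exprMin, highMin, fcMin, eps)
}

## extract the (fasting, 24h, 48h) sample ids of one tissue from a sheet
.tissueSamples <- function(colData, tissue) {
  tissue <- match.arg(tissue, TISSUES)
  sel <- colData[colData$tissue == tissue, , drop = FALSE]
  ids <- vapply(TIMEPOINTS, function(tp) {
    s <- rownames(sel)[sel$timepoint == tp]
    if (length(s) != 1L)
      .stopf("tissue '%s': expected exactly one '%s' sample, found %d",
             tissue, tp, length(s))
    s
  }, character(1))
  ids
}

#' Classify every gene of one tissue's time course
#'
#' @param se `SummarizedExperiment` with assay `fpkm` and design colData.
#' @param tissue One of `heart`, `liver`, `stomach`, `pancreas`, `intestine`.
#' @inheritParams classifyGene
#' @return A `data.frame` (one row per gene, `gene_id` first column) as in
#'   [classifyGene()], plus `color_name` and `hex`. The classification is a
#'   partition: every gene receives exactly one class.
#' @export
classifyTrends <- function(se, tissue, exprMin = 10, highMin = 200,
                           fcMin = 4, eps = 0.1) {
  ids <- .tissueSamples(colData(se), tissue)
  fpkm <- assay(se, "fpkm")
  out <- .classifyTriples(fpkm[, ids[1L]], fpkm[, ids[2L]], fpkm[, ids[3L]],
                          exprMin, highMin, fcMin, eps)
  col <- assignColor(as.character(out$class))
  cbind(data.frame(gene_id = rownames(fpkm), stringsAsFactors = FALSE),
        out, color_name = col$color_name, hex = col$hex)
}

#' Summarise trend classifications per tissue
#'
#' @param records A named list of [classifyTrends()] results (names are
#'   tissues), or a single such `data.frame`.
#' @return A `data.frame` with `tissue`, `class`, `count` and `percent`
#'   (percent of the tissue's gene total, one decimal). Counts over the
#'   seven classes sum to the gene total per tissue.
#' @export
summarizeTrends <- function(records) {
  if (is.data.frame(records)) records <- list(all = records)
  if (length(records) == 0L) .stopf("summarizeTrends: empty input")
  out <- lapply(names(records), function(tis) {
    df <- records[[tis]]
    if (nrow(df) == 0L) .stopf("summarizeTrends: empty classification")
    cnt <- table(factor(df$class, levels = TREND_CLASSES))
    data.frame(tissue = tis, class = TREND_CLASSES,
               count = as.integer(cnt),
               percent = round(100 * as.integer(cnt) / nrow(df), 1L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Strict DEG selection for heat maps
#'
#' A gene is selected when its FPKM is at least `fpkmMin` in one or more
#' time points and at least one pairwise fold change is at least `fcMin`
#' (both comparisons inclusive).
#'
#' @inheritParams classifyTrends
#' @param fpkmMin Minimum FPKM in at least one time point; default 400.
#' @param fcMin Minimum pairwise fold change; default 2.
#' @return Character vector of selected gene ids.
#' @export
selectStrictDegs <- function(se, tissue, fpkmMin = 400, fcMin = 2, eps = 0.1) {
  ids <- .tissueSamples(colData(se), tissue)
  fpkm <- assay(se, "fpkm")
  f0 <- fpkm[, ids[1L]]; f1 <- fpkm[, ids[2L]]; f2 <- fpkm[, ids[3L]]
  mag <- cbind(foldChange(f0, f1, eps)$magnitude,
               foldChange(f0, f2, eps)$magnitude,
               foldChange(f1, f2, eps)$magnitude)
  keep <- pmax(f0, f1, f2) >= fpkmMin & rowSums(mag >= fcMin) > 0L
  rownames(fpkm)[keep]
}
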