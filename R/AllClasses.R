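## S4 container for the subtractive secretome filter chain. Each stage
## records exactly which proteins it kept and which it removed (with a
## reason), so the whole chain is auditable:
##   retained(i) = retained(i - 1) \ removed(i).

#' FilterChainReport: audited subtractive filter chain
#'
#' Ordered record of a subtractive protein-filtering workflow. Stage `i`
#' starts from the proteins retained by stage `i - 1` (stage 1 from the
#' initial set), removes some with a per-protein reason, and retains the
#' rest. Validity enforces the audit identity
#' `|retained_i| + |removed_i| = |retained_{i-1}|` and exact set nesting.
#'
#' @slot initial Character vector of protein ids entering the chain.
#' @slot stageNames Character vector of stage names, in order.
#' @slot retained List (per stage) of retained protein-id vectors.
#' @slot removed List (per stage) of removed protein-id vectors.
#' @slot reasons List (per stage) of removal reasons, named by protein id.
#' @export
setClass("FilterChainReport",
         representation(initial = "character",
                        stageNames = "character",
                        retained = "list",
                        removed = "list",
                        reasons = "list"))

setValidity("FilterChainReport", function(object) {
  ns <- length(object@stageNames)
  if (length(object@retained) != ns || length(object@removed) != ns ||
      length(object@reasons) != ns)
    return("stage lists must have one element per stage name")
  prev <- object@initial
  for (i in seq_len(ns)) {
    ret <- object@retained[[i]]
    rem <- object@removed[[i]]
    if (length(ret) + length(rem) != length(prev))
      return(sprintf("stage '%s': |retained| + |removed| != |input|",
                     object@stageNames[i]))
    if (!setequal(union(ret, rem), prev) || length(intersect(ret, rem)) > 0L)
      return(sprintf("stage '%s': retained/removed do not partition input",
                     object@stageNames[i]))
    rs <- object@reasons[[i]]
    if (!setequal(names(rs), rem) || any(!nzchar(rs)))
      return(sprintf("stage '%s': every removed id needs a non-empty reason",
                     object@stageNames[i]))
    prev <- ret
  }
  TRUE
})

## internal constructor from a list of stage records
.filterChainReport <- function(initial, stages) {
  new("FilterChainReport",
      initial = initial,
      stageNames = vapply(stages, `[[`, character(1), "name"),
      retained = lapply(stages, `[[`, "retained"),
      removed = lapply(stages, `[[`, "removed"),
      reasons = lapply(stages, `[[`, "reasons"))
}

#' @describeIn FilterChainReport Stage names, in order.
#' @param x,object A `FilterChainReport`.
#' @export
setGeneric("stageNames", function(x) standardGeneric("stageNames"))

#' @rdname FilterChainReport
#' @export
setMethod("stageNames", "FilterChainReport", function(x) x@stageNames)

#' @describeIn FilterChainReport Retained counts per stage, preceded by the
#'   initial count (named vector).
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' @rdname FilterChainReport
#' @export
setMethod("stageCounts", "FilterChainReport", function(x) {
  c(input = length(x@initial),
    stats::setNames(lengths(x@retained), x@stageNames))
})

#' @describeIn FilterChainReport Ids retained after a stage (default: the
#'   final stage).
#' @param stage Stage name or index.
#' @export
setGeneric("retainedIds", function(x, stage) standardGeneric("retainedIds"))

#' @rdname FilterChainReport
#' @export
setMethod("retainedIds", "FilterChainReport", function(x, stage) {
  if (missing(stage)) stage <- length(x@stageNames)
  if (is.character(stage)) stage <- match(stage, x@stageNames)
  if (is.na(stage) || stage < 1L || stage > length(x@retained))
    .stopf("retainedIds: unknown stage")
  x@retained[[stage]]
})

#' @describeIn FilterChainReport Ids removed by a stage with their reasons
#'   (named character vector).
#' @export
setGeneric("removedIds", function(x, stage) standardGeneric("removedIds"))

#' @rdname FilterChainReport
#' @export
setMethod("removedIds", "FilterChainReport", function(x, stage) {
  if (is.character(stage)) stage <- match(stage, x@stageNames)
  if (is.na(stage) || stage < 1L || stage > length(x@removed))
    .stopf("removedIds: unknown stage")
  x@reasons[[stage]]
})

#' @rdname FilterChainReport
#' @export
setMethod("show", "FilterChainReport", function(object) {
  cnt <- stageCounts(object)
  cat("FilterChainReport:", paste(cnt, collapse = " -> "), "\n")
  cat("  stages:", paste(object@stageNames, collapse = ", "), "\n")
  invisible(object)
})

#' Serialise a FilterChainReport to a per-stage table
#'
#' @param report A `FilterChainReport`.
#' @return A `data.frame` with `stage`, `protein_id`, `status`
#'   (`retained`/`removed`) and `reason` (empty for retained ids).
#' @export
chainReportTable <- function(report) {
  rows <- lapply(seq_along(report@stageNames), function(i) {
    rbind(
      data.frame(stage = report@stageNames[i],
                 protein_id = report@retained[[i]],
                 status = "retained", reason = "",
                 stringsAsFactors = FALSE),
      data.frame(stage = report@stageNames[i],
                 protein_id = report@removed[[i]],
                 status = "removed",
                 reason = unname(report@reasons[[i]][report@removed[[i]]]),
                 stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
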