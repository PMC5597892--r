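## Readers for the pipeline's tabular inputs. All tables are TSV (see .readTsv).
## Readers validate rather than repair: bad rows raise errors, nothing is
## silently dropped.

#' Read and validate a sample sheet
#'
#' The design is a tissue-by-timepoint grid: five visceral organs sampled
#' fasting, 24 h and 48 h after feeding. Timepoint order is fixed by the
#' factor levels (`fasting < 24h < 48h`), never by file order.
#'
#' @param path TSV with columns `sample_id`, `tissue`, `timepoint`.
#' @return A `data.frame` with `tissue` and ordered `timepoint` factors.
#' @export
readSampleSheet <- function(path) {
  df <- .readTsv(path, required = c("sample_id", "tissue", "timepoint"))
  validateSampleSheet(df)
}

#' Validate an in-memory sample sheet
#'
#' @param df A data.frame with `sample_id`, `tissue`, `timepoint` columns.
#' @return The validated sheet with factor-typed design columns.
#' @export
validateSampleSheet <- function(df) {
  .checkColumns(df, c("sample_id", "tissue", "timepoint"), "sample sheet")
  if (nrow(df) == 0L) .stopf("sample sheet: no samples")
  if (anyDuplicated(df$sample_id))
    .stopf("sample sheet: duplicate sample_id(s): %s",
           paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  badT <- setdiff(unique(df$tissue), TISSUES)
  if (length(badT) > 0L)
    .stopf("sample sheet: unknown tissue(s): %s", paste(badT, collapse = ", "))
  badP <- setdiff(unique(df$timepoint), TIMEPOINTS)
  if (length(badP) > 0L)
    .stopf("sample sheet: unknown timepoint(s): %s", paste(badP, collapse = ", "))
  cell <- paste(df$tissue, df$timepoint)
  if (anyDuplicated(cell))
    .stopf("sample sheet: more than one sample in design cell(s): %s",
           paste(unique(cell[duplicated(cell)]), collapse = "; "))
  df$tissue <- factor(df$tissue, levels = TISSUES)
  df$timepoint <- factor(df$timepoint, levels = TIMEPOINTS, ordered = TRUE)
  df
}

## shared builder for transcript-level count containers
.makeCountSE <- function(df, sheet) {
  meta <- c("transcript_id", "gene_id", "length_nt")
  sampleCols <- setdiff(names(df), meta)
  if (anyDuplicated(df$transcript_id))
    .stopf("count table: duplicate transcript_id(s)")
  if (any(df$length_nt < 1L) || any(df$length_nt != round(df$length_nt)))
    .stopf("count table: length_nt must be a positive integer")
  extra <- setdiff(sampleCols, sheet$sample_id)
  if (length(extra) > 0L)
    .stopf("count table: sample column(s) absent from sample sheet: %s",
           paste(extra, collapse = ", "))
  absent <- setdiff(sheet$sample_id, sampleCols)
  if (length(absent) > 0L)
    .stopf("count table: sample(s) in sheet but not in table: %s",
           paste(absent, collapse = ", "))
  counts <- as.matrix(df[, sheet$sample_id, drop = FALSE])
  if (!is.numeric(counts)) .stopf("count table: non-numeric count values")
  if (any(counts < 0)) .stopf("count table: negative counts")
  rownames(counts) <- df$transcript_id
  SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(gene_id = df$gene_id,
                        length_nt = as.integer(df$length_nt),
                        row.names = df$transcript_id),
    colData = DataFrame(sheet, row.names = sheet$sample_id))
}

#' Read a transcript-level fragment-count table
#'
#' @param path TSV with `transcript_id`, `gene_id`, `length_nt` and one count
#'   column per sample in `sheet`.
#' @param sheet A validated sample sheet (see [readSampleSheet()]).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, rowData `gene_id`/`length_nt` and the sheet as colData.
#'   Sample columns are ordered as in the sheet.
#' @export
readCountTable <- function(path, sheet) {
  df <- .readTsv(path, required = c("transcript_id", "gene_id", "length_nt"))
  .makeCountSE(df, sheet)
}

#' Build a count container from in-memory data
#'
#' @param df Data frame in the layout accepted by [readCountTable()].
#' @param sheet Validated sample sheet.
#' @return A `SummarizedExperiment`, as for [readCountTable()].
#' @export
makeCountTable <- function(df, sheet) .makeCountSE(df, sheet)

#' Read a protein-identification table
#'
#' Emulates a search-engine export: one row per accepted protein with its
#' annotation, number of distinct (unique) peptide sequences, and optionally
#' an emPAI value. Missing `empai` columns are tolerated (recorded as `NA`).
#'
#' @param path TSV with at least `protein_id`, `annotation`,
#'   `unique_peptides`; optional `empai` and `source_db`.
#' @return A validated `data.frame`.
#' @export
readProteinTable <- function(path) {
  df <- .readTsv(path, required = c("protein_id", "annotation", "unique_peptides"))
  validateProteinTable(df)
}

#' Validate an in-memory protein-identification table
#'
#' @param df Data frame with the [readProteinTable()] columns.
#' @return The validated table, with `empai` present (possibly all `NA`).
#' @export
validateProteinTable <- function(df) {
  .checkColumns(df, c("protein_id", "annotation", "unique_peptides"),
                "protein table")
  if (anyDuplicated(df$protein_id))
    .stopf("protein table: duplicate protein_id(s): %s",
           paste(unique(df$protein_id[duplicated(df$protein_id)]), collapse = ", "))
  up <- df$unique_peptides
  if (!is.numeric(up) || any(is.na(up)) || any(up < 0) || any(up != round(up)))
    .stopf("protein table: unique_peptides must be non-negative integers")
  df$unique_peptides <- as.integer(up)
  if (!"empai" %in% names(df)) df$empai <- NA_real_
  if (any(!is.na(df$empai) & df$empai < 0))
    .stopf("protein table: empai must be non-negative")
  if ("source_db" %in% names(df)) {
    bad <- setdiff(unique(df$source_db), c("python", "mouse"))
    if (length(bad) > 0L)
      .stopf("protein table: unknown source_db value(s): %s",
             paste(bad, collapse = ", "))
  }
  df
}

#' Read gene-to-GO annotation
#'
#' @param path TSV with `gene_id`, `go_terms` (semicolon-separated term ids,
#'   empty for unannotated genes) and optional `description`.
#' @return A `data.frame`, one row per gene.
#' @export
readAnnotationTable <- function(path) {
  df <- .readTsv(path, required = c("gene_id", "go_terms"))
  if (anyDuplicated(df$gene_id)) .stopf("annotation table: duplicate gene_id(s)")
  if (!"description" %in% names(df)) df$description <- ""
  terms <- unlist(strsplit(df$go_terms[nzchar(df$go_terms)], ";", fixed = TRUE))
  bad <- terms[!grepl("^[A-Za-z]+[:_]?[A-Za-z0-9:_.-]+$", terms)]
  if (length(bad) > 0L)
    .stopf("annotation table: malformed term id(s): %s",
           paste(unique(bad), collapse = ", "))
  df
}

#' Read ontology parent-child edges
#'
#' Edges point child -> parent. The edge set must be acyclic (a DAG); cycles,
#' including self-edges, are rejected.
#'
#' @param path Two-column TSV `child`/`parent`.
#' @return A `data.frame` of validated edges.
#' @export
readOntologyEdges <- function(path) {
  df <- .readTsv(path, required = c("child", "parent"))
  validateOntologyEdges(df)
}

#' Validate an in-memory edge table
#' @param df Data frame with `child` and `parent` columns.
#' @return The validated edge table.
#' @export
validateOntologyEdges <- function(df) {
  .checkColumns(df, c("child", "parent"), "ontology edges")
  if (nrow(df) > 0L) {
    g <- graph_from_data_frame(df[, c("child", "parent")], directed = TRUE)
    if (!is_dag(g)) .stopf("ontology edges: cycle detected")
  }
  df
}

#' Read gene-to-pathway membership
#'
#' @param path TSV with `gene_id`, `pathway_id`, `entry_label`.
#' @return A validated `data.frame`.
#' @export
readPathwayMembership <- function(path) {
  df <- .readTsv(path, required = c("gene_id", "pathway_id", "entry_label"))
  key <- paste(df$gene_id, df$pathway_id)
  if (anyDuplicated(key))
    .stopf("pathway membership: duplicate (gene_id, pathway_id) pair(s)")
  df
}
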