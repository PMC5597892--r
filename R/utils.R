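## internal helpers shared across modules

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## fixed vocabularies; timepoint order is semantic (trend classes depend on it)
TISSUES <- c("heart", "liver", "stomach", "pancreas", "intestine")
TIMEPOINTS <- c("fasting", "24h", "48h")

.checkColumns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    .stopf("%s: missing required column(s): %s", what,
           paste(missing, collapse = ", "))
  }
  invisible(df)
}

## run code under a seed without disturbing the caller's RNG stream
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Read a tab-separated table
#'
#' Canonical tabular dialect for the package: UTF-8 TSV with a header row;
#' lines starting with `#` are comments and ignored.
#'
#' @param path Path to a TSV file.
#' @param required Character vector of column names that must be present.
#' @return A `data.frame` with `check.names = FALSE`.
#' @keywords internal
.readTsv <- function(path, required = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE, quote = "")
  if (!is.null(required)) .checkColumns(df, required, basename(path))
  df
}

#' Write a table as TSV
#'
#' Integer columns are serialised bit-exactly; real-valued columns are written
#' with a fixed six decimal places so files are stable across platforms.
#'
#' @param x A `data.frame`, `DataFrame` or matrix.
#' @param path Output path.
#' @param digits Decimal places used for real-valued columns.
#' @return Invisibly, `path`.
#' @export
writeTsv <- function(x, path, digits = 6L) {
  if (is.null(x)) .stopf("writeTsv: 'x' must be non-null")
  if (is.matrix(x)) {
    x <- data.frame(id = rownames(x), x, stringsAsFactors = FALSE,
                    check.names = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (j in seq_along(x)) {
    col <- x[[j]]
    if (is.double(col)) {
      x[[j]] <- ifelse(is.na(col), NA_character_,
                       sprintf(paste0("%.", digits, "f"), col))
    }
  }
  ok <- tryCatch({
    write.table(x, file = path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) .stopf("writeTsv: cannot write '%s'", path)
  invisible(path)
}
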