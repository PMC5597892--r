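## Subtractive gastric-juice secretome workflow: peptide-evidence filter,
## plasma subtraction (by id), prey-homolog subtraction (by base-name
## keyword), rule-based categorisation, and emPAI semi-quantitation.

SECRETOME_CATEGORIES <- c("MUCOSAL", "PROTEOLYTIC", "OTHER_HYDROLYTIC",
                          "OTHER", "NOT_SECRETED")

## a stage is a plain list consumed by .filterChainReport
.makeStage <- function(name, input, removedIdx, reasons) {
  ids <- input$protein_id
  removed <- ids[removedIdx]
  list(name = name,
       retained = ids[!removedIdx],
       removed = removed,
       reasons = stats::setNames(reasons, removed),
       table = input[!removedIdx, , drop = FALSE])
}

#' Minimum-unique-peptide evidence filter
#'
#' Protein hits are only accepted when identified from at least `minUnique`
#' distinct peptide sequences (search-engine semantics: modified forms of
#' one sequence count once).
#'
#' @param table Protein table (see [readProteinTable()]).
#' @param minUnique Minimum distinct peptides; default 2.
#' @return A stage list with `retained`, `removed`, `reasons` and the
#'   retained `table`.
#' @export
filterMinPeptides <- function(table, minUnique = 2L) {
  if (minUnique < 1L) .stopf("filterMinPeptides: minUnique must be >= 1")
  drop <- table$unique_peptides < minUnique
  .makeStage("min_peptides", table, drop,
             rep(sprintf("fewer than %d unique peptides", minUnique),
                 sum(drop)))
}

#' Exponentially modified protein abundance index (emPAI)
#'
#' `emPAI = 10^(n_observed / n_observable) - 1`, where `n_observed` is the
#' number of distinct peptides observed for the protein and `n_observable`
#' the number of observable peptides in silico (see
#' [countObservablePeptides()]).
#'
#' @param nObserved Non-negative integer(s), at most `nObservable`.
#' @param nObservable Positive integer(s).
#' @return emPAI value(s).
#' @export
computeEmpai <- function(nObserved, nObservable) {
  if (any(nObservable < 1L))
    .stopf("computeEmpai: nObservable must be >= 1")
  if (any(nObserved < 0L) || any(nObserved > nObservable))
    .stopf("computeEmpai: need 0 <= nObserved <= nObservable")
  10^(nObserved / nObservable) - 1
}

#' Subtract plasma proteins from a digestive-fluid table
#'
#' Proteins identified in plasma are assumed to be blood contamination when
#' seen in gastric juice and are removed by protein id.
#'
#' @param digestive Digestive-fluid protein table (peptide-filtered).
#' @param plasma Plasma protein table (peptide-filtered).
#' @return A stage list (see [filterMinPeptides()]).
#' @export
subtractPlasma <- function(digestive, plasma) {
  drop <- digestive$protein_id %in% plasma$protein_id
  .makeStage("plasma", digestive, drop, rep("plasma", sum(drop)))
}

## default token stop-list for base-name derivation
BASE_NAME_STOP_TOKENS <- c("alpha", "beta", "type", "chain", "isoform",
                           "precursor", "subunit")

#' Derive a base search term from a protein annotation
#'
#' Lowercases the annotation, cuts at the first comma, then truncates at the
#' first token that is a stop word (`alpha`, `beta`, `type`, `chain`,
#' `isoform`, `precursor`, `subunit`), a numeral (arabic or roman) or a
#' parenthesised qualifier. E.g. `"Collagen alpha-1(I) chain"` yields
#' `"collagen"`; `"Keratin, type II cytoskeletal 1"` yields `"keratin"`.
#'
#' @param annotation Character vector of annotations.
#' @param stopTokens Token stop-list; default `BASE_NAME_STOP_TOKENS`.
#' @return Character vector of base terms.
#' @export
baseTerm <- function(annotation, stopTokens = BASE_NAME_STOP_TOKENS) {
  stopRe <- paste0("^(", paste(stopTokens, collapse = "|"), ")([^a-z]|$)")
  vapply(annotation, function(a) {
    a <- tolower(trimws(a))
    a <- sub(",.*$", "", a)
    tokens <- strsplit(a, "[[:space:]]+")[[1]]
    keep <- character()
    for (tok in tokens) {
      if (grepl(stopRe, tok) || grepl("[()]", tok) ||
          grepl("^[0-9ivxlcdm]+[.)]?$", tok)) break
      keep <- c(keep, tok)
    }
    out <- paste(keep, collapse = " ")
    if (!nzchar(out))
      .stopf("baseTerm: empty base term for annotation '%s'", a)
    out
  }, character(1), USE.NAMES = FALSE)
}

#' Subtract prey-homolog identifications
#'
#' Each prey (e.g. mouse) annotation is reduced to a base term; digestive
#' proteins whose annotation contains any base term (case-insensitive
#' substring) are removed as likely prey-protein homologs. The removal
#' reason records the matching term.
#'
#' @param digestive Digestive-fluid protein table.
#' @param prey Prey-database protein table (its annotations seed the terms).
#' @param stopTokens Stop-token list passed to [baseTerm()].
#' @return A stage list (see [filterMinPeptides()]).
#' @export
subtractPreyHomologs <- function(digestive, prey,
                                 stopTokens = BASE_NAME_STOP_TOKENS) {
  terms <- unique(baseTerm(prey$annotation, stopTokens))
  ann <- tolower(digestive$annotation)
  hit <- rep(NA_character_, nrow(digestive))
  for (tm in terms) {
    m <- is.na(hit) & grepl(tm, ann, fixed = TRUE)
    hit[m] <- tm
  }
  drop <- !is.na(hit)
  .makeStage("prey_homolog", digestive, drop,
             sprintf("prey homolog: %s", hit[drop]))
}

#' Default secretome keyword map
#'
#' Reads the keyword configuration shipped with the package
#' (`extdata/secretome_keywords.yaml`): per category, the lowercase
#' substrings that assign a protein to it. The map is data, not code — the
#' original categorisation was a manual curation; edit the YAML to change
#' policy.
#'
#' @param path Optional path to an alternative YAML file.
#' @return Named list of keyword character vectors (`not_secreted`,
#'   `mucosal`, `proteolytic`, `other_hydrolytic`, `other`).
#' @export
defaultKeywordMap <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "secretome_keywords.yaml",
                        package = "serpentome", mustWork = TRUE)
  km <- read_yaml(path)
  need <- c("not_secreted", "mucosal", "proteolytic", "other_hydrolytic",
            "other")
  missing <- setdiff(need, names(km))
  if (length(missing) > 0L)
    .stopf("keyword map: missing categor%s: %s",
           if (length(missing) > 1L) "ies" else "y",
           paste(missing, collapse = ", "))
  lapply(km, function(x) tolower(unlist(x)))
}

#' Categorise retained proteins into secretome classes
#'
#' Keyword assignment with fixed priority: intracellular/membrane keywords
#' first (`NOT_SECRETED` overrides everything — e.g. the stomach-specific
#' intracellular protease calpain 9 must not land in `PROTEOLYTIC`), then
#' `MUCOSAL` > `PROTEOLYTIC` > `OTHER_HYDROLYTIC` > `OTHER`; proteins
#' matching nothing are `NOT_SECRETED`.
#'
#' @param retained Protein table after subtraction stages.
#' @param keywordMap Keyword list as from [defaultKeywordMap()].
#' @return A list with `proteins` (data.frame `protein_id`, `annotation`,
#'   `category`) and `counts` (named integer vector over the five classes).
#' @export
categorizeSecretome <- function(retained, keywordMap = defaultKeywordMap()) {
  ann <- tolower(retained$annotation)
  matchAny <- function(keys) {
    if (length(keys) == 0L) return(rep(FALSE, length(ann)))
    Reduce(`|`, lapply(keys, function(k) grepl(k, ann, fixed = TRUE)))
  }
  cat <- rep("NOT_SECRETED", length(ann))
  open <- !matchAny(keywordMap$not_secreted)
  prio <- c(MUCOSAL = "mucosal", PROTEOLYTIC = "proteolytic",
            OTHER_HYDROLYTIC = "other_hydrolytic", OTHER = "other")
  for (cls in names(prio)) {
    m <- open & cat == "NOT_SECRETED" & matchAny(keywordMap[[prio[[cls]]]])
    cat[m] <- cls
  }
  proteins <- data.frame(protein_id = retained$protein_id,
                         annotation = retained$annotation,
                         category = factor(cat, levels = SECRETOME_CATEGORIES),
                         stringsAsFactors = FALSE)
  list(proteins = proteins,
       counts = stats::setNames(as.integer(table(proteins$category)),
                                SECRETOME_CATEGORIES))
}

#' Linear model of protein abundance against transcript expression
#'
#' Ordinary least squares of emPAI on FPKM for matched protein/gene pairs;
#' reports the slope, intercept and coefficient of determination.
#'
#' @param empai Numeric emPAI values.
#' @param fpkm Matched FPKM values (same length, >= 3 pairs).
#' @param log10 Fit on `log10` of both variables (pairs with zeros are
#'   dropped); default `FALSE`.
#' @return A list with `slope`, `intercept`, `r_squared` and `n`.
#' @export
correlateExpressionProtein <- function(empai, fpkm, log10 = FALSE) {
  if (length(empai) != length(fpkm))
    .stopf("correlateExpressionProtein: length mismatch")
  keep <- !is.na(empai) & !is.na(fpkm)
  if (log10) keep <- keep & empai > 0 & fpkm > 0
  x <- fpkm[keep]; y <- empai[keep]
  if (log10) { x <- log10(x); y <- log10(y) }
  if (length(x) < 3L)
    .stopf("correlateExpressionProtein: need >= 3 matched pairs")
  if (sd(x) == 0)
    .stopf("correlateExpressionProtein: zero variance in FPKM")
  fit <- lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r_squared = 1 - ss_res / ss_tot,
       n = length(x))
}

#' Run the full subtractive secretome chain
#'
#' Applies, in order: the minimum-unique-peptide filter, plasma subtraction
#' by id, prey-homolog subtraction by base term, and keyword categorisation
#' (with a final stage removing `NOT_SECRETED` proteins). The plasma and
#' prey tables are themselves peptide-filtered first.
#'
#' @param digestive,plasma,prey Protein tables (see [readProteinTable()]).
#' @param minUnique Minimum unique peptides; default 2.
#' @param keywordMap Keyword map; default [defaultKeywordMap()].
#' @param stopTokens Base-name stop tokens.
#' @return A list with `report` (a [FilterChainReport-class]), `secretome`
#'   (categorised secreted proteins), `categories` (full categorisation of
#'   the post-subtraction set) and `counts` (per-category counts among
#'   secreted proteins).
#' @export
runSecretomeChain <- function(digestive, plasma, prey, minUnique = 2L,
                              keywordMap = defaultKeywordMap(),
                              stopTokens = BASE_NAME_STOP_TOKENS) {
  digestive <- validateProteinTable(digestive)
  plasma <- validateProteinTable(plasma)
  prey <- validateProteinTable(prey)
  plasmaKept <- filterMinPeptides(plasma, minUnique)$table
  preyKept <- filterMinPeptides(prey, minUnique)$table

  s1 <- filterMinPeptides(digestive, minUnique)
  s2 <- subtractPlasma(s1$table, plasmaKept)
  s3 <- subtractPreyHomologs(s2$table, preyKept, stopTokens)
  catg <- categorizeSecretome(s3$table, keywordMap)
  notSec <- catg$proteins$category == "NOT_SECRETED"
  s4 <- .makeStage("not_secreted", s3$table, notSec,
                   rep("intracellular/membrane keyword or uncategorised",
                       sum(notSec)))
  report <- .filterChainReport(digestive$protein_id, list(s1, s2, s3, s4))
  validObject(report)
  secretome <- catg$proteins[!notSec, , drop = FALSE]
  counts <- stats::setNames(as.integer(table(factor(
    secretome$category, levels = setdiff(SECRETOME_CATEGORIES, "NOT_SECRETED")))),
    setdiff(SECRETOME_CATEGORIES, "NOT_SECRETED"))
  list(report = report, secretome = secretome,
       categories = catg$proteins, counts = counts)
}
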