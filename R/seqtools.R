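## Sequence-level utilities: paired-read quality filtering, in-silico
## tryptic digestion, and the Tajima-Nei nucleotide distance.

## ---- read QC ---------------------------------------------------------------

## trim one read at the first sliding window (5'->3') whose mean Phred
## quality drops below qMin; returns the kept length
.trimLength <- function(qual, window, qMin) {
  n <- length(qual)
  if (n < window) return(n)
  cs <- cumsum(c(0, qual))
  means <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
  bad <- which(means < qMin)
  if (length(bad) == 0L) n else bad[1L] - 1L
}

#' Quality-filter and trim paired reads
#'
#' Pairs are dropped when either mate contains the adapter (exact substring)
#' or an ambiguous base (`N`). Surviving mates are scanned 5' to 3' with a
#' sliding window; at the first window whose mean Phred quality falls below
#' `qMin` the read is truncated from that window's start. Pairs with either
#' trimmed mate shorter than `minLen` are dropped. Filter order is fixed:
#' adapter, then N, then trim, then length.
#'
#' @param pairs A list with `id`, `seq1`, `qual1`, `seq2`, `qual2`:
#'   character vectors of read ids, bases and Phred+33 quality strings
#'   (per-mate strings of equal length).
#' @param adapter Adapter sequence, or `NULL` to skip adapter filtering.
#' @param window Sliding-window length; default 10.
#' @param qMin Mean-quality threshold; default 20.
#' @param minLen Minimum mate length after trimming; default 30.
#' @return A list with the retained (possibly trimmed) `pairs` and `stats`
#'   (`input`, `dropped_adapter`, `dropped_n`, `dropped_short`,
#'   `retained`).
#' @export
qualityFilterReads <- function(pairs, adapter = NULL, window = 10L,
                               qMin = 20L, minLen = 30L) {
  if (window < 1L) .stopf("qualityFilterReads: window must be >= 1")
  need <- c("id", "seq1", "qual1", "seq2", "qual2")
  .checkColumns(as.data.frame(pairs, stringsAsFactors = FALSE), need,
                "read pairs")
  n <- length(pairs$id)
  if (any(nchar(pairs$seq1) != nchar(pairs$qual1)) ||
      any(nchar(pairs$seq2) != nchar(pairs$qual2)))
    .stopf("qualityFilterReads: sequence/quality length mismatch")

  hasAdapter <- if (is.null(adapter)) rep(FALSE, n) else
    grepl(adapter, pairs$seq1, fixed = TRUE) |
    grepl(adapter, pairs$seq2, fixed = TRUE)
  hasN <- (grepl("N", pairs$seq1, fixed = TRUE) |
           grepl("N", pairs$seq2, fixed = TRUE)) & !hasAdapter

  keep <- !hasAdapter & !hasN
  idx <- which(keep)
  phred <- function(q) as.integer(charToRaw(q)) - 33L
  len1 <- integer(length(idx)); len2 <- integer(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    len1[j] <- .trimLength(phred(pairs$qual1[i]), window, qMin)
    len2[j] <- .trimLength(phred(pairs$qual2[i]), window, qMin)
  }
  ok <- len1 >= minLen & len2 >= minLen
  kept <- idx[ok]
  out <- list(id = pairs$id[kept],
              seq1 = substr(pairs$seq1[kept], 1L, len1[ok]),
              qual1 = substr(pairs$qual1[kept], 1L, len1[ok]),
              seq2 = substr(pairs$seq2[kept], 1L, len2[ok]),
              qual2 = substr(pairs$qual2[kept], 1L, len2[ok]))
  list(pairs = out,
       stats = list(input = n,
                    dropped_adapter = sum(hasAdapter),
                    dropped_n = sum(hasN),
                    dropped_short = sum(!ok),
                    retained = length(kept)))
}

#' Read a pair of FASTQ files (Phred+33)
#'
#' @param path1,path2 Mate-1 and mate-2 FASTQ paths.
#' @return A pairs list as accepted by [qualityFilterReads()].
#' @export
readPairedFastq <- function(path1, path2) {
  r1 <- readDNAStringSet(path1, format = "fastq", with.qualities = TRUE)
  r2 <- readDNAStringSet(path2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2))
    .stopf("readPairedFastq: mate files differ in read count")
  list(id = names(r1),
       seq1 = unname(as.character(r1)),
       qual1 = unname(as.character(S4Vectors::mcols(r1)$qualities)),
       seq2 = unname(as.character(r2)),
       qual2 = unname(as.character(S4Vectors::mcols(r2)$qualities)))
}

#' Write one mate of a pairs list to FASTQ (Phred+33)
#'
#' @param pairs A pairs list (see [qualityFilterReads()]).
#' @param path Output path.
#' @param mate 1 or 2.
#' @return Invisibly, `path`.
#' @export
writePairedFastq <- function(pairs, path, mate = 1L) {
  seqs <- if (mate == 1L) pairs$seq1 else pairs$seq2
  quals <- if (mate == 1L) pairs$qual1 else pairs$qual2
  x <- DNAStringSet(seqs)
  names(x) <- pairs$id
  writeXStringSet(x, path, format = "fastq",
                  qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

## ---- tryptic digestion -----------------------------------------------------

#' In-silico tryptic digestion
#'
#' Cleaves after lysine (K) or arginine (R) except when the next residue is
#' proline (P). With `missedCleavages = m`, all peptides spanning up to `m`
#' skipped cleavage sites are added to the fully cleaved set.
#'
#' @param protein Residue string (standard amino-acid alphabet) or
#'   `AAString`.
#' @param missedCleavages Non-negative integer; default 0.
#' @return Character vector of peptides (in N-to-C order of their start;
#'   the zero-missed peptides concatenate to the input).
#' @export
trypticDigest <- function(protein, missedCleavages = 0L) {
  protein <- toupper(as.character(protein))
  if (nchar(protein) == 0L) return(character())
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", protein))
    .stopf("trypticDigest: non-standard residue in sequence")
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut < n & res[pmin(cut + 1L, n)] != "P" | cut == n]
  bounds <- c(0L, cut[cut < n], n)
  bounds <- unique(bounds)
  frags <- substring(protein, head(bounds, -1L) + 1L, bounds[-1L])
  if (missedCleavages == 0L) return(frags)
  out <- character()
  for (span in 1L:(missedCleavages + 1L)) {
    if (span > length(frags)) break
    for (i in seq_len(length(frags) - span + 1L)) {
      out <- c(out, paste(frags[i:(i + span - 1L)], collapse = ""))
    }
  }
  out
}

#' Count observable tryptic peptides
#'
#' Number of distinct fully tryptic peptides (no missed cleavages) whose
#' length lies within the given bounds — the in-silico `n_observable` used
#' by [computeEmpai()].
#'
#' @param protein Residue string or `AAString`.
#' @param lenMin,lenMax Inclusive peptide-length bounds; defaults 6 and 35.
#' @return Integer count.
#' @export
countObservablePeptides <- function(protein, lenMin = 6L, lenMax = 35L) {
  peps <- unique(trypticDigest(protein, 0L))
  sum(nchar(peps) >= lenMin & nchar(peps) <= lenMax)
}

## ---- Tajima-Nei distance ---------------------------------------------------

#' Tajima-Nei pairwise nucleotide distance
#'
#' Distance correcting for unequal base composition and heterogeneous
#' substitution pattern: over the comparable sites (pairwise deletion of
#' positions with a gap or ambiguity in either sequence) with mismatch
#' proportion `p`, averaged base frequencies `g_i` and relative frequencies
#' `x_ij` of the unordered differing pairs,
#' `h = sum_{i<j} x_ij^2 / (2 g_i g_j)`,
#' `b = (1 - sum g_i^2 + p^2 / h) / 2`, and `d = -b log(1 - p / b)`.
#' Identical sequences give `d = 0` (the `h` indeterminacy is bypassed);
#' `p / b >= 1` means the correction saturates and is an error.
#'
#' @param s1,s2 Aligned nucleotide strings of equal length (gaps allowed),
#'   or a length-2 `DNAStringSet` as `s1`.
#' @return A list with `p`, `g` (named A/C/G/T), `x` (named unordered-pair
#'   frequencies), `h`, `b`, `d` and `n_sites` (comparable sites).
#' @export
tajimaNeiDistance <- function(s1, s2 = NULL) {
  if (is.null(s2)) {
    if (length(s1) != 2L) .stopf("tajimaNeiDistance: need exactly 2 sequences")
    s2 <- as.character(s1[[2L]]); s1 <- as.character(s1[[1L]])
  }
  a <- strsplit(toupper(as.character(s1)), "")[[1]]
  b_ <- strsplit(toupper(as.character(s2)), "")[[1]]
  if (length(a) != length(b_))
    .stopf("tajimaNeiDistance: sequences must be aligned to equal length")
  bases <- c("A", "C", "G", "T")
  comp <- a %in% bases & b_ %in% bases
  if (!any(comp)) .stopf("tajimaNeiDistance: no comparable sites")
  a <- a[comp]; b_ <- b_[comp]
  nSites <- length(a)
  p <- mean(a != b_)
  g <- (table(factor(a, bases)) + table(factor(b_, bases))) / (2 * nSites)
  g <- stats::setNames(as.numeric(g), bases)
  pairNames <- c("AC", "AG", "AT", "CG", "CT", "GT")
  x <- stats::setNames(numeric(6L), pairNames)
  diff <- which(a != b_)
  if (length(diff) > 0L) {
    key <- vapply(diff, function(i) paste(sort(c(a[i], b_[i])), collapse = ""),
                  character(1))
    tab <- table(factor(key, pairNames))
    x <- stats::setNames(as.numeric(tab) / nSites, pairNames)
  }
  if (p == 0) {
    return(list(p = 0, g = g, x = x, h = NA_real_, b = NA_real_, d = 0,
                n_sites = nSites))
  }
  gp <- list(AC = c("A", "C"), AG = c("A", "G"), AT = c("A", "T"),
             CG = c("C", "G"), CT = c("C", "T"), GT = c("G", "T"))
  h <- sum(vapply(pairNames, function(k) {
    gi <- g[gp[[k]][1L]]; gj <- g[gp[[k]][2L]]
    if (x[k] == 0) 0 else x[k]^2 / (2 * gi * gj)
  }, numeric(1)))
  bcoef <- (1 - sum(g^2) + p^2 / h) / 2
  if (p / bcoef >= 1)
    .stopf("tajimaNeiDistance: saturation (p/b >= 1), distance undefined")
  list(p = p, g = g, x = x, h = h, b = bcoef,
       d = -bcoef * log(1 - p / bcoef), n_sites = nSites)
}

#' Mean pairwise Tajima-Nei distance of an aligned set
#'
#' @param seqs A `DNAStringSet` or character vector of aligned sequences
#'   (equal lengths), length >= 2.
#' @return A list with `mean` (arithmetic mean of `d` over all unordered
#'   pairs) and the `pairs` table (`i`, `j`, `d`).
#' @export
meanPairwiseDistance <- function(seqs) {
  seqs <- as.character(seqs)
  n <- length(seqs)
  if (n < 2L) .stopf("meanPairwiseDistance: need >= 2 sequences")
  nm <- names(seqs)
  if (is.null(nm)) nm <- as.character(seq_len(n))
  rows <- list()
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d <- tryCatch(tajimaNeiDistance(seqs[i], seqs[j])$d, error = function(e) {
      .stopf("meanPairwiseDistance: pair (%s, %s) undefined: %s",
             nm[i], nm[j], conditionMessage(e))
    })
    rows[[length(rows) + 1L]] <- data.frame(i = nm[i], j = nm[j], d = d,
                                            stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  list(mean = mean(pairs$d), pairs = pairs)
}

#' Codon-aware nucleotide alignment from a protein alignment
#'
#' Back-translates a protein alignment onto its coding sequences: each
#' aligned residue column becomes the corresponding codon triplet, gaps
#' become `---`. Lets a nucleotide distance model be applied to sequences
#' aligned at the amino-acid level.
#'
#' @param proteinAln Character vector (or `AAStringSet`) of aligned protein
#'   sequences (equal lengths, `-` for gaps).
#' @param cds Character vector (or `DNAStringSet`) of the ungapped coding
#'   sequences, in the same order; each must have `3 x` the ungapped
#'   residue count nucleotides (a trailing stop codon is tolerated).
#' @return A `DNAStringSet` of gapped, codon-aligned nucleotide sequences.
#' @export
codonAlign <- function(proteinAln, cds) {
  alnNames <- names(proteinAln)
  proteinAln <- as.character(proteinAln)
  cds <- as.character(cds)
  if (length(proteinAln) != length(cds))
    .stopf("codonAlign: protein alignment and CDS sets differ in length")
  out <- vapply(seq_along(proteinAln), function(i) {
    res <- strsplit(proteinAln[i], "")[[1]]
    nRes <- sum(res != "-")
    nt <- toupper(cds[i])
    if (!nchar(nt) %in% (3L * nRes + c(0L, 3L)))
      .stopf("codonAlign: CDS %d has %d nt for %d residues", i, nchar(nt), nRes)
    codons <- substring(nt, seq(1L, 3L * nRes, by = 3L),
                        seq(3L, 3L * nRes, by = 3L))
    filled <- rep("---", length(res))
    filled[res != "-"] <- codons
    paste(filled, collapse = "")
  }, character(1))
  names(out) <- alnNames
  DNAStringSet(out)
}
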