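onePair <- function(seq1, qual1, seq2 = seq1, qual2 = qual1, id = "r1") {
  list(id = id, seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2)
}

qstr <- function(phreds) rawToChar(as.raw(phreds + 33L))

test_that("read filtering applies adapter, N, trim and length rules in order", {
  good <- onePair(strrep("ACGT", 25), qstr(rep(40L, 100)))
  res <- qualityFilterReads(good, adapter = "GGGGGGGG", minLen = 30)
  expect_equal(res$stats$retained, 1L)
  expect_equal(res$pairs$seq1, good$seq1)  # all-high-quality passes unchanged

  # the first sub-threshold window starts at position 51 (earlier windows
  # straddling the boundary still average >= 20), so 50 bases are kept
  qual <- c(rep(40L, 50), rep(19L, 50))
  trimmed <- qualityFilterReads(onePair(strrep("ACGT", 25), qstr(qual)),
                                minLen = 30)
  expect_equal(nchar(trimmed$pairs$seq1), 50L)
  expect_equal(nchar(trimmed$pairs$qual1), 50L)

  # any N drops the pair
  withN <- onePair(paste0(strrep("ACGT", 12), "N", strrep("A", 51)),
                   qstr(rep(40L, 100)))
  res <- qualityFilterReads(withN)
  expect_equal(res$stats$dropped_n, 1L)
  expect_equal(res$stats$retained, 0L)

  # adapter-containing pairs are dropped before the N rule applies
  withAd <- onePair(paste0("TTTT", "GGGGGGGG", strrep("N", 88)),
                    qstr(rep(40L, 100)))
  res <- qualityFilterReads(withAd, adapter = "GGGGGGGG")
  expect_equal(res$stats$dropped_adapter, 1L)
  expect_equal(res$stats$dropped_n, 0L)

  # over-trimmed mates drop the whole pair
  lowQ <- onePair(strrep("ACGT", 25), qstr(rep(5L, 100)))
  res <- qualityFilterReads(lowQ, minLen = 30)
  expect_equal(res$stats$dropped_short, 1L)
})

test_that("trimming never lengthens a read and accounting is exact", {
  set.seed(101)
  pairs <- randomReadPairs(500)
  res <- qualityFilterReads(pairs, adapter = "ACGTACGTGG", minLen = 20)
  st <- res$stats
  expect_equal(st$dropped_adapter + st$dropped_n + st$dropped_short +
                 st$retained, st$input)
  keptIdx <- match(res$pairs$id, pairs$id)
  expect_true(all(nchar(res$pairs$seq1) <= nchar(pairs$seq1[keptIdx])))
  expect_true(all(nchar(res$pairs$seq2) <= nchar(pairs$seq2[keptIdx])))
  expect_true(all(nchar(res$pairs$seq1) == nchar(res$pairs$qual1)))
})

test_that("FASTQ pairs survive a write/read round trip", {
  set.seed(7)
  pairs <- randomReadPairs(20, nProb = 0)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  writePairedFastq(pairs, f1, mate = 1L)
  writePairedFastq(pairs, f2, mate = 2L)
  back <- readPairedFastq(f1, f2)
  expect_equal(back$seq1, pairs$seq1)
  expect_equal(back$qual1, pairs$qual1)
  expect_equal(back$seq2, pairs$seq2)
  expect_equal(back$id, pairs$id)
})

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_equal(trypticDigest("MKRAPKGFR"), c("MK", "R", "APK", "GFR"))
  expect_equal(trypticDigest("MAGICSEQENCE"), "MAGICSEQENCE")
  expect_setequal(trypticDigest("MKRA", 1L),
                  c("MK", "R", "A", "MKR", "RA"))
  expect_equal(trypticDigest(""), character())
  expect_error(trypticDigest("MKZ"), "non-standard")

  set.seed(41)
  for (rep in 1:25) {
    prot <- randomProtein(sample(10:200, 1))
    peps <- trypticDigest(prot)
    expect_equal(paste(peps, collapse = ""), prot)
    # every internal boundary is a K/R not followed by P
    ends <- cumsum(nchar(peps))
    for (e in head(ends, -1)) {
      expect_true(substr(prot, e, e) %in% c("K", "R"))
      expect_false(substr(prot, e + 1, e + 1) == "P")
    }
  }
})

test_that("observable-peptide counting applies length bounds and distinctness", {
  expect_equal(countObservablePeptides("MKRAPKGFR"), 0L)
  polyA <- strrep("A", 40)
  expect_equal(countObservablePeptides(polyA), 0L)  # 40 > default max 35
  expect_equal(countObservablePeptides(polyA, lenMax = 50), 1L)
  # two copies of the same peptide count once
  dup <- "AAAAAAKAAAAAAK"
  expect_equal(countObservablePeptides(dup), 1L)
})

test_that("Tajima-Nei reduces to Jukes-Cantor in the symmetric case", {
  s <- symmetricDivergedPair(nSame = 540L, nDiff = 60L)
  tn <- tajimaNeiDistance(s$s1, s$s2)
  expect_equal(tn$p, 0.1, tolerance = 1e-12)
  expect_equal(unname(tn$g), rep(0.25, 4), tolerance = 1e-12)
  expect_equal(tn$b, 0.75, tolerance = 1e-9)
  expect_equal(tn$d, -0.75 * log(1 - 4 / 3 * 0.1), tolerance = 1e-9)

  # identical sequences have distance zero
  expect_equal(tajimaNeiDistance(s$s1, s$s1)$d, 0)

  # distance grows with divergence at fixed composition
  d1 <- tajimaNeiDistance(symmetricDivergedPair(588L, 12L)$s1,
                          symmetricDivergedPair(588L, 12L)$s2)$d
  d2 <- tajimaNeiDistance(symmetricDivergedPair(540L, 60L)$s1,
                          symmetricDivergedPair(540L, 60L)$s2)$d
  d3 <- tajimaNeiDistance(symmetricDivergedPair(480L, 120L)$s1,
                          symmetricDivergedPair(480L, 120L)$s2)$d
  expect_true(d1 < d2 && d2 < d3)

  # saturation: p/b >= 1 is an error
  sat <- symmetricDivergedPair(nSame = 24L, nDiff = 576L)
  expect_error(tajimaNeiDistance(sat$s1, sat$s2), "saturation")
})

test_that("gapped and ambiguous sites are pairwise-deleted", {
  tn <- tajimaNeiDistance("ACGT-NACGT", "ACGTTTACGA")
  expect_equal(tn$n_sites, 8L)  # gap and N columns excluded
  expect_equal(tn$p, 1 / 8, tolerance = 1e-12)
  expect_error(tajimaNeiDistance("----", "ACGT"), "no comparable")
  expect_error(tajimaNeiDistance("ACG", "ACGT"), "equal length")
})

test_that("mean pairwise distance averages the oracle pair distances", {
  sim <- simulateAlignedSequences(n = 4, length = 600, rate = 0.1, seed = 5)
  mp <- meanPairwiseDistance(sim$seqs)
  ds <- combn(4, 2, function(ij)
    tajimaNeiDistance(sim$seqs[[ij[1]]], sim$seqs[[ij[2]]])$d)
  expect_equal(mp$mean, mean(ds), tolerance = 1e-12)
  expect_equal(nrow(mp$pairs), 6L)

  # permutation invariance
  mp2 <- meanPairwiseDistance(sim$seqs[c(3, 1, 4, 2)])
  expect_equal(mp2$mean, mp$mean, tolerance = 1e-12)

  # identical sequences give zero
  expect_equal(meanPairwiseDistance(c("ACGTACGT", "ACGTACGT"))$mean, 0)
})

test_that("codon-aware back-translation maps residues to codons", {
  aln <- c(a = "MK-R", b = "MKQR")
  cds <- c(a = "ATGAAACGT", b = "ATGAAACAACGT")
  nt <- codonAlign(aln, cds)
  expect_equal(as.character(nt[["a"]]), "ATGAAA---CGT")
  expect_equal(as.character(nt[["b"]]), "ATGAAACAACGT")
  expect_error(codonAlign(c("MK"), c("ATGAA")), "nt for")
})
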