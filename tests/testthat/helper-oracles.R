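# Independent brute-force oracles used to check the package's fast paths.
# These deliberately avoid the implementation's code paths (no phyper,
# p.adjust, hclust or cor).

# hypergeometric upper tail P(X >= k) by explicit log-binomial sums
bruteHyperTail <- function(k, K, N, n) {
  iMax <- min(n, K)
  if (k > iMax) return(0)
  i <- k:iMax
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Benjamini-Hochberg step-up adjusted values, written out longhand
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  running <- Inf
  for (r in n:1) {
    running <- min(running, p[o[r]] * n / r)
    q[o[r]] <- min(running, 1)
  }
  q
}

# naive UPGMA: repeatedly merge the closest pair of clusters, inter-cluster
# distance = unweighted mean over all cross pairs; returns merge heights
bruteUpgmaHeights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL
    bestd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a < b) {
        d <- mean(D[clusters[[a]], clusters[[b]]])
        if (d < bestd) { bestd <- d; best <- c(a, b) }
      }
    }
    heights <- c(heights, bestd)
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  heights
}

# Spearman distance by explicit rank-then-Pearson arithmetic
bruteSpearmanDist <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  1 - num / den
}

# random paired reads for QC property tests
randomReadPairs <- function(n, lenRange = c(50L, 101L), nProb = 0.02,
                            qualRange = c(2L, 40L)) {
  bases <- c("A", "C", "G", "T")
  mk <- function() {
    len <- sample(lenRange[1L]:lenRange[2L], n, replace = TRUE)
    seq <- vapply(len, function(l) {
      s <- sample(bases, l, replace = TRUE)
      if (stats::runif(1) < nProb) s[sample.int(l, 1L)] <- "N"
      paste(s, collapse = "")
    }, character(1))
    qual <- vapply(len, function(l) {
      rawToChar(as.raw(sample(qualRange[1L]:qualRange[2L], l,
                              replace = TRUE) + 33L))
    }, character(1))
    list(seq = seq, qual = qual)
  }
  m1 <- mk(); m2 <- mk()
  list(id = sprintf("r%05d", seq_len(n)),
       seq1 = m1$seq, qual1 = m1$qual,
       seq2 = m2$seq, qual2 = m2$qual)
}

# random protein sequence from the 20-letter alphabet
randomProtein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# aligned pair with p differing sites spread evenly over the six unordered
# nucleotide pairs and balanced composition (the symmetric, Jukes-Cantor
# limit of the Tajima-Nei model); nDiff must be divisible by 12
symmetricDivergedPair <- function(nSame = 540L, nDiff = 60L) {
  stopifnot(nSame %% 4L == 0L, nDiff %% 12L == 0L)
  bases <- c("A", "C", "G", "T")
  s1 <- rep(bases, each = nSame / 4L)
  s2 <- s1
  pairs <- list(c("A", "C"), c("A", "G"), c("A", "T"),
                c("C", "G"), c("C", "T"), c("G", "T"))
  per <- nDiff / 12L
  for (pr in pairs) {
    s1 <- c(s1, rep(pr[1L], per), rep(pr[2L], per))
    s2 <- c(s2, rep(pr[2L], per), rep(pr[1L], per))
  }
  list(s1 = paste(s1, collapse = ""), s2 = paste(s2, collapse = ""))
}
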