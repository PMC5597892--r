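## Seeded generators producing every pipeline input with planted ground
## truth. All generators are pure functions of (spec, seed): the caller's
## RNG stream is saved and restored.

## planted FPKM base triples per trend class. Levels keep a >= 1.5x margin
## to every decision threshold (expressed > 10, DEG fold change > 4, highly
## expressed > 200), so bounded multiplicative noise cannot flip a class.
.TREND_PLANT_LEVELS <- list(
  UP                   = c(20, 22, 300),
  UP_THEN_DOWN         = c(20, 400, 25),
  DOWN                 = c(300, 280, 20),
  DOWN_THEN_UP         = c(400, 25, 380),
  HIGHLY_EXPRESSED     = c(500, 480, 520),
  MODERATELY_EXPRESSED = c(60, 70, 80),
  LOWLY_EXPRESSED      = c(3, 4, 5))

#' Simulate a transcript count table with planted expression trends
#'
#' Plants `genesPerClass` genes of each of the seven trend classes in every
#' tissue. Per-gene FPKM triples start from class-specific base levels with
#' comfortable margins to all thresholds, receive multiplicative log-normal
#' noise (clamped at 2.5 sd so margins hold), and are inverted through the
#' FPKM formula at a fixed library size to integer transcript counts split
#' over 1-3 transcripts per gene. Rounding-induced FPKM error is bounded
#' below 1 percent and asserted.
#'
#' @param genesPerClass Genes planted per class (default 200).
#' @param tissues Tissues to simulate (default all five).
#' @param noiseSd Log-normal noise sd on the natural-log scale; default
#'   0.05. Set 0 for noise-free plants.
#' @param librarySize Per-sample total fragments (default 1e7).
#' @param seed Integer seed (generators are pure functions of it).
#' @return A list with `counts` (transcript-level `SummarizedExperiment`),
#'   `sheet` (sample sheet), `totals` (named library sizes for
#'   [computeFpkm()]), `truth` (`gene_id`, `tissue`, `class`) and
#'   `plantedFpkm` (the noisy planted gene-level FPKM matrix).
#' @export
simulateTrendCounts <- function(genesPerClass = 200L, tissues = TISSUES,
                                noiseSd = 0.05, librarySize = 1e7,
                                seed = 1L) {
  if (genesPerClass < 1L) .stopf("simulateTrendCounts: genesPerClass >= 1")
  if (noiseSd < 0) .stopf("simulateTrendCounts: noiseSd must be >= 0")
  tissues <- match.arg(tissues, TISSUES, several.ok = TRUE)
  .withSeed(seed, {
    classes <- rep(names(.TREND_PLANT_LEVELS), each = genesPerClass)
    nGenes <- length(classes)
    gids <- sprintf("g%05d", seq_len(nGenes))

    sheet <- data.frame(
      sample_id = as.vector(outer(substr(tissues, 1L, 2L), c("0", "1", "2"),
                                  function(a, b) paste0(a, b))),
      tissue = rep(tissues, times = 3L),
      timepoint = rep(TIMEPOINTS, each = length(tissues)),
      stringsAsFactors = FALSE)
    sheet <- validateSampleSheet(sheet)

    ## gene structure: 1-3 transcripts, lengths 2000-4000 nt; the longest
    ## transcript is the representative (keeps minimum counts ~50 at the
    ## lowest planted FPKM so rounding error stays below 1%)
    nTx <- sample(1:3, nGenes, replace = TRUE)
    geneLen <- sample(2000:4000, nGenes, replace = TRUE)

    noise <- function(k) {
      if (noiseSd == 0) return(rep(1, k))
      z <- pmin(pmax(rnorm(k, 0, noiseSd), -2.5 * noiseSd), 2.5 * noiseSd)
      exp(z)
    }

    fpkm <- matrix(0, nGenes, nrow(sheet),
                   dimnames = list(gids, sheet$sample_id))
    truth <- list()
    for (tis in tissues) {
      ids <- sheet$sample_id[sheet$tissue == tis][order(sheet$timepoint[sheet$tissue == tis])]
      base <- do.call(rbind, .TREND_PLANT_LEVELS[classes])
      vals <- base * matrix(noise(3L * nGenes), nGenes, 3L)
      fpkm[, ids] <- vals
      truth[[tis]] <- data.frame(gene_id = gids, tissue = tis,
                                 class = classes, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL

    ## verify the plant: the noisy triples must classify as planted
    for (tis in tissues) {
      ids <- sheet$sample_id[sheet$tissue == tis][order(sheet$timepoint[sheet$tissue == tis])]
      got <- .classifyTriples(fpkm[, ids[1L]], fpkm[, ids[2L]], fpkm[, ids[3L]])
      if (!all(as.character(got$class) == classes))
        .stopf("simulateTrendCounts: infeasible spec, noise flips a planted class")
    }

    ## invert FPKM to gene counts, then split over member transcripts
    totals <- stats::setNames(rep(librarySize, nrow(sheet)), sheet$sample_id)
    geneCounts <- round(sweep(fpkm * geneLen / 1e9, 2L, totals, "*"))
    recFpkm <- sweep(geneCounts * 1e9 / geneLen, 2L, totals, "/")
    relErr <- abs(recFpkm - fpkm) / fpkm
    if (any(relErr >= 0.01))
      .stopf("simulateTrendCounts: rounding error exceeds 1%%")

    txRows <- list()
    for (g in seq_len(nGenes)) {
      k <- nTx[g]
      lens <- if (k == 1L) geneLen[g] else
        c(geneLen[g], sample(1000:geneLen[g], k - 1L, replace = TRUE))
      share <- matrix(0, k, nrow(sheet))
      gc <- geneCounts[g, ]
      if (k == 1L) {
        share[1L, ] <- gc
      } else {
        w <- runif(k); w <- w / sum(w)
        for (s in seq_len(nrow(sheet))) {
          parts <- floor(gc[s] * w)
          parts[1L] <- parts[1L] + gc[s] - sum(parts)
          share[, s] <- parts
        }
      }
      txRows[[g]] <- data.frame(
        transcript_id = sprintf("%s.t%d", gids[g], seq_len(k)),
        gene_id = gids[g], length_nt = as.integer(lens),
        share, stringsAsFactors = FALSE, check.names = FALSE)
    }
    txDf <- do.call(rbind, txRows)
    names(txDf)[-(1:3)] <- sheet$sample_id

    list(counts = makeCountTable(txDf, sheet), sheet = sheet,
         totals = totals, truth = truth, plantedFpkm = fpkm)
  })
}

## annotation vocabularies for the proteome generator. Pools are disjoint
## (no word of one pool is a substring of another pool's annotations) so
## planted strata map exactly onto filter stages.
.PROT_POOLS <- list(
  plasma = c("serum albumin", "apolipoprotein A-I", "serotransferrin",
             "haptoglobin", "fibrinogen gamma", "alpha-2-macroglobulin",
             "complement C3", "hemopexin", "transthyretin",
             "anti-haemorrhagic factor cHLP-B"),
  prey = c("Collagen alpha-1(I) chain", "Keratin, type II cytoskeletal 1",
           "Titin", "Desmin", "Vimentin", "Fibronectin", "Elastin",
           "Laminin subunit beta-1", "Myoglobin", "Troponin C"),
  intracellular = c("beta-actin", "alpha-tubulin", "histone H4",
                    "60S ribosomal protein L7", "calpain-9",
                    "proteasome subunit alpha", "elongation factor 1-alpha",
                    "alpha-enolase", "fructose-bisphosphate aldolase",
                    "heat shock protein 90"),
  mucosal = c("mucin-6-like", "mucin-5AC", "gastrokine-1", "gastrokine-2",
              "trefoil factor 2"),
  proteolytic = c("gastricsin-like precursor", "progastricsin",
                  "embryonic pepsinogen-like", "pepsinogen A-like",
                  "prochymosin"),
  other_hydrolytic = c("phospholipase A2", "gastric triacylglycerol lipase",
                       "lysozyme C", "pancreatic alpha-amylase"),
  other = c("gastric intrinsic factor", "carbonic anhydrase 2",
            "cystatin-B-like secreted", "transcobalamin-1",
            "secretoglobin family 1A", "galactose-specific lectin"))

#' Simulate digestive, plasma and prey protein tables with planted strata
#'
#' The digestive-fluid table is the disjoint union of planted strata:
#' single-peptide artefacts, plasma contaminants (ids shared with the
#' plasma table), prey-protein homologs (annotations sharing a base term
#' with the prey table), intracellular distractors, and secreted proteins
#' per category. Defaults mirror a realistic subtractive chain:
#' 549 identifications reducing to 314, then 114, then a 37-protein
#' secretome split 18/7/4/8 over the four secreted categories.
#'
#' @param nSingle Single-peptide identifications (default 235).
#' @param nPlasmaContam Plasma contaminants in the digestive table
#'   (default 50).
#' @param nPrey Prey-homolog identifications (default 150).
#' @param nIntracellular Intracellular distractors surviving subtraction
#'   (default 77).
#' @param nSecreted Named counts per secreted category (default
#'   `c(MUCOSAL = 18, PROTEOLYTIC = 7, OTHER_HYDROLYTIC = 4, OTHER = 8)`).
#' @param nPlasmaOnly Plasma proteins absent from the digestive fluid
#'   (default 14, for a 64-protein plasma table).
#' @param nPreyDb Rows of the prey (mouse) table (default 60).
#' @param seed Integer seed.
#' @return A list with `digestive`, `plasma`, `prey` protein tables and
#'   `truth` (`protein_id`, `stratum`).
#' @export
simulateProteinTables <- function(nSingle = 235L, nPlasmaContam = 50L,
                                  nPrey = 150L, nIntracellular = 77L,
                                  nSecreted = c(MUCOSAL = 18L,
                                                PROTEOLYTIC = 7L,
                                                OTHER_HYDROLYTIC = 4L,
                                                OTHER = 8L),
                                  nPlasmaOnly = 14L, nPreyDb = 60L,
                                  seed = 1L) {
  .withSeed(seed, {
    draw <- function(pool, k, tag) {
      base <- .PROT_POOLS[[pool]]
      idx <- seq_len(k)
      sprintf("%s %s", base[(idx - 1L) %% length(base) + 1L],
              ifelse(idx > length(base),
                     paste0("variant ", (idx - 1L) %/% length(base)), ""))
    }
    strata <- c(rep("single", nSingle), rep("plasma", nPlasmaContam),
                rep("prey", nPrey), rep("intracellular", nIntracellular),
                rep("MUCOSAL", nSecreted[["MUCOSAL"]]),
                rep("PROTEOLYTIC", nSecreted[["PROTEOLYTIC"]]),
                rep("OTHER_HYDROLYTIC", nSecreted[["OTHER_HYDROLYTIC"]]),
                rep("OTHER", nSecreted[["OTHER"]]))
    n <- length(strata)
    if (n == 0L) {
      empty <- data.frame(protein_id = character(), annotation = character(),
                          unique_peptides = integer(), empai = numeric(),
                          stringsAsFactors = FALSE)
      return(list(digestive = empty, plasma = empty, prey = empty,
                  truth = data.frame(protein_id = character(),
                                     stratum = character())))
    }
    ids <- sprintf("dp%04d", seq_len(n))
    ann <- character(n)
    ann[strata == "single"] <- sprintf("hypothetical protein H%04d",
                                       seq_len(nSingle))
    ann[strata == "plasma"] <- trimws(draw("plasma", nPlasmaContam))
    ann[strata == "prey"] <- trimws(paste(
      tolower(baseTerm(draw("prey", nPrey))), "homolog",
      seq_len(max(nPrey, 1L))[seq_len(nPrey)]))
    ann[strata == "intracellular"] <- trimws(draw("intracellular",
                                                  nIntracellular))
    for (cl in c("MUCOSAL", "PROTEOLYTIC", "OTHER_HYDROLYTIC", "OTHER")) {
      pool <- c(MUCOSAL = "mucosal", PROTEOLYTIC = "proteolytic",
                OTHER_HYDROLYTIC = "other_hydrolytic", OTHER = "other")[[cl]]
      ann[strata == cl] <- trimws(draw(pool, nSecreted[[cl]]))
    }
    up <- ifelse(strata == "single", 1L, sample(2:20, n, replace = TRUE))
    digestive <- data.frame(
      protein_id = ids, annotation = ann, unique_peptides = up,
      empai = round(10^(runif(n, 0.05, 1)) - 1, 4L),
      stringsAsFactors = FALSE)

    plasmaIds <- c(ids[strata == "plasma"],
                   sprintf("pl%04d", seq_len(nPlasmaOnly)))
    plasmaAnn <- c(ann[strata == "plasma"],
                   trimws(draw("plasma", nPlasmaOnly)))
    plasma <- data.frame(
      protein_id = plasmaIds, annotation = plasmaAnn,
      unique_peptides = sample(2:20, length(plasmaIds), replace = TRUE),
      empai = round(10^(runif(length(plasmaIds), 0.05, 1)) - 1, 4L),
      stringsAsFactors = FALSE)

    prey <- data.frame(
      protein_id = sprintf("mm%04d", seq_len(nPreyDb)),
      annotation = trimws(draw("prey", nPreyDb)),
      unique_peptides = sample(2:15, nPreyDb, replace = TRUE),
      empai = NA_real_, stringsAsFactors = FALSE)

    list(digestive = digestive, plasma = plasma, prey = prey,
         truth = data.frame(protein_id = ids, stratum = strata,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a GO annotation with one planted enriched term
#'
#' Builds a reference universe of `nGenes` genes annotated with `nTerms`
#' exchangeable terms plus one planted term carried by exactly `plantedK`
#' genes, a random tree of child -> parent edges, and a test set of
#' `testN` genes drawn without replacement with sampling odds
#' `oddsMultiplier` for carriers of the planted term (`1` = null).
#'
#' @param nGenes Universe size (default 2000).
#' @param nTerms Number of background terms (default 20; the planted term
#'   is `T01`, backgrounds are `T02`...).
#' @param plantedK Carriers of the planted term (default 50).
#' @param testN Test-set size (default 100).
#' @param oddsMultiplier Sampling odds multiplier for planted-term carriers
#'   (>= 1; default 10).
#' @param seed Integer seed.
#' @return A list with `annotation` (data.frame `gene_id`, `go_terms`,
#'   `description`), `termGenes` (named list), `edges`, `testSet` and
#'   `plantedTerm`.
#' @export
simulateAnnotations <- function(nGenes = 2000L, nTerms = 20L,
                                plantedK = 50L, testN = 100L,
                                oddsMultiplier = 10, seed = 1L) {
  if (oddsMultiplier < 1) .stopf("simulateAnnotations: multiplier >= 1")
  .withSeed(seed, {
    genes <- sprintf("g%05d", seq_len(nGenes))
    terms <- sprintf("T%02d", seq_len(nTerms))
    termGenes <- vector("list", nTerms)
    names(termGenes) <- terms
    termGenes[[1L]] <- sample(genes, plantedK)
    for (j in seq_len(nTerms)[-1L]) {
      termGenes[[j]] <- sample(genes, sample(20:200, 1L))
    }
    ## per-gene term strings
    g2t <- split(rep(terms, lengths(termGenes)),
                 unlist(termGenes, use.names = FALSE))
    go <- rep("", nGenes)
    names(go) <- genes
    go[names(g2t)] <- vapply(g2t, paste, character(1), collapse = ";")
    annotation <- data.frame(gene_id = genes, go_terms = unname(go),
                             description = "", stringsAsFactors = FALSE)
    w <- rep(1, nGenes)
    names(w) <- genes
    w[termGenes[[1L]]] <- oddsMultiplier
    testSet <- sample(genes, testN, prob = w)
    parents <- if (nTerms > 1L)
      vapply(2:nTerms, function(j) terms[sample.int(j - 1L, 1L)], character(1))
    else character()
    edges <- data.frame(child = terms[-1L][seq_along(parents)],
                        parent = parents, stringsAsFactors = FALSE)
    list(annotation = annotation, termGenes = termGenes, edges = edges,
         testSet = testSet, plantedTerm = terms[1L])
  })
}

#' Simulate an aligned set of diverged nucleotide sequences
#'
#' Sequence 1 is uniform random over A/C/G/T; each further sequence is an
#' independent mutant of it in which every site is substituted with
#' probability `rate` by a uniformly chosen different base. The realised
#' mismatch proportion of every unordered pair is recorded as truth.
#'
#' @param n Number of sequences (>= 2).
#' @param length Alignment length.
#' @param rate Per-site substitution probability in `[0, 0.7]`.
#' @param seed Integer seed.
#' @return A list with `seqs` (`DNAStringSet`) and `p` (symmetric matrix of
#'   realised pairwise mismatch proportions).
#' @export
simulateAlignedSequences <- function(n = 2L, length = 1000L, rate = 0.1,
                                     seed = 1L) {
  if (rate < 0 || rate > 0.7)
    .stopf("simulateAlignedSequences: rate must lie in [0, 0.7]")
  .withSeed(seed, {
    bases <- c("A", "C", "G", "T")
    root <- sample(bases, length, replace = TRUE)
    mat <- matrix(rep(root, n), nrow = n, byrow = TRUE)
    if (n > 1L && rate > 0) for (i in 2:n) {
      hit <- runif(length) < rate
      k <- sum(hit)
      if (k > 0L) {
        cur <- mat[i, hit]
        mat[i, hit] <- vapply(cur, function(b) sample(setdiff(bases, b), 1L),
                              character(1))
      }
    }
    seqs <- DNAStringSet(apply(mat, 1L, paste, collapse = ""))
    names(seqs) <- sprintf("s%02d", seq_len(n))
    p <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      p[i, j] <- mean(mat[i, ] != mat[j, ])
    }
    list(seqs = seqs, p = p)
  })
}
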