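test_that("pseudocounted fold change matches hand evaluation", {
  expect_equal(foldChange(7, 7), list(magnitude = 1, direction = 0L))
  fc <- foldChange(50, 300, eps = 0.1)
  expect_equal(fc$magnitude, 300.1 / 50.1, tolerance = 1e-12)
  expect_equal(fc$direction, 1L)
  expect_equal(foldChange(0, 0), list(magnitude = 1, direction = 0L))
  expect_error(foldChange(-1, 2), ">= 0")
})

test_that("single-gene classification reproduces the worked examples", {
  cases <- list(
    list(f = c(0.5, 2, 8), cls = "LOWLY_EXPRESSED"),
    list(f = c(20, 400, 30), cls = "UP_THEN_DOWN"),
    list(f = c(50, 300, 250), cls = "UP"),
    list(f = c(500, 480, 520), cls = "HIGHLY_EXPRESSED"),
    list(f = c(150, 140, 160), cls = "MODERATELY_EXPRESSED"),
    list(f = c(300, 30, 320), cls = "DOWN_THEN_UP"),
    list(f = c(300, 250, 40), cls = "DOWN"))
  for (cs in cases) {
    got <- classifyGene(cs$f[1], cs$f[2], cs$f[3])
    expect_equal(as.character(got$class), cs$cls,
                 label = paste(cs$f, collapse = "/"))
  }
  # boundary: max exactly at the expressed gate stays lowly expressed
  expect_equal(as.character(classifyGene(10, 10, 10)$class),
               "LOWLY_EXPRESSED")
})

test_that("classification is a partition and monotone in the DEG gate", {
  set.seed(42)
  for (rep in 1:20) {
    f0 <- rexp(200, 0.02); f1 <- rexp(200, 0.02); f2 <- rexp(200, 0.02)
    got <- classifyGene(f0, f1, f2)
    expect_false(anyNA(got$class))
    s <- summarizeTrends(data.frame(class = got$class))
    expect_equal(sum(s$count), 200L)

    # raising fc_min can only shrink the DEG side of the partition
    loose <- classifyGene(f0, f1, f2, fcMin = 4)
    tight <- classifyGene(f0, f1, f2, fcMin = 8)
    degClasses <- c("UP", "DOWN", "UP_THEN_DOWN", "DOWN_THEN_UP")
    wasNonDeg <- !(as.character(loose$class) %in% degClasses)
    expect_false(any(wasNonDeg &
                       as.character(tight$class) %in% degClasses))
  }
})

test_that("time reversal swaps UP/DOWN and fixes the other classes", {
  # reversing the time axis negates every direction: monotone trends swap,
  # while a rise-then-fall profile read backwards is still rise-then-fall,
  # so the biphasic and expression-level classes are fixed points
  set.seed(7)
  f0 <- rexp(500, 0.02); f1 <- rexp(500, 0.02); f2 <- rexp(500, 0.02)
  fwd <- as.character(classifyGene(f0, f1, f2)$class)
  rev <- as.character(classifyGene(f2, f1, f0)$class)
  swap <- c(UP = "DOWN", DOWN = "UP",
            UP_THEN_DOWN = "UP_THEN_DOWN", DOWN_THEN_UP = "DOWN_THEN_UP",
            HIGHLY_EXPRESSED = "HIGHLY_EXPRESSED",
            MODERATELY_EXPRESSED = "MODERATELY_EXPRESSED",
            LOWLY_EXPRESSED = "LOWLY_EXPRESSED")
  expect_equal(rev, unname(swap[fwd]))
})

test_that("matrix classification recovers planted classes and is order-equivariant", {
  sim <- simulateTrendCounts(genesPerClass = 30, tissues = "liver", seed = 9)
  fp <- computeFpkm(aggregateToGenes(sim$counts), totals = sim$totals)
  got <- classifyTrends(fp, "liver")
  expect_equal(as.character(got$class), sim$truth$class)

  # all-zero matrix is entirely lowly expressed
  zero <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = matrix(0, 5, 3,
                                dimnames = list(paste0("g", 1:5),
                                                colnames(fp)[1:3]))),
    colData = SummarizedExperiment::colData(fp)[1:3, ])
  gotZero <- classifyTrends(zero, "liver")
  expect_true(all(gotZero$class == "LOWLY_EXPRESSED"))

  # permuting gene rows permutes output identically
  perm <- sample(nrow(fp))
  gotPerm <- classifyTrends(fp[perm, ], "liver")
  expect_equal(gotPerm$gene_id, got$gene_id[perm])
  expect_equal(as.character(gotPerm$class), as.character(got$class)[perm])

  # missing timepoint is a validation error
  expect_error(classifyTrends(fp[, -1], "liver"), "exactly one")
})

test_that("summaries count a partition with one-decimal percentages", {
  df <- data.frame(class = factor(c(rep("UP", 7), rep("DOWN", 3)),
                                  levels = trendColors()$class))
  s <- summarizeTrends(list(stomach = df))
  expect_equal(s$count[s$class == "UP"], 7L)
  expect_equal(s$percent[s$class == "UP"], 70.0)
  expect_equal(s$percent[s$class == "DOWN"], 30.0)
  expect_equal(sum(s$count), 10L)

  one <- summarizeTrends(data.frame(class = "UP"))
  expect_equal(one$percent[one$class == "UP"], 100.0)
  expect_error(summarizeTrends(list()), "empty")
})

test_that("strict DEG selection applies inclusive thresholds", {
  mk <- function(f) {
    sheet <- validateSampleSheet(data.frame(
      sample_id = c("st0", "st1", "st2"), tissue = "stomach",
      timepoint = c("fasting", "24h", "48h"), stringsAsFactors = FALSE))
    SummarizedExperiment::SummarizedExperiment(
      assays = list(fpkm = matrix(f, 1, 3,
                                  dimnames = list("g1", sheet$sample_id))),
      colData = S4Vectors::DataFrame(sheet, row.names = sheet$sample_id))
  }
  expect_equal(selectStrictDegs(mk(c(100, 450, 420)), "stomach"), "g1")
  expect_equal(selectStrictDegs(mk(c(450, 450, 450)), "stomach"), character())
  expect_equal(selectStrictDegs(mk(c(399, 133, 50)), "stomach"), character())
  # boundary: a gene peaking at exactly FPKM 400 is eligible
  expect_equal(selectStrictDegs(mk(c(400, 199, 380)), "stomach"), "g1")
})

test_that("trend colour mapping is total, injective and matches the scheme", {
  cols <- trendColors()
  expect_equal(nrow(cols), 7L)
  expect_false(anyDuplicated(cols$hex) > 0)
  expect_equal(assignColor("UP")$color_name, "Red")
  expect_equal(assignColor("UP")$hex, "#FF0000")
  expect_equal(assignColor("LOWLY_EXPRESSED")$color_name, "Dark grey")
  expect_equal(assignColor("LOWLY_EXPRESSED")$hex, "#A9A9A9")
  expect_equal(assignColor("DOWN")$color_name, "Blue")
  expect_equal(assignColor("UP_THEN_DOWN")$color_name, "Yellow")
  expect_equal(assignColor("DOWN_THEN_UP")$color_name, "Brown")
  expect_equal(assignColor("HIGHLY_EXPRESSED")$color_name, "Purple")
  expect_equal(assignColor("MODERATELY_EXPRESSED")$color_name, "Pink")
  expect_error(assignColor("SIDEWAYS"), "unknown")
})
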