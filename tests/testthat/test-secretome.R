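protTable <- function(up = c(1L, 2L, 3L, 1L, 5L),
                      ann = sprintf("protein %d", seq_along(up))) {
  validateProteinTable(data.frame(
    protein_id = sprintf("p%02d", seq_along(up)),
    annotation = ann, unique_peptides = up, stringsAsFactors = FALSE))
}

test_that("peptide-evidence filter keeps proteins with enough unique peptides", {
  st <- filterMinPeptides(protTable())
  expect_equal(length(st$retained), 3L)
  expect_setequal(st$removed, c("p01", "p04"))
  expect_true(all(nzchar(st$reasons)))
  # minUnique = 1 is the identity
  expect_equal(length(filterMinPeptides(protTable(), 1L)$removed), 0L)
  expect_error(filterMinPeptides(protTable(), 0L), ">= 1")
})

test_that("emPAI follows its closed form and is monotone", {
  expect_equal(computeEmpai(8, 8), 9)
  expect_equal(computeEmpai(0, 8), 0)
  expect_equal(computeEmpai(4, 8), 10^0.5 - 1, tolerance = 1e-12)
  vals <- computeEmpai(0:10, 10)
  expect_true(all(diff(vals) > 0))
  expect_error(computeEmpai(1, 0), ">= 1")
  expect_error(computeEmpai(5, 4), "<=")
})

test_that("plasma subtraction removes by id and is idempotent", {
  dig <- protTable(up = rep(3L, 6))
  plasma <- protTable(up = rep(2L, 3))  # ids p01..p03 overlap
  st <- subtractPlasma(dig, plasma)
  expect_setequal(st$removed, c("p01", "p02", "p03"))
  expect_true(all(st$reasons == "plasma"))
  again <- subtractPlasma(st$table, plasma)
  expect_equal(length(again$removed), 0L)

  disjoint <- plasma; disjoint$protein_id <- paste0("x", disjoint$protein_id)
  expect_equal(length(subtractPlasma(dig, disjoint)$removed), 0L)
})

test_that("base-term derivation reproduces the collagen and keratin rules", {
  expect_equal(baseTerm("Collagen alpha-1(I) chain"), "collagen")
  expect_equal(baseTerm("Keratin, type II cytoskeletal 1"), "keratin")
  expect_equal(baseTerm("Troponin C"), "troponin")
  expect_equal(baseTerm("Laminin subunit beta-1"), "laminin")
  expect_equal(baseTerm("serum albumin"), "serum albumin")
  expect_error(baseTerm("alpha-1(I)"), "empty base term")
})

test_that("prey-homolog subtraction removes annotation matches with reasons", {
  dig <- protTable(up = rep(3L, 4),
                   ann = c("collagen alpha-2(I) chain-like", "keratin-like",
                           "mucin-6-like", "gastricsin-like precursor"))
  prey <- protTable(up = rep(2L, 2),
                    ann = c("Collagen alpha-1(I) chain",
                            "Keratin, type II cytoskeletal 1"))
  st <- subtractPreyHomologs(dig, prey)
  expect_setequal(st$removed, c("p01", "p02"))
  expect_match(st$reasons[["p01"]], "collagen")
  expect_match(st$reasons[["p02"]], "keratin")
  # idempotent: re-running removes nothing new
  expect_equal(length(subtractPreyHomologs(st$table, prey)$removed), 0L)
  # no base term present anywhere -> identity
  inert <- protTable(up = rep(2L, 2), ann = c("Myoglobin", "Desmin"))
  expect_equal(length(subtractPreyHomologs(dig[3:4, ], inert)$removed), 0L)
})

test_that("keyword categorisation follows the fixed priority", {
  km <- defaultKeywordMap()
  expect_setequal(names(km), c("not_secreted", "mucosal", "proteolytic",
                               "other_hydrolytic", "other"))
  tab <- protTable(up = rep(3L, 5),
                   ann = c("mucin-6-like", "gastricsin-like precursor",
                           "phospholipase A2", "gastric intrinsic factor",
                           "calpain 9"))
  got <- categorizeSecretome(tab, km)
  expect_equal(as.character(got$proteins$category),
               c("MUCOSAL", "PROTEOLYTIC", "OTHER_HYDROLYTIC", "OTHER",
                 "NOT_SECRETED"))
  # calpain 9 is a protease, but the intracellular keyword wins
  expect_equal(unname(got$counts["PROTEOLYTIC"]), 1L)
  # unmatched annotations are conservatively non-secreted
  unk <- categorizeSecretome(protTable(up = 2L, ann = "mystery factor"), km)
  expect_equal(as.character(unk$proteins$category), "NOT_SECRETED")
})

test_that("emPAI-FPKM regression matches the normal-equation oracle", {
  x <- c(1, 2, 3, 4, 5)
  fit <- correlateExpressionProtein(2 * x + 1, x)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  set.seed(3)
  xs <- rexp(5, 0.1); ys <- rexp(5, 1)
  fit <- correlateExpressionProtein(ys, xs)
  X <- cbind(1, xs)
  beta <- solve(t(X) %*% X, t(X) %*% ys)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-12)
  expect_equal(fit$slope, beta[2], tolerance = 1e-12)

  # independence gives a near-zero coefficient of determination
  set.seed(21)
  r2 <- replicate(50, {
    x <- rexp(64, 0.01)
    correlateExpressionProtein(sample(x), x)$r_squared
  })
  expect_lt(mean(r2), 0.05)

  expect_error(correlateExpressionProtein(c(1, 2), c(1, 2)), ">= 3")
  expect_error(correlateExpressionProtein(c(1, 2, 3), c(5, 5, 5)),
               "zero variance")
})

test_that("the full chain recovers planted strata counts exactly", {
  pt <- simulateProteinTables(seed = 11)
  res <- runSecretomeChain(pt$digestive, pt$plasma, pt$prey)
  cnt <- stageCounts(res$report)
  expect_equal(unname(cnt), c(549L, 314L, 264L, 114L, 37L))
  expect_equal(unname(res$counts),
               c(18L, 7L, 4L, 8L))

  # per-stage audit identity and strict nesting
  prev <- cnt[["input"]]
  for (i in seq_along(stageNames(res$report))) {
    ret <- retainedIds(res$report, i)
    rem <- names(removedIds(res$report, i))
    expect_equal(length(ret) + length(rem), prev)
    prev <- length(ret)
  }

  # removed sets match the planted strata
  truth <- pt$truth
  expect_setequal(names(removedIds(res$report, "min_peptides")),
                  truth$protein_id[truth$stratum == "single"])
  expect_setequal(names(removedIds(res$report, "plasma")),
                  truth$protein_id[truth$stratum == "plasma"])
  expect_setequal(names(removedIds(res$report, "prey_homolog")),
                  truth$protein_id[truth$stratum == "prey"])
  secIds <- truth$protein_id[truth$stratum %in%
                               c("MUCOSAL", "PROTEOLYTIC",
                                 "OTHER_HYDROLYTIC", "OTHER")]
  expect_setequal(retainedIds(res$report), secIds)
})

test_that("chain report validity, show and serialisation behave", {
  pt <- simulateProteinTables(nSingle = 5L, nPlasmaContam = 2L, nPrey = 3L,
                              nIntracellular = 2L,
                              nSecreted = c(MUCOSAL = 2L, PROTEOLYTIC = 1L,
                                            OTHER_HYDROLYTIC = 1L,
                                            OTHER = 1L),
                              nPlasmaOnly = 1L, nPreyDb = 10L, seed = 2)
  res <- runSecretomeChain(pt$digestive, pt$plasma, pt$prey)
  expect_output(show(res$report), "FilterChainReport")
  tab <- chainReportTable(res$report)
  expect_true(all(tab$reason[tab$status == "removed"] != ""))
  expect_error(retainedIds(res$report, "nonexistent"), "unknown stage")

  # an empty digestive table flows through without error
  empty <- pt$digestive[0, ]
  res0 <- runSecretomeChain(empty, pt$plasma, pt$prey)
  expect_equal(unname(stageCounts(res0$report)), rep(0L, 5))
})
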