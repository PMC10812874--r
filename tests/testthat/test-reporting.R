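rankTable <- function(mseA, mseB) {
  data.frame(split = rep(seq_along(mseA), 2),
             condition = rep(c("A", "B"), each = length(mseA)),
             mse = c(mseA, mseB))
}

test_that("average rankings follow the winner-fraction arithmetic", {
  # A wins all 30 splits
  all30 <- rankTable(rep(1, 30), rep(2, 30))
  expect_equal(averageRanking(all30), c(A = 1.0, B = 2.0))
  # A wins 24 of 30: 0.8*1 + 0.2*2 = 1.2 vs 1.8
  a <- rep(1, 30); b <- rep(2, 30)
  b[1:6] <- 0.5
  expect_equal(averageRanking(rankTable(a, b)), c(A = 1.2, B = 1.8))
  # exact tie on a split shares the midrank
  tie <- rankTable(c(1, 1), c(1, 2))
  expect_equal(unname(averageRanking(tie)), c(1.25, 1.75))
  expect_error(averageRanking(rankTable(1, 2)[1, ]), "2 conditions")
  expect_error(averageRanking(rbind(all30, all30[1, ])), "exactly once")
})

test_that("percentage MSE reduction is the referenced relative difference", {
  expect_equal(percentMseReduction(2, 1), 50)
  expect_equal(percentMseReduction(1.5, 1.5), 0)
  set.seed(6)
  r <- rexp(50) + 0.1; c <- rexp(50)
  expect_equal(percentMseReduction(r, c), 100 * (r - c) / r,
               tolerance = 1e-12)
  # antisymmetry after rescaling by the reference
  expect_equal(percentMseReduction(2, 1) / 100,
               -(percentMseReduction(1, 2) / 100) * (1 / 2))
  expect_error(percentMseReduction(0, 1), "positive")
})

test_that("per-drug errors partition the overall test error", {
  resp <- randomResponses(10, 2, seed = 41)
  pd <- toyPaired(resp)
  bm <- fitDrugAverage(pd)
  per <- perDrugError(bm, pd)
  for (d in per$drug) {   # per-drug MSE equals the subset's whole MSE
    sub <- subsetPairs(pd, idx = which(pd@pairIndex$drug == d))
    expect_equal(per$mse[per$drug == d],
                 mse(predictDrugAverage(bm, sub), sub@targets))
  }
  # a perfect predictor scores zero
  perfect <- new("BenchmarkModel",
                 perDrugMean = c(dA = 1), globalMean = 1)
  one <- toyPaired(data.frame(cell_line = c("c1", "c2"), drug = "dA",
                              ln_ic50 = c(1, 1)))
  expect_equal(perDrugError(perfect, one)$mse, 0)
  # the mean predictor's per-drug MSE is the drug's target variance (pop.)
  for (d in per$drug) {
    y <- pd@targets[pd@pairIndex$drug == d]
    expect_equal(per$mse[per$drug == d], mean((y - mean(y))^2))
  }
  expect_true(all(per$n >= 2))
})

test_that("variability association handles monotone, constant and noisy input", {
  upDf <- data.frame(drug = letters[1:8], mse = 1:8,
                     n = 5L, target_sd = seq(0.1, 0.8, 0.1),
                     flagged = FALSE)
  up <- drugVariabilityAssociation(upDf, seed = 1)
  expect_equal(up$rho, 1)
  expect_lt(up$p_value, 0.05)
  const <- upDf
  const$mse <- 2
  got <- drugVariabilityAssociation(const, seed = 1)
  expect_equal(got$rho, 0)
  expect_true(got$degenerate)
  expect_error(drugVariabilityAssociation(upDf[1:4, ]), "at least 5")
})

test_that("normality summary reports Gaussian vs skewed residuals correctly", {
  gaussHits <- skewHits <- 0
  for (s in 1:10) {
    set.seed(s)
    res <- errorNormalitySummary(list(gauss = rnorm(500),
                                      skew = rexp(500)))
    gaussHits <- gaussHits + (res$p_value[res$condition == "gauss"] > 0.01)
    skewHits <- skewHits + (res$p_value[res$condition == "skew"] < 0.01)
  }
  expect_gte(gaussHits, 9)
  expect_gte(skewHits, 9)
  const <- errorNormalitySummary(list(flat = rep(1, 25)))
  expect_true(const$degenerate)
  expect_true(is.na(const$p_value))
  expect_error(errorNormalitySummary(list(tiny = rnorm(5))), "fewer than 20")
})

test_that("the experiment driver emits consistent artifacts end to end", {
  cfg <- experimentConfig(
    synthetic = syntheticConfig(nCellLines = 24, nDrugs = 5,
                                nFeatures = c(rnaseq = 15, proteomics = 15),
                                nInformative = 4, responseSparsity = 0.2,
                                seed = 3),
    modalities = c("rnaseq", "proteomics"),
    learners = c("benchmark", "gbt"),
    nRepeats = 2, kSizes = 2, minSize = 15,
    gbtParams = list(nrounds = 40, max_depth = 3),
    seed = 5, outDir = withr::local_tempdir())
  res <- runExperiment(cfg)
  for (p in res$paths) expect_true(file.exists(p))
  # every condition appears at every size in every repeat
  tidy <- read.csv(res$paths$tidy)
  expect_identical(nrow(tidy), 2L * 2L * 3L)  # reps x sizes x conditions
  # comparison cells equal the max-size entries of the curves
  comp <- read.csv(res$paths$comparison)
  maxSize <- max(tidy$size)
  for (i in seq_len(nrow(comp))) {
    row <- tidy[tidy$rep == comp$rep[i] &
                tidy$modality == comp$modality[i] &
                tidy$learner == comp$learner[i] & tidy$size == maxSize, ]
    expect_equal(comp$test_mse[i], row$error)
  }
  # summary recomputes from the comparison rows
  summ <- read.csv(res$paths$comparisonSummary)
  for (i in seq_len(nrow(summ))) {
    sub <- comp[comp$modality == summ$modality[i] &
                comp$learner == summ$learner[i], ]
    expect_equal(summ$mean_mse[i], mean(sub$test_mse))
  }
  # rankings are permutations per split
  rk <- averageRanking(data.frame(
    split = comp$rep, condition = paste(comp$modality, comp$learner),
    mse = comp$test_mse))
  expect_equal(sum(rk), sum(1:3))
})

test_that("planted modality advantage shows in both mean MSE and mean rank", {
  wins <- 0
  for (s in 1:5) {
    set.seed(s)
    # rnaseq carries signal; proteomics is pure noise relative to it
    nCells <- 30; nDrugs <- 5
    cells <- sprintf("c%02d", seq_len(nCells))
    x <- rnorm(nCells)
    rna <- toyOmics(cells, 10, "rnaseq", seed = s)
    rna@values[, 1] <- x
    prot <- toyOmics(cells, 10, "proteomics", seed = s + 100)
    mu <- rnorm(nDrugs, sd = 2)
    resp <- expand.grid(cell_line = cells, drug = sprintf("d%d", 1:nDrugs),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    resp$ln_ic50 <- mu[as.integer(sub("d", "", resp$drug))] +
      1.5 * x[match(resp$cell_line, cells)] + rnorm(nrow(resp), 0, 0.3)
    pdR <- buildPairs(rna, resp)
    pdP <- buildPairs(prot, resp)
    msesR <- msesP <- numeric(3)
    for (r in 1:3) {
      sp <- cancerBlindSplit(cells, seed = s * 10 + r)
      fitEval <- function(pd) {
        g <- fitGBT(subsetPairs(pd, cells = trainCells(sp)),
                    subsetPairs(pd, cells = valCells(sp)),
                    list(nrounds = 60, max_depth = 3), seed = r)
        te <- subsetPairs(pd, cells = testCells(sp))
        mse(predictResponse(g, te), te@targets)
      }
      msesR[r] <- fitEval(pdR)
      msesP[r] <- fitEval(pdP)
    }
    rk <- averageRanking(data.frame(
      split = rep(1:3, 2), condition = rep(c("rna", "prot"), each = 3),
      mse = c(msesR, msesP)))
    if (mean(msesR) < mean(msesP) && rk["rna"] < rk["prot"])
      wins <- wins + 1
  }
  expect_gte(wins, 4)
})
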