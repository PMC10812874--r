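test_that("drug-average fitting matches the printed arithmetic", {
  resp <- data.frame(cell_line = c("c1", "c2", "c1"),
                     drug = c("dA", "dA", "dB"),
                     ln_ic50 = c(2, 4, 1))
  pd <- toyPaired(resp)
  bm <- fitDrugAverage(pd)
  expect_equal(bm@perDrugMean, c(dA = 3, dB = 1))
  expect_equal(bm@globalMean, 7 / 3)
  expect_equal(predictDrugAverage(bm, c("dA", "dZ")), c(3, 7 / 3))
  single <- fitDrugAverage(subsetPairs(pd, idx = 1L))
  expect_equal(unname(single@perDrugMean), single@globalMean)
  expect_error(fitDrugAverage(subsetPairs(pd, idx = integer())), "empty")
})

test_that("benchmark equals a brute-force group-by oracle on random tables", {
  resp <- randomResponses(25, 20, sparsity = 0.1, seed = 13)
  pd <- toyPaired(resp)
  bm <- fitDrugAverage(pd)
  for (d in unique(resp$drug)) {   # independent loop-based oracle
    expect_identical(unname(bm@perDrugMean[d]),
                     mean(resp$ln_ic50[resp$drug == d]))
  }
  expect_identical(bm@globalMean, mean(resp$ln_ic50))
  # predictions ignore the cell line entirely
  preds <- predictDrugAverage(bm, pd)
  for (d in unique(resp$drug)) {
    expect_identical(length(unique(preds[pd@pairIndex$drug == d])), 1L)
  }
})

test_that("mse matches explicit summation", {
  expect_identical(mse(c(1, 2), c(1, 2)), 0)
  expect_identical(mse(c(0, 0), c(1, 3)), 5)
  set.seed(21)
  a <- rnorm(100); b <- rnorm(100)
  acc <- 0
  for (i in 1:100) acc <- acc + (a[i] - b[i])^2
  expect_equal(mse(a, b), acc / 100, tolerance = 1e-12)
  expect_error(mse(1:3, 1:2), "length")
})

test_that("GBT captures a pure drug-mean signal to benchmark precision", {
  cfg <- syntheticConfig(nCellLines = 12, nDrugs = 3,
                         nFeatures = c(rnaseq = 6), cellEffectSD = 0,
                         noiseSD = 0, responseSparsity = 0, seed = 2)
  prof <- list(rnaseq = generateOmicsProfiles(cfg, "rnaseq"))
  resp <- generateIC50Table(cfg, prof)$responses
  pd <- buildPairs(prof$rnaseq, resp)
  sp <- cancerBlindSplit(cellLineIds(prof$rnaseq), c(0.6, 0.2, 0.2),
                         seed = 3)
  tr <- subsetPairs(pd, cells = trainCells(sp))
  va <- subsetPairs(pd, cells = valCells(sp))
  te <- subsetPairs(pd, cells = testCells(sp))
  g <- fitGBT(tr, va, list(nrounds = 2000, max_depth = 3,
                           learning_rate = 0.3), seed = 1)
  bench <- mse(predictDrugAverage(fitDrugAverage(tr), te), te@targets)
  expect_lte(mse(predictResponse(g, te), te@targets), bench + 1e-6)
})

test_that("GBT fits are reproducible and respect early stopping", {
  resp <- randomResponses(20, 5, seed = 17)
  pd <- toyPaired(resp, nFeatures = 6)
  sp <- cancerBlindSplit(sort(unique(resp$cell_line)), seed = 5)
  tr <- subsetPairs(pd, cells = trainCells(sp))
  va <- subsetPairs(pd, cells = valCells(sp))
  g1 <- fitGBT(tr, va, list(nrounds = 100), seed = 9)
  g2 <- fitGBT(tr, va, list(nrounds = 100), seed = 9)
  expect_identical(validationMSE(g1), validationMSE(g2))
  expect_lte(g1@stoppedAt, 100L)
  # early stopping returns the best observed round's score
  expect_true(is.finite(validationMSE(g1)))
  trBad <- tr
  trBad@cellInputs[1, 1] <- NA_real_
  expect_error(fitGBT(trBad, va), "non-finite")
})

test_that("learners beat the benchmark when omics carry the signal", {
  # averaged over seeds: at this desk scale single splits are noisy but
  # the omics-driven learners must win on average (their hypothesis space
  # nests the benchmark via the drug one-hots)
  res <- sapply(1:3, function(s) {
    cfg <- syntheticConfig(nCellLines = 80, nDrugs = 8,
                           nFeatures = c(rnaseq = 40), nInformative = 10,
                           cellEffectSD = 2, noiseSD = 0.3,
                           responseSparsity = 0.1, seed = s)
    prof <- list(rnaseq = generateOmicsProfiles(cfg, "rnaseq"))
    resp <- generateIC50Table(cfg, prof)$responses
    pd <- buildPairs(prof$rnaseq, resp)
    sp <- cancerBlindSplit(cellLineIds(prof$rnaseq), c(0.7, 0.15, 0.15),
                           seed = s)
    tr <- subsetPairs(pd, cells = trainCells(sp))
    va <- subsetPairs(pd, cells = valCells(sp))
    te <- subsetPairs(pd, cells = testCells(sp))
    bench <- mse(predictDrugAverage(fitDrugAverage(tr), te), te@targets)
    g <- fitGBT(tr, va, list(nrounds = 200, max_depth = 4), seed = 1)
    nn <- fitNN(tr, va, list(omics_widths = c(32L, 16L), head_widths = 16L),
                seed = 1)
    c(bench = bench, gbt = mse(predictResponse(g, te), te@targets),
      nn = mse(predictResponse(nn, te), te@targets))
  })
  expect_lt(mean(res["gbt", ]), mean(res["bench", ]))
  expect_lt(mean(res["nn", ]), mean(res["bench", ]))
})

test_that("NN fits are seed-reproducible and near-optimal on drug-only signal", {
  cfg <- syntheticConfig(nCellLines = 30, nDrugs = 5,
                         nFeatures = c(rnaseq = 10), cellEffectSD = 0,
                         noiseSD = 0.5, responseSparsity = 0, seed = 23)
  prof <- list(rnaseq = generateOmicsProfiles(cfg, "rnaseq"))
  resp <- generateIC50Table(cfg, prof)$responses
  pd <- buildPairs(prof$rnaseq, resp)
  sp <- cancerBlindSplit(cellLineIds(prof$rnaseq), c(0.7, 0.15, 0.15),
                         seed = 2)
  tr <- subsetPairs(pd, cells = trainCells(sp))
  va <- subsetPairs(pd, cells = valCells(sp))
  te <- subsetPairs(pd, cells = testCells(sp))
  prm <- list(omics_widths = c(16L, 8L), head_widths = 8L,
              max_epochs = 150, learning_rate = 3e-3)
  n1 <- fitNN(tr, va, prm, seed = 4)
  n2 <- fitNN(tr, va, prm, seed = 4)
  expect_equal(validationMSE(n1), validationMSE(n2), tolerance = 1e-6)
  expect_identical(n1@stoppedAt, n2@stoppedAt)
  bench <- mse(predictDrugAverage(fitDrugAverage(tr), te), te@targets)
  # the benchmark is optimal here; the network should land in its vicinity
  expect_lt(mse(predictResponse(n1, te), te@targets), bench * 1.5)
})

test_that("random search runs every trial and returns the validation minimum", {
  resp <- randomResponses(16, 4, seed = 19)
  pd <- toyPaired(resp, nFeatures = 5)
  sp <- cancerBlindSplit(sort(unique(resp$cell_line)), c(0.6, 0.2, 0.2),
                         seed = 3)
  tr <- subsetPairs(pd, cells = trainCells(sp))
  va <- subsetPairs(pd, cells = valCells(sp))
  space <- hyperparameterSpace(list(
    max_depth = list(choices = 2:4),
    learning_rate = list(low = 0.05, high = 0.3, scale = "log")),
    trialCount = 15L)
  best <- randomSearch("gbt", space, tr, va, seed = 6,
                       fixedParams = list(nrounds = 15))
  expect_identical(nrow(best@trials), 15L)
  expect_identical(validationMSE(best), min(best@trials$validation_mse))
  # single-point space returns exactly that configuration
  one <- hyperparameterSpace(list(max_depth = list(choices = 3L)),
                             trialCount = 2L)
  got <- randomSearch("gbt", one, tr, va, seed = 6,
                      fixedParams = list(nrounds = 10))
  expect_identical(got@hyperparameters$max_depth, 3L)
})
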