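makeFmap <- function() {
  featureMap(
    landmarkGenes = c("g2", "g3", "g9"),
    geneToProtein = data.frame(gene = c("g2", "g3", "g5"),
                               protein = c("p2", "p3", "p5")),
    geneTargets = data.frame(gene = c("g2", "g3"),
                             peptide = c("pep2a", "pep3a")),
    peptideToProtein = data.frame(
      peptide = c("pep2a", "pep2b", "pep3a", "pep5a"),
      protein = c("p2", "p2", "p3", "p5")))
}

test_that("omics matrices round-trip through write-then-read, masks included", {
  v <- matrix(c(1.5, 2.25, -3, 4, 5.125, 6), 3, 2,
              dimnames = list(c("c1", "c2", "c3"), c("f1", "f2")))
  m <- omicsMatrix(v, "rnaseq")
  path <- tempfile(fileext = ".tsv")
  writeOmicsMatrix(m, path)
  back <- suppressMessages(readOmicsMatrix(path, "rnaseq"))
  expect_identical(omicsValues(back), v)
  # one masked cell survives the round trip as exactly one mask entry
  mask <- matrix(FALSE, 3, 2)
  mask[2, 1] <- TRUE
  mm <- omicsMatrix(v, "proteomics", missingMask = mask)
  writeOmicsMatrix(mm, path)
  back2 <- suppressMessages(readOmicsMatrix(path, "proteomics"))
  expect_identical(sum(missingMask(back2)), 1L)
  expect_true(missingMask(back2)[2, 1])
})

test_that("transposed files read back to the identical matrix", {
  v <- matrix(rnorm(12), 3, 4,
              dimnames = list(sprintf("c%d", 1:3), sprintf("f%d", 1:4)))
  p1 <- tempfile(fileext = ".tsv")
  p2 <- tempfile(fileext = ".tsv")
  writeOmicsMatrix(omicsMatrix(v, "rnaseq"), p1)
  writeOmicsMatrix(omicsMatrix(t(v), "rnaseq"), p2)  # features-by-cells
  a <- suppressMessages(readOmicsMatrix(p1, "rnaseq"))
  b <- suppressMessages(readOmicsMatrix(p2, "rnaseq",
                                        orientation = "features-by-cells"))
  expect_equal(omicsValues(a), omicsValues(b))
})

test_that("reader rejects duplicate ids and ragged rows with diagnostics", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("id,f1,f2", "c1,1,2", "c1,3,4"), p)
  expect_error(suppressMessages(readOmicsMatrix(p, "rnaseq")), "c1")
  writeLines(c("id,f1,f2", "c1,1,2", "c2,3"), p)
  expect_error(suppressMessages(readOmicsMatrix(p, "rnaseq")), "line 3")
})

test_that("zero-imputation fills exactly the masked entries and clears the mask", {
  v <- matrix(c(1, NA, NA, 4), 2, 2,
              dimnames = list(c("c1", "c2"), c("p1", "p2")))
  m <- omicsMatrix(v, "proteomics", missingMask = is.na(v))
  out <- imputeMissingZero(m)
  expect_equal(unname(omicsValues(out)), matrix(c(1, 0, 0, 4), 2, 2))
  expect_null(missingMask(out))
  # identity on a complete matrix
  full <- omicsMatrix(matrix(1:4 + 0, 2, 2,
                             dimnames = list(c("a", "b"), c("x", "y"))),
                      "proteomics")
  expect_identical(omicsValues(imputeMissingZero(full)), omicsValues(full))
  # random mask: zeros exactly where the mask was true
  set.seed(42)
  vv <- matrix(rnorm(200) + 10, 20, 10,
               dimnames = list(sprintf("c%d", 1:20), sprintf("p%d", 1:10)))
  mk <- matrix(runif(200) < 0.3, 20, 10)
  imp <- omicsValues(imputeMissingZero(
    omicsMatrix(vv, "proteomics", missingMask = mk)))
  for (i in 1:20) for (j in 1:10) {
    if (mk[i, j]) expect_identical(imp[i, j], 0) else
      expect_identical(imp[i, j], vv[i, j])
  }
})

test_that("per-cell-line scaling yields mean 0 / population SD 1 rows", {
  m <- omicsMatrix(matrix(c(1, 2, 3), 1, 3,
                          dimnames = list("c1", c("a", "b", "c"))),
                   "phospho")
  expect_equal(as.numeric(omicsValues(scalePerCellLine(m))),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  cm <- omicsMatrix(matrix(5, 1, 3, dimnames = list("c1", c("a", "b", "c"))),
                    "phospho")
  expect_equal(as.numeric(omicsValues(scalePerCellLine(cm))), c(0, 0, 0))
  set.seed(1)
  big <- omicsMatrix(matrix(rnorm(500, 3, 2), 10, 50,
                            dimnames = list(sprintf("c%d", 1:10),
                                            sprintf("f%d", 1:50))),
                     "phospho")
  sv <- omicsValues(scalePerCellLine(big))
  expect_true(all(abs(rowMeans(sv)) < 1e-9))
  expect_true(all(abs(sqrt(rowMeans((sv - rowMeans(sv))^2)) - 1) < 1e-9))
  one <- omicsMatrix(matrix(1, 2, 1, dimnames = list(c("a", "b"), "f")),
                     "phospho")
  expect_error(scalePerCellLine(one), "at least 2")
})

test_that("landmark selection implements the per-modality rules", {
  fmap <- makeFmap()
  rna <- toyOmics(c("c1", "c2"), 3, "rnaseq")
  colnames(rna@values) <- c("g1", "g2", "g3")
  expect_identical(featureIds(selectLandmarkFeatures(rna, fmap)),
                   c("g2", "g3"))
  prot <- toyOmics(c("c1", "c2"), 3, "proteomics")
  colnames(prot@values) <- c("p2", "p4", "p5")
  # p5 is coded by g5, not a landmark; p4 unmapped
  expect_identical(featureIds(selectLandmarkFeatures(prot, fmap)), "p2")
  ph <- toyOmics(c("c1", "c2"), 4, "phospho")
  colnames(ph@values) <- c("pep2a", "pep2b", "pep3a", "pep5a")
  # pep2b sits on a landmark-coded protein but is not a landmark target
  expect_identical(featureIds(selectLandmarkFeatures(ph, fmap)),
                   c("pep2a", "pep3a"))
  bad <- toyOmics(c("c1", "c2"), 2, "rnaseq")
  colnames(bad@values) <- c("gX", "gY")
  expect_error(selectLandmarkFeatures(bad, fmap), "mapping")
  expect_error(selectLandmarkFeatures(toyOmics("c1", 2, "metab"), fmap),
               "rnaseq")
})

test_that("phospho selection equals brute-force enumeration of the rule", {
  set.seed(9)
  genes <- sprintf("g%d", 1:12)
  prots <- sprintf("p%d", 1:12)
  peps <- sprintf("pep%d", 1:40)
  fmap <- featureMap(
    landmarkGenes = sample(genes, 5),
    geneToProtein = data.frame(gene = genes, protein = prots),
    geneTargets = data.frame(gene = sample(genes, 25, replace = TRUE),
                             peptide = sample(peps, 25)),
    peptideToProtein = data.frame(peptide = peps,
                                  protein = sample(prots, 40,
                                                   replace = TRUE)))
  ph <- toyOmics(sprintf("c%d", 1:3), 40, "phospho")
  colnames(ph@values) <- peps
  got <- featureIds(selectLandmarkFeatures(ph, fmap))
  lmProt <- fmap@geneToProtein$protein[
    fmap@geneToProtein$gene %in% fmap@landmarkGenes]
  expected <- character()
  for (pep in peps) {   # brute force over every peptide
    host <- fmap@peptideToProtein$protein[
      fmap@peptideToProtein$peptide == pep]
    isTarget <- any(fmap@geneTargets$peptide == pep &
                    fmap@geneTargets$gene %in% fmap@landmarkGenes)
    if (length(host) && host %in% lmProt && isTarget)
      expected <- c(expected, pep)
  }
  expect_identical(got, expected)
  # idempotence
  once <- selectLandmarkFeatures(ph, fmap)
  expect_identical(omicsValues(selectLandmarkFeatures(once, fmap)),
                   omicsValues(once))
})

test_that("feature subsampling is seeded, order-preserving and near-uniform", {
  m <- toyOmics(sprintf("c%d", 1:4), 6)
  expect_identical(featureIds(subsampleFeatures(m, 6, seed = 1)),
                   featureIds(m))
  a <- subsampleFeatures(m, 3, seed = 11)
  b <- subsampleFeatures(m, 3, seed = 11)
  expect_identical(featureIds(a), featureIds(b))
  expect_error(subsampleFeatures(m, 7, seed = 1), "cannot subsample")
  counts <- integer(6)
  for (s in 1:1000) {
    idx <- match(featureIds(subsampleFeatures(m, 2, seed = s)),
                 featureIds(m))
    counts[idx] <- counts[idx] + 1L
  }
  expect_true(all(abs(counts / 1000 - 1 / 3) < 0.06))
})

test_that("one-site-per-protein keeps the highest-variance site", {
  v <- cbind(pepA1 = c(0, 4, 8), pepA2 = c(1, 1.5, 2), pepB1 = c(5, 6, 7))
  rownames(v) <- sprintf("c%d", 1:3)
  fmap <- featureMap("g1",
    peptideToProtein = data.frame(peptide = c("pepA1", "pepA2", "pepB1"),
                                  protein = c("pA", "pA", "pB")))
  out <- collapseOneSitePerProtein(omicsMatrix(v, "phospho"), fmap)
  expect_identical(featureIds(out), c("pepA1", "pepB1"))
  # all-singleton map: identity
  fmap2 <- featureMap("g1",
    peptideToProtein = data.frame(peptide = colnames(v),
                                  protein = c("pA", "pB", "pC")))
  expect_identical(featureIds(collapseOneSitePerProtein(
    omicsMatrix(v, "phospho"), fmap2)), colnames(v))
  # random map: one column per distinct protein
  set.seed(3)
  peps <- sprintf("pep%d", 1:20)
  prot <- sample(sprintf("p%d", 1:7), 20, replace = TRUE)
  m <- toyOmics(sprintf("c%d", 1:5), 20, "phospho")
  colnames(m@values) <- peps
  fmap3 <- featureMap("g1",
    peptideToProtein = data.frame(peptide = peps, protein = prot))
  expect_identical(length(featureIds(collapseOneSitePerProtein(m, fmap3))),
                   length(unique(prot)))
  fmap4 <- featureMap("g1",
    peptideToProtein = data.frame(peptide = peps[-1], protein = prot[-1]))
  expect_error(collapseOneSitePerProtein(m, fmap4), "pep1")
})

test_that("the pipeline scales phospho rows before selecting features", {
  set.seed(5)
  peps <- c("pep2a", "pep2b", "pep3a", "pep5a")
  v <- matrix(rnorm(12, 2, 3), 3, 4,
              dimnames = list(sprintf("c%d", 1:3), peps))
  m <- omicsMatrix(v, "phospho")
  fmap <- makeFmap()
  got <- prepOmics(m, fmap)
  scaleFirst <- selectLandmarkFeatures(scalePerCellLine(m), fmap)
  selectFirst <- scalePerCellLine(selectLandmarkFeatures(m, fmap))
  expect_equal(omicsValues(got), omicsValues(scaleFirst))
  expect_gt(max(abs(omicsValues(scaleFirst) - omicsValues(selectFirst))), 1e-6)
})

test_that("no preprocessing operation reorders or drops cell lines", {
  cells <- sprintf("c%02d", 1:6)
  m <- toyOmics(cells, 8, "phospho", seed = 2)
  fmap <- featureMap("g1",
    peptideToProtein = data.frame(peptide = featureIds(m),
                                  protein = sprintf("p%d", rep(1:4, 2))))
  expect_identical(cellLineIds(scalePerCellLine(m)), cells)
  expect_identical(cellLineIds(subsampleFeatures(m, 4, 1)), cells)
  expect_identical(cellLineIds(collapseOneSitePerProtein(m, fmap)), cells)
  expect_identical(cellLineIds(imputeMissingZero(m)), cells)
})
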