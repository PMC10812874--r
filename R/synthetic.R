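#' @include AllClasses.R
NULL

#' Configure the synthetic multi-omics study
#'
#' Builds a [SyntheticConfig-class] describing a simulated drug-response
#' study. Defaults are sized for desk-scale experiments: 200 cell lines,
#' 50 drugs and 200 features per modality, with proteomics-style
#' missingness at 38\% and 30\% of (cell, drug) responses unmeasured.
#'
#' The generating model is \eqn{y(c,d) = \mu_d + e_c + \epsilon} with
#' \eqn{\mu_d \sim N(1, drugMeanSD^2)}, a per-cell sensitivity effect
#' \eqn{e_c \sim N(0, cellEffectSD^2)} embedded linearly into the
#' informative features of every modality, and
#' \eqn{\epsilon \sim N(0, noiseSD^2)}.
#'
#' @param nCellLines,nDrugs study dimensions.
#' @param nFeatures named integer vector of features per modality; names
#'   declare the modalities (\code{"proteomics"} receives missingness).
#' @param drugMeanSD SD of drug-level mean ln(IC50).
#' @param cellEffectSD SD of the cell-line effect.
#' @param nInformative informative features per modality.
#' @param noiseSD residual noise SD.
#' @param missingRate proteomics missingness fraction.
#' @param responseSparsity fraction of unmeasured (cell, drug) pairs.
#' @param seed integer seed.
#' @return A [SyntheticConfig-class].
#' @examples
#' cfg <- syntheticConfig(nCellLines = 20, nDrugs = 5, seed = 7)
#' @export
syntheticConfig <- function(nCellLines = 200L, nDrugs = 50L,
                            nFeatures = c(rnaseq = 200L, proteomics = 200L,
                                          phospho = 200L),
                            drugMeanSD = 2, cellEffectSD = 1,
                            nInformative = 20L, noiseSD = 0.5,
                            missingRate = 0.38, responseSparsity = 0.3,
                            seed = 1L) {
  nInformative <- min(as.integer(nInformative), as.integer(min(nFeatures)))
  nf <- vapply(nFeatures, as.integer, integer(1))
  new("SyntheticConfig", nCellLines = as.integer(nCellLines),
      nDrugs = as.integer(nDrugs), nFeatures = nf,
      drugMeanSD = drugMeanSD, cellEffectSD = cellEffectSD,
      nInformative = nInformative, noiseSD = noiseSD,
      missingRate = missingRate, responseSparsity = responseSparsity,
      seed = as.integer(seed))
}

# shared latent cell effect (unit scale) and informative columns; both are
# functions of the config seed only, so every modality embeds the same signal
.syntheticLatent <- function(config, modality) {
  set.seed(deriveSeed(config@seed, 7L))
  z <- stats::rnorm(config@nCellLines)
  p <- config@nFeatures[[modality]]
  midx <- match(modality, names(config@nFeatures))
  set.seed(deriveSeed(config@seed, 11L + midx))
  inf <- sort(sample.int(p, config@nInformative))
  loadings <- stats::runif(config@nInformative, 0.5, 1.5)
  list(z = z, informative = inf, loadings = loadings)
}

.syntheticIds <- function(config, modality) {
  p <- config@nFeatures[[modality]]
  cells <- sprintf("CL%04d", seq_len(config@nCellLines))
  feats <- switch(modality,
    rnaseq = sprintf("G%04d", seq_len(p)),
    proteomics = sprintf("P%04d", seq_len(p)),
    phospho = sprintf("PP%04d", seq_len(p)),
    sprintf("%s_F%04d", toupper(modality), seq_len(p)))
  list(cells = cells, feats = feats)
}

#' Generate one modality's synthetic omics profiles
#'
#' Draws a cell-line x feature matrix on a log2-like continuous scale and
#' embeds the shared latent cell-line effect into the modality's
#' informative features, so downstream learners can recover cell-line
#' signal from any modality. For the \code{"proteomics"} modality a
#' fraction \code{missingRate} of entries is flagged missing (mask set,
#' values \code{NA}) prior to zero-imputation, mirroring
#' below-limit-of-quantitation dropout.
#'
#' @param config a [SyntheticConfig-class].
#' @param modality one of the modalities declared in
#'   \code{config@nFeatures}.
#' @return An [OmicsMatrix-class]; identical output for identical config.
#' @examples
#' cfg <- syntheticConfig(nCellLines = 10, nDrugs = 3,
#'                        nFeatures = c(rnaseq = 20), seed = 7)
#' generateOmicsProfiles(cfg, "rnaseq")
#' @export
generateOmicsProfiles <- function(config, modality) {
  validObject(config)
  if (!modality %in% names(config@nFeatures))
    stop("modality '", modality, "' is not declared in the config (declared: ",
         paste(names(config@nFeatures), collapse = ", "), ")")
  n <- config@nCellLines
  p <- config@nFeatures[[modality]]
  ids <- .syntheticIds(config, modality)
  midx <- match(modality, names(config@nFeatures))
  set.seed(deriveSeed(config@seed, 100L + midx))
  base <- switch(modality,
    rnaseq = matrix(stats::rnorm(n * p, mean = 5, sd = 2), n, p),
    proteomics = matrix(stats::rnorm(n * p, mean = 0, sd = 1.5), n, p),
    matrix(stats::rnorm(n * p), n, p))
  lat <- .syntheticLatent(config, modality)
  if (length(lat$informative))
    base[, lat$informative] <- base[, lat$informative] +
      outer(lat$z, lat$loadings)
  dimnames(base) <- list(ids$cells, ids$feats)
  mask <- NULL
  if (identical(modality, "proteomics") && config@missingRate > 0) {
    set.seed(deriveSeed(config@seed, 200L + midx))
    mask <- matrix(stats::runif(n * p) < config@missingRate, n, p)
  }
  omicsMatrix(base, modality, missingMask = mask)
}

#' Generate a synthetic ln(IC50) response table
#'
#' Simulates \eqn{y(c,d) = \mu_d + e_c + \epsilon} for every (cell, drug)
#' pair, then drops a fraction \code{responseSparsity} of pairs uniformly
#' at random. The cell effect \eqn{e_c = cellEffectSD \cdot z_c} uses the
#' same latent \eqn{z_c} that [generateOmicsProfiles()] embeds into the
#' informative features, so the signal is learnable from the profiles.
#'
#' @param config a [SyntheticConfig-class].
#' @param profiles named list of [OmicsMatrix-class], one per declared
#'   modality (consistency check; the table itself depends only on the
#'   config).
#' @return list with elements \code{responses} (data.frame
#'   \code{cell_line}, \code{drug}, \code{ln_ic50}, sorted by cell line
#'   then drug) and \code{truth} (a [GroundTruth-class]).
#' @examples
#' cfg <- syntheticConfig(nCellLines = 10, nDrugs = 4,
#'                        nFeatures = c(rnaseq = 20),
#'                        responseSparsity = 0, seed = 1)
#' prof <- list(rnaseq = generateOmicsProfiles(cfg, "rnaseq"))
#' nrow(generateIC50Table(cfg, prof)$responses)  # 40
#' @export
generateIC50Table <- function(config, profiles) {
  validObject(config)
  if (!length(profiles)) stop("profiles must be a non-empty list")
  absent <- setdiff(names(config@nFeatures), names(profiles))
  if (length(absent))
    stop("profiles missing declared modalities: ",
         paste(absent, collapse = ", "))
  n <- config@nCellLines
  d <- config@nDrugs
  cells <- cellLineIds(profiles[[1L]])
  drugs <- sprintf("D%03d", seq_len(d))

  set.seed(deriveSeed(config@seed, 9L))
  mu <- stats::rnorm(d, mean = 1, sd = config@drugMeanSD)
  names(mu) <- drugs

  set.seed(deriveSeed(config@seed, 7L))
  z <- stats::rnorm(n)
  e <- config@cellEffectSD * z
  names(e) <- cells

  grid <- expand.grid(drug = drugs, cell_line = cells,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("cell_line", "drug")]
  set.seed(deriveSeed(config@seed, 13L))
  eps <- stats::rnorm(nrow(grid), sd = config@noiseSD)
  grid$ln_ic50 <- mu[grid$drug] + e[grid$cell_line] + eps

  if (config@responseSparsity > 0) {
    nDrop <- floor(config@responseSparsity * nrow(grid))
    if (nDrop > 0) {
      set.seed(deriveSeed(config@seed, 17L))
      grid <- grid[-sample.int(nrow(grid), nDrop), ]
    }
  }
  grid <- grid[order(grid$cell_line, grid$drug), ]
  rownames(grid) <- NULL

  weights <- lapply(names(config@nFeatures), function(m) {
    lat <- .syntheticLatent(config, m)
    w <- numeric(config@nFeatures[[m]])
    w[lat$informative] <- lat$loadings
    w
  })
  names(weights) <- names(config@nFeatures)
  truth <- new("GroundTruth", drugMeans = mu, effectWeights = weights,
               cellEffects = e, noiseSD = config@noiseSD)
  list(responses = grid, truth = truth)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits one TSV matrix per modality (readable by [readOmicsMatrix()],
#' with missing proteomics entries as empty cells), the long-format
#' response CSV (readable by [readResponseTable()]) and a small JSON
#' ground-truth summary, so synthetic and real data flow through the same
#' reader code path.
#'
#' @param config a [SyntheticConfig-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of written file paths.
#' @export
writeSyntheticDataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- lapply(names(config@nFeatures),
                     function(m) generateOmicsProfiles(config, m))
  names(profiles) <- names(config@nFeatures)
  tab <- generateIC50Table(config, profiles)
  paths <- list()
  for (m in names(profiles)) {
    p <- file.path(dir, paste0(m, ".tsv"))
    writeOmicsMatrix(profiles[[m]], p)
    paths[[m]] <- p
  }
  rp <- file.path(dir, "responses.csv")
  writeResponseTable(tab$responses, rp)
  paths$responses <- rp
  tp <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(
    drugMeans = as.list(tab$truth@drugMeans),
    noiseSD = tab$truth@noiseSD,
    cellEffectSD = config@cellEffectSD,
    nInformative = config@nInformative), tp, auto_unbox = TRUE, digits = NA)
  paths$truth <- tp
  invisible(paths)
}
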