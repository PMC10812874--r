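#' @include AllClasses.R
NULL

#' Replace missing entries with zeros
#'
#' Sets every masked entry to 0 and clears the missing mask, the treatment
#' applied to proteomics abundances assumed to be below the limit of
#' quantitation. Unmasked entries are untouched; a matrix without missing
#' entries is returned unchanged.
#'
#' @param m an [OmicsMatrix-class].
#' @return An [OmicsMatrix-class] with no missing entries.
#' @examples
#' v <- matrix(c(1, NA, NA, 4), 2, 2,
#'             dimnames = list(c("c1", "c2"), c("p1", "p2")))
#' m <- omicsMatrix(v, "proteomics", missingMask = is.na(v))
#' omicsValues(imputeMissingZero(m))
#' @export
imputeMissingZero <- function(m) {
  mask <- missingMask(m)
  if (is.null(mask)) return(m)
  v <- omicsValues(m)
  v[mask] <- 0
  omicsMatrix(v, modality(m))
}

#' Standard-scale each cell line's profile
#'
#' Scales every row (cell line) to mean 0 and population standard
#' deviation 1 (divide-by-n convention), the per-sample normalization
#' applied to phosphoproteomics profiles to correct batch effects.
#' Zero-variance rows map to all zeros rather than erroring, so degenerate
#' inputs flow through.
#'
#' @param m an [OmicsMatrix-class] with at least 2 features and no missing
#'   entries (impute first).
#' @return A row-standardized [OmicsMatrix-class].
#' @examples
#' v <- matrix(c(1, 2, 3), 1, 3, dimnames = list("c1", c("a", "b", "c")))
#' omicsValues(scalePerCellLine(omicsMatrix(rbind(v, v + 1), "phospho")))
#' @export
scalePerCellLine <- function(m) {
  v <- omicsValues(m)
  if (ncol(v) < 2L)
    stop("per-cell-line scaling needs at least 2 features")
  if (!is.null(missingMask(m)))
    stop("matrix has missing entries; impute before scaling")
  mu <- rowMeans(v)
  cen <- v - mu
  sdp <- sqrt(rowMeans(cen^2))  # population SD
  zero <- sdp < .EPS_VAR
  sdp[zero] <- 1
  out <- cen / sdp
  out[zero, ] <- 0
  omicsMatrix(out, modality(m))
}

#' Landmark-gene feature selection
#'
#' Restricts a modality's features to those driven by the landmark gene
#' panel, preserving input column order:
#' \itemize{
#'   \item \code{rnaseq}: genes in the landmark panel;
#'   \item \code{proteomics}: proteins coded for by a landmark gene
#'     (via \code{geneToProtein});
#'   \item \code{phospho}: phosphopeptides whose host protein is coded for
#'     by a landmark gene (via \code{peptideToProtein} and
#'     \code{geneToProtein}) \emph{and} that are a target of one of the
#'     landmark genes (via \code{geneTargets}).
#' }
#'
#' @param m an [OmicsMatrix-class] with modality \code{"rnaseq"},
#'   \code{"proteomics"} or \code{"phospho"}.
#' @param fmap a [FeatureMap-class].
#' @return The column-restricted [OmicsMatrix-class].
#' @export
selectLandmarkFeatures <- function(m, fmap) {
  mod <- modality(m)
  if (!mod %in% c("rnaseq", "proteomics", "phospho"))
    stop("landmark selection is defined for rnaseq, proteomics and phospho, ",
         "not '", mod, "'")
  feats <- featureIds(m)
  lm <- fmap@landmarkGenes
  keep <- switch(mod,
    rnaseq = feats %in% lm,
    proteomics = {
      lmProt <- fmap@geneToProtein$protein[fmap@geneToProtein$gene %in% lm]
      feats %in% lmProt
    },
    phospho = {
      lmProt <- fmap@geneToProtein$protein[fmap@geneToProtein$gene %in% lm]
      pep2prot <- stats::setNames(fmap@peptideToProtein$protein,
                                  fmap@peptideToProtein$peptide)
      targets <- fmap@geneTargets$peptide[fmap@geneTargets$gene %in% lm]
      onLmProtein <- !is.na(pep2prot[feats]) & pep2prot[feats] %in% lmProt
      onLmProtein & feats %in% targets
    })
  if (!any(keep))
    stop("no ", mod, " features survive landmark selection; ",
         "check that the mapping tables use the same identifiers as the matrix")
  v <- omicsValues(m)[, keep, drop = FALSE]
  mask <- missingMask(m)
  omicsMatrix(v, mod,
              missingMask = if (!is.null(mask)) mask[, keep, drop = FALSE])
}

#' Randomly subsample features
#'
#' Keeps exactly \code{k} columns chosen uniformly without replacement
#' (seeded); surviving columns retain their input order. Used to test
#' whether a modality's advantage stems merely from having more features.
#'
#' @param m an [OmicsMatrix-class].
#' @param k number of features to keep, \code{<= ncol}.
#' @param seed integer seed.
#' @return The column-subsampled [OmicsMatrix-class].
#' @export
subsampleFeatures <- function(m, k, seed) {
  p <- length(featureIds(m))
  if (k > p)
    stop("cannot subsample ", k, " features from ", p)
  set.seed(seed)
  idx <- sort(sample.int(p, k))
  v <- omicsValues(m)[, idx, drop = FALSE]
  mask <- missingMask(m)
  omicsMatrix(v, modality(m),
              missingMask = if (!is.null(mask)) mask[, idx, drop = FALSE])
}

#' Collapse phosphopeptides to one site per protein
#'
#' For each protein, keeps the single phosphopeptide with the highest
#' variance across cell lines (ties broken by input column order); all
#' other sites on that protein are dropped. Proteins represented by a
#' single peptide pass through unchanged.
#'
#' @param m a phospho [OmicsMatrix-class] with no missing entries.
#' @param fmap a [FeatureMap-class] whose \code{peptideToProtein} covers
#'   every feature of \code{m}.
#' @return The collapsed [OmicsMatrix-class], one column per protein.
#' @export
collapseOneSitePerProtein <- function(m, fmap) {
  if (!identical(modality(m), "phospho"))
    stop("one-site-per-protein collapsing applies to the phospho modality")
  feats <- featureIds(m)
  pep2prot <- stats::setNames(fmap@peptideToProtein$protein,
                              fmap@peptideToProtein$peptide)
  prot <- pep2prot[feats]
  if (anyNA(prot))
    stop("peptides missing from peptideToProtein: ",
         paste(feats[is.na(prot)], collapse = ", "))
  v <- omicsValues(m)
  vars <- apply(v, 2L, stats::var)
  keep <- logical(length(feats))
  for (pr in unique(prot)) {
    cols <- which(prot == pr)
    keep[cols[which.max(vars[cols])]] <- TRUE
  }
  omicsMatrix(v[, keep, drop = FALSE], "phospho")
}

#' One-call preprocessing for a modality
#'
#' Applies the fixed preprocessing order: zero-imputation of missing
#' entries, then (for phospho, or on request) per-cell-line standard
#' scaling, then landmark feature selection when a map is supplied.
#' Scaling precedes selection because per-sample normalization is defined
#' on the full downloaded profile.
#'
#' @param m an [OmicsMatrix-class].
#' @param fmap optional [FeatureMap-class]; when given, landmark selection
#'   runs last.
#' @param scaleRows apply per-cell-line scaling; defaults to \code{TRUE}
#'   for the phospho modality.
#' @return The preprocessed [OmicsMatrix-class].
#' @export
prepOmics <- function(m, fmap = NULL,
                      scaleRows = identical(modality(m), "phospho")) {
  m <- imputeMissingZero(m)
  if (scaleRows) m <- scalePerCellLine(m)
  if (!is.null(fmap)) m <- selectLandmarkFeatures(m, fmap)
  m
}
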