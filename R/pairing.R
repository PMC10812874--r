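#' @include AllClasses.R
NULL

#' One-hot encode drug identifiers
#'
#' Encodes drugs against a fixed, ordered vocabulary so train and test
#' splits share one encoding (the vocabulary is fixed from the full
#' response table before splitting; unseen-drug handling lives in the
#' benchmark's prediction fallback, not the encoder).
#'
#' @param drugIds character vector of drug ids to encode.
#' @param vocabulary ordered character vector; the one-hot column space.
#' @return numeric matrix, \code{length(drugIds)} x
#'   \code{length(vocabulary)}, each row summing to 1, columns named by
#'   the vocabulary.
#' @examples
#' oneHotEncodeDrugs("dB", c("dA", "dB", "dC"))
#' @export
oneHotEncodeDrugs <- function(drugIds, vocabulary) {
  pos <- match(drugIds, vocabulary)
  if (anyNA(pos))
    stop("drugs absent from the vocabulary: ",
         paste(unique(drugIds[is.na(pos)]), collapse = ", "))
  out <- matrix(0, nrow = length(drugIds), ncol = length(vocabulary),
                dimnames = list(NULL, vocabulary))
  out[cbind(seq_along(drugIds), pos)] <- 1
  out
}

#' Drop cell lines without any measured response
#'
#' Removes, from every modality identically, cell lines that contribute no
#' row to the response table; profiles without targets cannot enter the
#' supervised dataset.
#'
#' @param omics named list of [OmicsMatrix-class] objects.
#' @param responses response data.frame with a \code{cell_line} column.
#' @return The filtered list of [OmicsMatrix-class] objects (warns if
#'   empty).
#' @export
dropCellLinesWithoutTargets <- function(omics, responses) {
  withTargets <- unique(responses$cell_line)
  lapply(omics, function(m) {
    keep <- cellLineIds(m) %in% withTargets
    if (!any(keep))
      warning("no cell line of modality '", modality(m),
              "' has a measured response")
    v <- omicsValues(m)[keep, , drop = FALSE]
    mask <- missingMask(m)
    omicsMatrix(v, modality(m),
                missingMask = if (!is.null(mask)) mask[keep, , drop = FALSE])
  })
}

#' Intersect cell-line sets across modalities
#'
#' @param matrices list of [OmicsMatrix-class] objects (at least one).
#' @return sorted character vector: cell lines present in every matrix.
#' @examples
#' # with matrices covering {c1,c2,c3} and {c2,c3,c4}: c("c2", "c3")
#' @export
intersectCellLineSets <- function(matrices) {
  if (!length(matrices)) stop("need at least one omics matrix")
  sets <- lapply(matrices, cellLineIds)
  sort(Reduce(intersect, sets))
}

#' Build the paired (cell profile, drug one-hot, response) dataset
#'
#' Realizes the supervised dataset: one triple per response row, the cell
#' line's profile vector repeated across all of its drugs, drugs one-hot
#' encoded against the vocabulary. Row order is deterministic (cell line,
#' then drug, lexicographic).
#'
#' @param omics an [OmicsMatrix-class] (preprocessed; no missing entries
#'   expected downstream).
#' @param responses response data.frame (\code{cell_line}, \code{drug},
#'   \code{ln_ic50}); rows outside \code{cellLines} are dropped.
#' @param cellLines cell lines to include; must all carry a profile.
#' @param vocabulary drug one-hot space; defaults to the sorted distinct
#'   drugs of \code{responses}. Fix it from the full table before
#'   splitting so all splits share an encoding.
#' @return A [PairedDataset-class].
#' @export
buildPairs <- function(omics, responses, cellLines = cellLineIds(omics),
                       vocabulary = sort(unique(responses$drug))) {
  absent <- setdiff(cellLines, cellLineIds(omics))
  if (length(absent))
    stop("responses reference cell lines without omics profiles: ",
         paste(absent, collapse = ", "))
  resp <- responses[responses$cell_line %in% cellLines, , drop = FALSE]
  resp <- resp[order(resp$cell_line, resp$drug), , drop = FALSE]
  rownames(resp) <- NULL
  cellInputs <- omicsValues(omics)[match(resp$cell_line, cellLineIds(omics)),
                                   , drop = FALSE]
  rownames(cellInputs) <- NULL
  new("PairedDataset",
      cellInputs = cellInputs,
      drugInputs = oneHotEncodeDrugs(resp$drug, vocabulary),
      targets = resp$ln_ic50,
      pairIndex = resp[c("cell_line", "drug")],
      drugVocabulary = vocabulary)
}

#' Subset a paired dataset by row indices or cell lines
#'
#' @param pd a [PairedDataset-class].
#' @param idx integer row (pair) indices; mutually exclusive with
#'   \code{cells}.
#' @param cells character cell-line ids; selects all pairs of those cells.
#' @return The row-subset [PairedDataset-class] (vocabulary unchanged).
#' @export
subsetPairs <- function(pd, idx = NULL, cells = NULL) {
  if (is.null(idx) == is.null(cells))
    stop("supply exactly one of 'idx' or 'cells'")
  if (!is.null(cells)) idx <- which(pd@pairIndex$cell_line %in% cells)
  pi <- pd@pairIndex[idx, , drop = FALSE]
  rownames(pi) <- NULL
  new("PairedDataset",
      cellInputs = pd@cellInputs[idx, , drop = FALSE],
      drugInputs = pd@drugInputs[idx, , drop = FALSE],
      targets = pd@targets[idx],
      pairIndex = pi,
      drugVocabulary = pd@drugVocabulary)
}

#' Pair indices belonging to a set of cell lines
#'
#' @param pd a [PairedDataset-class].
#' @param cells character cell-line ids.
#' @return integer vector of pair (row) indices.
#' @export
pairsForCells <- function(pd, cells) {
  which(pd@pairIndex$cell_line %in% cells)
}
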