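#' @include AllClasses.R
NULL

#' Cancer-blind train/validation/test split
#'
#' Shuffles the cell lines by seed and partitions them by the given
#' fractions, so that no cell line occupies more than one set; every pair
#' of a cell line inherits its partition. Validation and test sizes are
#' rounded; the remainder goes to training.
#'
#' @param cellLines ordered character vector of cell-line ids (>= 3).
#' @param fractions length-3 positive numeric (train, val, test) summing
#'   to 1.
#' @param seed integer shuffle seed.
#' @param repeatIndex repeat label stored on the split (default 0).
#' @return A [CancerBlindSplit-class].
#' @examples
#' s <- cancerBlindSplit(sprintf("c%02d", 1:10), c(0.8, 0.1, 0.1), seed = 1)
#' lengths(list(trainCells(s), valCells(s), testCells(s)))  # 8 1 1
#' @export
cancerBlindSplit <- function(cellLines, fractions = c(0.8, 0.1, 0.1),
                             seed = 1L, repeatIndex = 0L) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three positive numbers summing to 1")
  n <- length(cellLines)
  if (n < 3L)
    stop("need at least as many cell lines (", n, ") as partitions (3)")
  set.seed(seed)
  perm <- sample(cellLines)
  nVal <- max(1L, round(n * fractions[2L]))
  nTest <- max(1L, round(n * fractions[3L]))
  if (nVal + nTest >= n)
    stop("fractions leave no training cell lines for n = ", n)
  new("CancerBlindSplit",
      valCells = perm[seq_len(nVal)],
      testCells = perm[nVal + seq_len(nTest)],
      trainCells = perm[(nVal + nTest + 1L):n],
      repeatIndex = as.integer(repeatIndex), seed = as.integer(seed))
}

#' Repeated cancer-blind splits
#'
#' Repeats the shuffle-then-partition process with distinct derived seeds;
#' the default of 30 repeats matches the averaging protocol used for the
#' learning curves.
#'
#' @param cellLines ordered character vector of cell-line ids.
#' @param fractions (train, val, test) fractions.
#' @param nRepeats number of repeats (>= 1), default 30.
#' @param baseSeed integer; repeat r uses a seed derived from
#'   \code{(baseSeed, r)}.
#' @return list of [CancerBlindSplit-class], \code{repeatIndex} 0 ..
#'   \code{nRepeats - 1}.
#' @export
repeatSplits <- function(cellLines, fractions = c(0.8, 0.1, 0.1),
                         nRepeats = 30L, baseSeed = 1L) {
  if (nRepeats < 1L) stop("nRepeats must be >= 1")
  lapply(seq_len(nRepeats) - 1L, function(r) {
    cancerBlindSplit(cellLines, fractions,
                     seed = if (r == 0L) baseSeed
                            else deriveSeed(baseSeed, 300L + r),
                     repeatIndex = r)
  })
}

#' Log-spaced nested training-subset schedule
#'
#' Splits the training pairs into K nested subsets of log-spaced sizes
#' n_1 < ... < n_K with n_K the full training size. Subsets are prefixes
#' of one seeded shuffle, so differences between adjacent learning-curve
#' points reflect added data rather than resampling. In \code{"cells"}
#' mode the sizes count whole cell lines and each subset contains all
#' pairs of a prefix of shuffled cell lines.
#'
#' @param trainPairs integer vector of training pair indices.
#' @param k number of sizes (>= 2), default 8.
#' @param minSize smallest subset size (pairs, or cells in \code{"cells"}
#'   mode), default 32.
#' @param seed shuffle seed.
#' @param mode \code{"pairs"} (default) or \code{"cells"}.
#' @param pairCells character vector parallel to \code{trainPairs} giving
#'   each pair's cell line; required in \code{"cells"} mode.
#' @param sizes optional explicit increasing sizes (overrides the
#'   log-spacing); used to share one size grid across repeats whose full
#'   training sizes differ slightly.
#' @return A [SubsetSchedule-class].
#' @examples
#' s <- makeSubsetSchedule(1:1000, k = 3, minSize = 10, seed = 1)
#' s@sizes  # 10 100 1000
#' @export
makeSubsetSchedule <- function(trainPairs, k = 8L, minSize = 32L, seed = 1L,
                               mode = c("pairs", "cells"),
                               pairCells = NULL, sizes = NULL) {
  mode <- match.arg(mode)
  if (k < 2L) stop("k must be >= 2")
  if (minSize < 1L) stop("minSize must be >= 1")
  full <- if (mode == "pairs") length(trainPairs)
          else length(unique(pairCells))
  if (mode == "cells" && (is.null(pairCells) ||
                          length(pairCells) != length(trainPairs)))
    stop("'cells' mode needs pairCells parallel to trainPairs")
  if (full < minSize)
    stop("full size ", full, " is below minSize ", minSize)
  if (is.null(sizes)) {
    sizes <- round(exp(seq(log(minSize), log(full), length.out = k)))
    sizes[1L] <- minSize
    sizes[k] <- full
  } else {
    if (max(sizes) > full)
      stop("requested size ", max(sizes), " exceeds full size ", full)
  }
  if (any(diff(sizes) <= 0))
    stop("log spacing infeasible: ", k, " distinct sizes do not fit between ",
         minSize, " and ", full)
  set.seed(seed)
  if (mode == "pairs") {
    perm <- sample(trainPairs)
    subsets <- lapply(sizes, function(s) perm[seq_len(s)])
  } else {
    cellPerm <- sample(unique(pairCells))
    subsets <- lapply(sizes, function(s) {
      trainPairs[pairCells %in% cellPerm[seq_len(s)]]
    })
  }
  new("SubsetSchedule", sizes = as.integer(sizes), subsets = subsets,
      mode = mode, seed = as.integer(seed))
}

#' Serialize splits to a JSON manifest
#'
#' Writes seed, fractions and per-repeat cell-line assignments so a run
#' can be audited and reproduced exactly.
#'
#' @param splits list of [CancerBlindSplit-class].
#' @param fractions the (train, val, test) fractions used.
#' @param path output JSON path.
#' @return invisibly, \code{path}.
#' @export
writeSplitManifest <- function(splits, fractions, path) {
  jsonlite::write_json(list(
    fractions = fractions,
    repeats = lapply(splits, function(s) list(
      repeat_index = s@repeatIndex, seed = s@seed,
      train = s@trainCells, val = s@valCells, test = s@testCells))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
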