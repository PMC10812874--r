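#' @include AllClasses.R
NULL

# pick the delimiter: explicit > tab-if-present > comma
.guessSep <- function(path, sep) {
  if (!is.null(sep)) return(sep)
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a delimited omics matrix
#'
#' Parses a delimited file with one header row and one identifier column
#' into an [OmicsMatrix-class]. Empty cells are recorded in the missing
#' mask (values set to \code{NA}), never silently zeroed; use
#' [imputeMissingZero()] for the zero-replacement step. Orientation is
#' configurable: \code{"cells-by-features"} (default) or
#' \code{"features-by-cells"} (file is transposed on read).
#'
#' @param path file path.
#' @param modality modality name to stamp on the result.
#' @param sep field delimiter; \code{NULL} auto-detects tab vs comma.
#' @param orientation matrix orientation in the file.
#' @return An [OmicsMatrix-class].
#' @seealso [writeOmicsMatrix()]
#' @export
readOmicsMatrix <- function(path, modality,
                            sep = NULL,
                            orientation = c("cells-by-features",
                                            "features-by-cells")) {
  orientation <- match.arg(orientation)
  sep <- .guessSep(path, sep)
  nf <- utils::count.fields(path, sep = sep, quote = "\"",
                            blank.lines.skip = FALSE)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged row in '", path, "': line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1L])
  }
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, colClasses = NULL,
                          na.strings = c("", "NA"))
  ids <- as.character(dt[[1L]])
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  if (orientation == "features-by-cells") vals <- t(vals)
  dup <- function(x, what) {
    d <- unique(x[duplicated(x)])
    if (length(d)) stop("duplicate ", what, " ids in '", path, "': ",
                        paste(d, collapse = ", "))
  }
  dup(rownames(vals), "cell-line")
  dup(colnames(vals), "feature")
  mask <- is.na(vals)
  message(sprintf("read %s: %d cell lines x %d features (%d missing) from %s",
                  modality, nrow(vals), ncol(vals), sum(mask), path))
  omicsMatrix(vals, modality, missingMask = if (any(mask)) mask else NULL)
}

#' Write an omics matrix to a delimited file
#'
#' Masked (missing) entries are written as empty cells so a write-then-read
#' round trip preserves the mask.
#'
#' @param m an [OmicsMatrix-class].
#' @param path output file path.
#' @param sep field delimiter (default tab).
#' @return invisibly, \code{path}.
#' @export
writeOmicsMatrix <- function(m, path, sep = "\t") {
  v <- omicsValues(m)
  df <- data.frame(id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a long-format drug response table
#'
#' Expects columns \code{cell_line}, \code{drug}, \code{ln_ic50} (natural
#' logarithm of IC50, the convention used throughout). Duplicate
#' (cell line, drug) pairs and non-finite responses are rejected.
#'
#' @param path CSV/TSV file path.
#' @param sep delimiter; \code{NULL} auto-detects.
#' @return data.frame with the three columns above.
#' @export
readResponseTable <- function(path, sep = NULL) {
  sep <- .guessSep(path, sep)
  df <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  need <- c("cell_line", "drug", "ln_ic50")
  if (!all(need %in% names(df)))
    stop("response table must have columns ", paste(need, collapse = ", "))
  df <- df[need]
  df$cell_line <- as.character(df$cell_line)
  df$drug <- as.character(df$drug)
  key <- paste(df$cell_line, df$drug, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (cell_line, drug) pairs in '", path, "'")
  if (any(!is.finite(df$ln_ic50)))
    stop("non-finite ln_ic50 values in '", path, "'")
  message(sprintf("read %d response rows (%d cell lines, %d drugs) from %s",
                  nrow(df), length(unique(df$cell_line)),
                  length(unique(df$drug)), path))
  df
}

#' Write a long-format drug response table
#'
#' @param responses data.frame with columns \code{cell_line}, \code{drug},
#'   \code{ln_ic50}.
#' @param path output CSV path.
#' @param sep delimiter (default comma).
#' @return invisibly, \code{path}.
#' @export
writeResponseTable <- function(responses, path, sep = ",") {
  utils::write.table(responses[c("cell_line", "drug", "ln_ic50")], path,
                     sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read landmark and mapping tables into a FeatureMap
#'
#' All four inputs are plain TSVs: a one-column gene list and three
#' two-column mapping tables (\code{gene,protein}; \code{gene,peptide};
#' \code{peptide,protein}). Mapping arguments are optional; absent maps
#' default to empty (sufficient for RNA-seq-only selection).
#'
#' @param landmarkPath one-column TSV of landmark gene ids (header
#'   \code{gene}).
#' @param geneProteinPath optional TSV with header \code{gene,protein}.
#' @param geneTargetPath optional TSV with header \code{gene,peptide}.
#' @param peptideProteinPath optional TSV with header
#'   \code{peptide,protein}.
#' @return A [FeatureMap-class].
#' @export
readFeatureMap <- function(landmarkPath, geneProteinPath = NULL,
                           geneTargetPath = NULL,
                           peptideProteinPath = NULL) {
  rd <- function(p) data.table::fread(p, header = TRUE, data.table = FALSE,
                                      colClasses = "character")
  lm <- rd(landmarkPath)
  if (!"gene" %in% names(lm)) stop("landmark file needs a 'gene' column")
  args <- list(landmarkGenes = lm$gene)
  if (!is.null(geneProteinPath)) args$geneToProtein <- rd(geneProteinPath)
  if (!is.null(geneTargetPath)) args$geneTargets <- rd(geneTargetPath)
  if (!is.null(peptideProteinPath))
    args$peptideToProtein <- rd(peptideProteinPath)
  do.call(featureMap, args)
}
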