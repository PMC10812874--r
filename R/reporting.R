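#' @include AllClasses.R AllGenerics.R
NULL

#' Average ranking of conditions across splits
#'
#' For every split, conditions (modality/learner combinations) are ranked
#' by ascending test MSE (1 = best; exact ties share midranks); the
#' per-condition mean rank across splits summarizes which condition wins
#' most consistently. A condition beating another on 24 of 30 splits
#' yields mean ranks 1.2 and 1.8.
#'
#' @param table long data.frame with columns \code{split},
#'   \code{condition}, \code{mse} (one row per split x condition, all
#'   cells present).
#' @param conditions optional character subset of conditions to rank
#'   against each other.
#' @return named numeric vector of mean ranks.
#' @export
averageRanking <- function(table, conditions = NULL) {
  if (!all(c("split", "condition", "mse") %in% names(table)))
    stop("table needs columns split, condition, mse")
  if (!is.null(conditions))
    table <- table[table$condition %in% conditions, , drop = FALSE]
  conds <- sort(unique(table$condition))
  if (length(conds) < 2L) stop("ranking needs at least 2 conditions")
  wide <- stats::xtabs(mse ~ split + condition, data = table)
  if (any(table(table$split, table$condition) != 1L))
    stop("every (split, condition) cell must be present exactly once")
  ranks <- t(apply(wide, 1L, rank, ties.method = "average"))
  colMeans(ranks)[conds]
}

#' Percentage reduction in MSE
#'
#' \code{100 * (reference - comparison) / reference}: positive when the
#' comparison condition has the lower error.
#'
#' @param reference reference MSE (> 0).
#' @param comparison comparison MSE.
#' @return percentage reduction (vectorized).
#' @examples
#' percentMseReduction(2, 1)  # 50
#' @export
percentMseReduction <- function(reference, comparison) {
  if (any(reference <= 0)) stop("reference MSE must be positive")
  100 * (reference - comparison) / reference
}

#' Per-drug error analysis
#'
#' Groups squared test errors by drug: per-drug MSE, pair count and the
#' SD of the drug's test targets. Drugs with fewer than 2 test pairs have
#' undefined target SD and are flagged.
#'
#' @param model a fitted model ([TrainedModel-class] or
#'   [BenchmarkModel-class]).
#' @param test a non-empty [PairedDataset-class].
#' @return data.frame with columns \code{drug}, \code{mse}, \code{n},
#'   \code{target_sd}, \code{flagged}.
#' @export
perDrugError <- function(model, test) {
  if (!length(test@targets)) stop("empty test set")
  pred <- predictResponse(model, test)
  sq <- (pred - test@targets)^2
  drug <- test@pairIndex$drug
  drugs <- sort(unique(drug))
  out <- data.frame(
    drug = drugs,
    mse = as.numeric(tapply(sq, drug, mean)[drugs]),
    n = as.integer(table(drug)[drugs]),
    target_sd = as.numeric(tapply(test@targets, drug, stats::sd)[drugs]))
  out$flagged <- out$n < 2L
  rownames(out) <- NULL
  out
}

#' Association between per-drug error and response variability
#'
#' Rank correlation (Spearman, midranks on ties) between per-drug MSE and
#' per-drug target SD, with a one-sided permutation p-value for positive
#' association: drugs with more variable ln(IC50) are expected to be
#' harder to predict.
#'
#' @param perDrug data.frame from [perDrugError()] (needs >= 5 usable
#'   drugs after dropping flagged ones).
#' @param nPermutations number of permutations (>= 999).
#' @param seed integer seed for the permutations.
#' @return list with \code{rho}, \code{p_value}, \code{n_drugs},
#'   \code{degenerate} (TRUE when either variable is constant, in which
#'   case \code{rho = 0} and \code{p_value = 1}).
#' @export
drugVariabilityAssociation <- function(perDrug, nPermutations = 999L,
                                       seed = 1L) {
  use <- perDrug[!perDrug$flagged & is.finite(perDrug$target_sd), ,
                 drop = FALSE]
  if (nrow(use) < 5L)
    stop("association needs at least 5 drugs with >= 2 test pairs")
  x <- use$mse
  y <- use$target_sd
  if (stats::sd(x) < .EPS_VAR || stats::sd(y) < .EPS_VAR)
    return(list(rho = 0, p_value = 1, n_drugs = nrow(use),
                degenerate = TRUE))
  rho <- stats::cor(x, y, method = "spearman")
  set.seed(seed)
  perm <- vapply(seq_len(nPermutations), function(i)
    stats::cor(x, sample(y), method = "spearman"), numeric(1))
  p <- (1 + sum(perm >= rho)) / (nPermutations + 1)
  list(rho = rho, p_value = p, n_drugs = nrow(use), degenerate = FALSE)
}

#' Normality summary of model residuals
#'
#' Anderson-Darling normality test per condition, reported (statistic and
#' p-value) but never used to gate results. Constant residual vectors are
#' flagged as degenerate with no p-value.
#'
#' @param residuals named list of numeric residual vectors (each
#'   >= 20 values).
#' @return data.frame with columns \code{condition}, \code{n},
#'   \code{statistic}, \code{p_value}, \code{degenerate}.
#' @export
errorNormalitySummary <- function(residuals) {
  if (!length(residuals) || is.null(names(residuals)))
    stop("residuals must be a named list")
  rows <- lapply(names(residuals), function(nm) {
    r <- residuals[[nm]]
    if (length(r) < 20L)
      stop("condition '", nm, "' has fewer than 20 residuals")
    if (stats::sd(r) < .EPS_VAR)
      return(data.frame(condition = nm, n = length(r),
                        statistic = NA_real_, p_value = NA_real_,
                        degenerate = TRUE))
    t <- nortest::ad.test(r)
    data.frame(condition = nm, n = length(r),
               statistic = unname(t$statistic),
               p_value = unname(t$p.value), degenerate = FALSE)
  })
  do.call(rbind, rows)
}
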