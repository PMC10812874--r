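#' @include AllClasses.R AllGenerics.R
NULL

#' Assemble an averaged learning curve
#'
#' Averages the per-repeat generalization errors at each training-set size
#' into a single curve: mean error per size, with standard errors
#' (sample SD across repeats divided by the square root of the repeat
#' count).
#'
#' @param perRepeatError numeric matrix, repeats x sizes, no missing
#'   cells.
#' @param sizes integer training-set sizes, one per column.
#' @param modality,learner condition labels.
#' @return A [LearningCurve-class].
#' @examples
#' assembleCurve(rbind(c(2, 1), c(3, 1.5)), c(10, 100), "rnaseq", "gbt")
#' @export
assembleCurve <- function(perRepeatError, sizes, modality = "",
                          learner = "") {
  perRepeatError <- as.matrix(perRepeatError)
  if (anyNA(perRepeatError)) stop("perRepeatError has missing cells")
  if (ncol(perRepeatError) != length(sizes))
    stop("one column per size required")
  mean_ <- colMeans(perRepeatError)
  se <- if (nrow(perRepeatError) > 1L)
    apply(perRepeatError, 2L, stats::sd) / sqrt(nrow(perRepeatError))
  else rep(0, ncol(perRepeatError))
  new("LearningCurve", sizes = as.integer(sizes), meanError = mean_,
      stdErr = se, perRepeatError = perRepeatError,
      modality = modality, learner = learner)
}

#' Fit the power law eps(n) = alpha * n^beta
#'
#' Least-squares line in (log n, log mean error) over a window of size
#' indices: \code{beta} is the slope and \code{alpha} the exponentiated
#' intercept. The default window drops the smallest and largest sizes,
#' where curves typically leave the power-law region.
#'
#' @param curve a [LearningCurve-class].
#' @param window integer index range (first, last) into the curve's
#'   sizes; default interior sizes (2 .. K-1) when K >= 4, else the full
#'   range.
#' @return A [PowerLawFit-class].
#' @examples
#' cv <- assembleCurve(matrix(2 * c(10, 100, 1000)^-0.3, 1), c(10, 100, 1000))
#' fitPowerLaw(cv, c(1, 3))  # alpha 2, beta -0.3
#' @export
fitPowerLaw <- function(curve, window = NULL) {
  k <- length(curve@sizes)
  if (is.null(window))
    window <- if (k >= 4L) c(2L, k - 1L) else c(1L, k)
  window <- as.integer(window)
  idx <- window[1L]:window[2L]
  if (length(idx) < 2L) stop("fit window must span at least 2 sizes")
  if (window[1L] < 1L || window[2L] > k) stop("fit window outside the curve")
  eps <- curve@meanError[idx]
  if (any(eps <= 0))
    stop("non-positive mean error inside the fit window; ",
         "the log-log fit is undefined")
  fit <- stats::lm(log(eps) ~ log(curve@sizes[idx]))
  new("PowerLawFit", alpha = exp(unname(stats::coef(fit)[1L])),
      beta = unname(stats::coef(fit)[2L]), fitWindow = window,
      residualSum = sum(stats::residuals(fit)^2))
}

#' Classify learning-curve regions
#'
#' Labels each size as \code{small_data}, \code{power_law} or
#' \code{diminishing_returns} from local log-log slopes. The contiguous
#' run of steep segments (local slope magnitude at least
#' \code{dimFraction} of the steepest, and within \code{slopeTolerance}
#' relative of the run's fitted exponent) forms the power-law region;
#' flat stretches before it are the small-data region and flat stretches
#' after it the diminishing-returns region.
#'
#' @param curve a [LearningCurve-class] with >= 4 sizes.
#' @param slopeTolerance relative tolerance for membership of the
#'   power-law run (default 0.25).
#' @param dimFraction slope-magnitude fraction below which a segment
#'   counts as flat (default 0.5).
#' @return character vector of per-size labels.
#' @export
classifyRegions <- function(curve, slopeTolerance = 0.25,
                            dimFraction = 0.5) {
  k <- length(curve@sizes)
  if (k < 4L) stop("region classification needs at least 4 sizes")
  if (any(curve@meanError <= 0))
    stop("non-positive mean errors; log-log slopes are undefined")
  ls <- log(as.numeric(curve@sizes))
  le <- log(curve@meanError)
  seg <- diff(le) / diff(ls)               # one slope per adjacent pair
  smax <- max(abs(seg))
  if (smax < 1e-12) return(rep("power_law", k))  # constant curve, beta = 0
  steep <- abs(seg) >= dimFraction * smax
  # contiguous run of steep segments containing the steepest one
  core <- which.max(abs(seg))
  lo <- core
  while (lo > 1L && steep[lo - 1L]) lo <- lo - 1L
  hi <- core
  while (hi < length(seg) && steep[hi + 1L]) hi <- hi + 1L
  beta <- mean(seg[lo:hi])
  # extend the run over adjacent segments whose slope matches beta
  while (lo > 1L && abs(seg[lo - 1L] - beta) <= slopeTolerance * abs(beta))
    lo <- lo - 1L
  while (hi < length(seg) &&
         abs(seg[hi + 1L] - beta) <= slopeTolerance * abs(beta))
    hi <- hi + 1L
  labels <- rep("power_law", k)
  if (lo > 1L) labels[seq_len(lo - 1L)] <- "small_data"
  if (hi + 1L < k) labels[(hi + 2L):k] <- "diminishing_returns"
  labels
}

#' Extrapolate a fitted power law
#'
#' Evaluates \eqn{\alpha n^\beta} at a target size. When the target lies
#' beyond the sizes used for the fit the result carries attribute
#' \code{extrapolated = TRUE}; such projections assume the power-law
#' region continues, which cannot be guaranteed.
#'
#' @param fit a [PowerLawFit-class].
#' @param nTarget positive target training-set size.
#' @param observedSizes optional integer sizes the fit was computed from;
#'   used to set the extrapolation flag.
#' @return predicted error (numeric scalar, possibly with attribute
#'   \code{extrapolated}).
#' @examples
#' f <- new("PowerLawFit", alpha = 2, beta = -0.3, fitWindow = c(1L, 3L),
#'          residualSum = 0)
#' extrapolateError(f, 1000)  # ~0.2524
#' @export
extrapolateError <- function(fit, nTarget, observedSizes = NULL) {
  if (nTarget <= 0) stop("nTarget must be positive")
  out <- fit@alpha * nTarget^fit@beta
  if (!is.null(observedSizes) && nTarget > max(observedSizes))
    attr(out, "extrapolated") <- TRUE
  out
}

#' Locate a persistent crossing between two learning curves
#'
#' Finds the smallest grid size at which the difference (b - a) changes
#' sign and keeps the new sign through every larger grid size; transient
#' flips do not count. The crossing point is refined by linear
#' interpolation of the difference in log(n) between the bracketing grid
#' sizes.
#'
#' @param a,b [LearningCurve-class] objects on identical size grids.
#' @return \code{NULL} when no persistent sign change exists; otherwise a
#'   list with \code{size} (interpolated crossing), \code{interval}
#'   (bracketing grid sizes) and \code{index} (grid index after the
#'   crossing).
#' @export
findCrossing <- function(a, b) {
  if (!identical(a@sizes, b@sizes))
    stop("curves must share one size grid")
  d <- b@meanError - a@meanError
  s <- sign(d)
  k <- length(d)
  for (j in 2:k) {
    prev <- s[seq_len(j - 1L)]
    prev <- prev[prev != 0]
    if (!length(prev)) next
    if (s[j] != 0 && s[j] != prev[length(prev)] &&
        all(s[j:k] == s[j])) {
      lo <- log(as.numeric(a@sizes[j - 1L]))
      hi <- log(as.numeric(a@sizes[j]))
      t <- d[j - 1L] / (d[j - 1L] - d[j])
      return(list(size = exp(lo + t * (hi - lo)),
                  interval = c(a@sizes[j - 1L], a@sizes[j]),
                  index = j))
    }
  }
  NULL
}

#' Export a learning curve as tidy tables
#'
#' @param curve a [LearningCurve-class].
#' @return list of two data.frames: \code{tidy} (size, repeat, error) and
#'   \code{summary} (size, mean, stderr).
#' @export
curveTables <- function(curve) {
  m <- curve@perRepeatError
  tidy <- data.frame(
    modality = curve@modality, learner = curve@learner,
    size = rep(curve@sizes, each = nrow(m)),
    rep = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
    error = as.vector(m))
  summary <- data.frame(
    modality = curve@modality, learner = curve@learner,
    size = curve@sizes, mean = curve@meanError, stderr = curve@stdErr)
  list(tidy = tidy, summary = summary)
}
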