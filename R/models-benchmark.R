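#' @include AllClasses.R AllGenerics.R
NULL

#' Fit the drug-average benchmark
#'
#' The rule-based baseline: for each drug, the mean of that drug's
#' training-set ln(IC50) values; the global training mean is kept for the
#' unseen-drug fallback. No omics input is used, so beating this model is
#' the minimal evidence that molecular profiles add predictive value.
#'
#' @param train a non-empty [PairedDataset-class].
#' @return A [BenchmarkModel-class].
#' @examples
#' # with training targets {(c1,dA,2), (c2,dA,4), (c1,dB,1)}:
#' # per-drug means dA = 3, dB = 1; global mean 7/3
#' @export
fitDrugAverage <- function(train) {
  if (!length(train@targets)) stop("empty training set")
  means <- tapply(train@targets, train@pairIndex$drug, mean)
  new("BenchmarkModel",
      perDrugMean = stats::setNames(as.numeric(means), names(means)),
      globalMean = mean(train@targets))
}

#' Predict with the drug-average benchmark
#'
#' Returns the training mean of each pair's drug; for drugs absent from
#' training, the mean of all training ln(IC50) values. Predictions never
#' depend on the cell line.
#'
#' @param m a [BenchmarkModel-class].
#' @param pairs a [PairedDataset-class], or a character vector of drug ids.
#' @return numeric vector of predictions.
#' @export
predictDrugAverage <- function(m, pairs) {
  drugs <- if (is.character(pairs)) pairs else pairs@pairIndex$drug
  out <- m@perDrugMean[drugs]
  out[is.na(out)] <- m@globalMean
  unname(out)
}

#' @describeIn predictResponse benchmark prediction (drug means with
#'   global-mean fallback).
setMethod("predictResponse", "BenchmarkModel", function(object, newdata, ...) {
  predictDrugAverage(object, newdata)
})

# wrap a benchmark fit in the common TrainedModel interface
trainedBenchmark <- function(train, val) {
  bm <- fitDrugAverage(train)
  new("TrainedModel", kind = "benchmark", fit = bm, hyperparameters = list(),
      validationMSE = mse(predictDrugAverage(bm, val), val@targets),
      stoppedAt = 0L, trials = data.frame())
}

#' @describeIn predictResponse dispatch on the wrapped learner kind
#'   (benchmark, gradient-boosted trees, or feed-forward network).
setMethod("predictResponse", "TrainedModel", function(object, newdata, ...) {
  switch(object@kind,
    benchmark = predictDrugAverage(object@fit, newdata),
    gbt = predictGBT(object, newdata),
    nn = predictNN(object, newdata))
})
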