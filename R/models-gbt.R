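#' @include AllClasses.R AllGenerics.R
NULL

# concatenate the two input branches into one tabular design matrix
.designMatrix <- function(pd) {
  cbind(pd@cellInputs, pd@drugInputs)
}

#' Fit a gradient-boosted tree regressor
#'
#' Trains an XGBoost regressor with squared-error objective on the
#' concatenated (omics profile, drug one-hot) features, halting boosting
#' by early stopping on held-out validation MSE. Single-threaded and
#' seeded, so repeated fits are reproducible.
#'
#' @param train,val [PairedDataset-class] objects sharing feature
#'   dimensions.
#' @param params named list of hyperparameters; recognized:
#'   \code{learning_rate} (default 0.1), \code{max_depth} (6),
#'   \code{subsample} (1), \code{colsample_bytree} (1),
#'   \code{min_child_weight} (1), \code{nrounds} (cap, 2000),
#'   \code{early_stopping_rounds} (patience, 20).
#' @param seed integer seed.
#' @return A [TrainedModel-class] of kind \code{"gbt"}; its
#'   \code{validationMSE} is the MSE of the retained (best) iteration.
#' @export
fitGBT <- function(train, val, params = list(), seed = 1L) {
  p <- utils::modifyList(list(
    learning_rate = 0.1, max_depth = 6L, subsample = 1,
    colsample_bytree = 1, min_child_weight = 1,
    nrounds = 2000L, early_stopping_rounds = 20L), params)
  Xtr <- .designMatrix(train)
  Xva <- .designMatrix(val)
  if (any(!is.finite(Xtr)) || any(!is.finite(Xva)))
    stop("non-finite feature values; impute missing entries before fitting")
  set.seed(seed)
  dtr <- xgboost::xgb.DMatrix(Xtr, label = train@targets, nthread = 1)
  dva <- xgboost::xgb.DMatrix(Xva, label = val@targets, nthread = 1)
  booster <- xgboost::xgb.train(
    params = xgboost::xgb.params(
      objective = "reg:squarederror", eval_metric = "rmse", nthread = 1,
      learning_rate = p$learning_rate, max_depth = as.integer(p$max_depth),
      subsample = p$subsample, colsample_bytree = p$colsample_bytree,
      min_child_weight = p$min_child_weight, seed = as.integer(seed)),
    data = dtr, nrounds = as.integer(p$nrounds),
    evals = list(val = dva),
    early_stopping_rounds = as.integer(p$early_stopping_rounds),
    verbose = 0)
  best <- xgboost::xgb.attr(booster, "best_iteration")
  best <- if (is.null(best) || !length(best)) as.integer(p$nrounds)
          else as.integer(best)
  vmse <- mse(stats::predict(booster, dva), val@targets)
  new("TrainedModel", kind = "gbt", fit = booster, hyperparameters = p,
      validationMSE = vmse, stoppedAt = best, trials = data.frame())
}

# prediction path for a TrainedModel of kind "gbt"
predictGBT <- function(model, newdata) {
  X <- .designMatrix(newdata)
  stats::predict(model@fit, xgboost::xgb.DMatrix(X, nthread = 1))
}
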