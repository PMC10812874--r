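#' @include AllClasses.R
NULL

#' Default random-search spaces
#'
#' Built-in hyperparameter ranges for the two learners. GBT: tree depth
#' 3-10, learning rate 1e-3 to 0.3 (log scale), subsample 0.5-1, with the
#' round cap and early-stopping patience fixed. NN: branch/head widths,
#' dropout 0-0.5, learning rate 1e-4 to 1e-2 (log scale), batch size in
#' \{64, 256, 1024\}. 15 trials by default.
#'
#' @param kind \code{"gbt"} or \code{"nn"}.
#' @param trialCount number of random-search trials (default 15).
#' @return A [HyperparameterSpace-class].
#' @export
defaultSearchSpace <- function(kind = c("gbt", "nn"), trialCount = 15L) {
  kind <- match.arg(kind)
  params <- switch(kind,
    gbt = list(
      max_depth = list(choices = 3:10),
      learning_rate = list(low = 1e-3, high = 0.3, scale = "log"),
      subsample = list(low = 0.5, high = 1)),
    nn = list(
      omics_widths = list(choices = list(c(64L, 32L), c(128L, 64L),
                                         c(256L, 128L))),
      head_widths = list(choices = list(32L, 64L, c(64L, 32L))),
      dropout = list(low = 0, high = 0.5),
      learning_rate = list(low = 1e-4, high = 1e-2, scale = "log"),
      batch_size = list(choices = c(64L, 256L, 1024L))))
  hyperparameterSpace(params, trialCount)
}

# draw one assignment from the space (uses the current RNG stream)
.sampleAssignment <- function(space) {
  out <- lapply(space@params, function(p) {
    if (!is.null(p$choices)) {
      ch <- p$choices
      ch[[sample.int(length(ch), 1L)]]
    } else {
      v <- if (identical(p$scale, "log"))
        exp(stats::runif(1L, log(p$low), log(p$high)))
      else stats::runif(1L, p$low, p$high)
      if (isTRUE(p$integer)) as.integer(round(v)) else v
    }
  })
  names(out) <- names(space@params)
  out
}

#' Random hyperparameter search
#'
#' Samples \code{trialCount} hyperparameter assignments (seeded), fits
#' each on the training set, and returns the model with the lowest
#' held-out validation MSE; ties break toward the earliest trial. The full
#' trial log (assignment, validation MSE, stopping point) is attached to
#' the returned model.
#'
#' @param kind learner: \code{"gbt"} or \code{"nn"}.
#' @param space a [HyperparameterSpace-class]; default
#'   \code{defaultSearchSpace(kind)}.
#' @param train,val [PairedDataset-class] objects.
#' @param seed integer seed governing both the assignment draws and the
#'   per-trial fit seeds.
#' @param fixedParams named list merged under every sampled assignment
#'   (e.g. a smaller \code{max_epochs}).
#' @return The best [TrainedModel-class]; slot \code{trials} holds the
#'   trial log.
#' @export
randomSearch <- function(kind = c("gbt", "nn"), space = NULL, train, val,
                         seed = 1L, fixedParams = list()) {
  kind <- match.arg(kind)
  if (is.null(space)) space <- defaultSearchSpace(kind)
  validObject(space)
  set.seed(seed)
  assignments <- lapply(seq_len(space@trialCount),
                        function(i) .sampleAssignment(space))
  fitFun <- switch(kind, gbt = fitGBT, nn = fitNN)
  fits <- vector("list", length(assignments))
  errors <- character()
  for (i in seq_along(assignments)) {
    prm <- utils::modifyList(fixedParams, assignments[[i]])
    fits[[i]] <- tryCatch(
      fitFun(train, val, params = prm, seed = deriveSeed(seed, 500L + i)),
      error = function(e) {
        errors[[length(errors) + 1L]] <<- conditionMessage(e)
        NULL
      })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("all ", length(fits), " random-search trials failed: ",
         paste(unique(errors), collapse = "; "))
  vmse <- vapply(fits, function(f) if (is.null(f)) Inf else f@validationMSE,
                 numeric(1))
  log <- data.frame(
    trial = seq_along(fits),
    params = vapply(assignments, function(a)
      as.character(jsonlite::toJSON(a, auto_unbox = TRUE, digits = NA)),
      character(1)),
    validation_mse = vmse,
    stopped_at = vapply(fits, function(f)
      if (is.null(f)) NA_integer_ else f@stoppedAt, integer(1)))
  best <- fits[[which.min(vmse)]]   # which.min takes the earliest tie
  best@trials <- log
  best
}
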