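#' @include AllClasses.R AllGenerics.R
NULL

# ---- compact feed-forward network (two input branches, Adam, dropout) ----
# The omics branch passes through dense ReLU layers; the drug one-hot is
# concatenated unchanged before the head layers; the output layer is linear.
# Plain base-R matrix algebra: single-threaded and deterministic per seed.

.nnInit <- function(dOmics, dDrug, omicsWidths, headWidths) {
  layers <- list()
  he <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  }
  nin <- dOmics
  for (w in omicsWidths) {
    layers[[length(layers) + 1L]] <- list(W = he(nin, w),
                                          b = numeric(w), branch = "omics")
    nin <- w
  }
  nin <- nin + dDrug
  for (w in headWidths) {
    layers[[length(layers) + 1L]] <- list(W = he(nin, w),
                                          b = numeric(w), branch = "head")
    nin <- w
  }
  layers[[length(layers) + 1L]] <- list(W = he(nin, 1L), b = 0,
                                        branch = "out")
  layers
}

.nnForward <- function(layers, Xo, Xd, dropout = 0, training = FALSE) {
  caches <- vector("list", length(layers))
  a <- Xo
  concatAt <- NA_integer_
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$branch == "head" && is.na(concatAt)) {
      concatAt <- i
      a <- cbind(a, Xd)
    }
    if (ly$branch == "out" && is.na(concatAt)) {  # no head layers
      concatAt <- i
      a <- cbind(a, Xd)
    }
    z <- a %*% ly$W
    z <- sweep(z, 2L, ly$b, "+")
    if (ly$branch == "out") {
      caches[[i]] <- list(input = a)
      a <- z
    } else {
      act <- pmax(z, 0)
      mask <- NULL
      if (training && dropout > 0) {
        mask <- matrix(stats::runif(length(act)) >= dropout,
                       nrow(act), ncol(act))
        act <- act * mask / (1 - dropout)
      }
      caches[[i]] <- list(input = a, z = z, mask = mask)
      a <- act
    }
  }
  list(yhat = as.numeric(a), caches = caches, concatAt = concatAt)
}

.nnBackward <- function(layers, fwd, y, dropout, dOmicsOut) {
  n <- length(y)
  grads <- vector("list", length(layers))
  delta <- matrix(2 * (fwd$yhat - y) / n, n, 1L)
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cache <- fwd$caches[[i]]
    if (ly$branch != "out") {
      if (!is.null(cache$mask)) delta <- delta * cache$mask / (1 - dropout)
      delta <- delta * (cache$z > 0)
    }
    grads[[i]] <- list(W = crossprod(cache$input, delta),
                       b = colSums(delta))
    delta <- delta %*% t(ly$W)
    if (i == fwd$concatAt) {
      # drop the drug-branch columns of the concatenated gradient
      delta <- delta[, seq_len(dOmicsOut), drop = FALSE]
    }
  }
  grads
}

#' Fit a feed-forward network regressor
#'
#' Trains a two-branch multilayer perceptron: the omics profile passes
#' through dense ReLU layers with dropout, is concatenated with the raw
#' drug one-hot vector, and flows through dense head layers to a linear
#' output. Optimized with Adam on the MSE loss; training halts by early
#' stopping on held-out validation MSE with patience, and the best-epoch
#' weights are restored. Omics features and targets are standardized
#' internally using training-set statistics.
#'
#' With a fixed seed, repeated single-threaded fits agree in validation
#' MSE to numerical precision.
#'
#' @param train,val [PairedDataset-class] objects sharing feature
#'   dimensions.
#' @param params named list; recognized: \code{omics_widths} (default
#'   \code{c(64, 32)}), \code{head_widths} (\code{32}), \code{dropout}
#'   (0.1), \code{learning_rate} (2e-3), \code{batch_size} (128),
#'   \code{max_epochs} (200), \code{patience} (20 epochs).
#' @param seed integer seed (weight init, shuffling, dropout).
#' @return A [TrainedModel-class] of kind \code{"nn"};
#'   \code{validationMSE} is the best epoch's validation MSE and
#'   \code{stoppedAt} that epoch.
#' @export
fitNN <- function(train, val, params = list(), seed = 1L) {
  p <- utils::modifyList(list(
    omics_widths = c(64L, 32L), head_widths = 32L, dropout = 0.1,
    learning_rate = 2e-3, batch_size = 128L, max_epochs = 200L,
    patience = 20L), params)
  Xo <- train@cellInputs
  Xd <- train@drugInputs
  if (any(!is.finite(Xo)) || any(!is.finite(val@cellInputs)))
    stop("non-finite feature values; impute missing entries before fitting")
  xCenter <- colMeans(Xo)
  xScale <- apply(Xo, 2L, stats::sd)
  xScale[!is.finite(xScale) | xScale < .EPS_VAR] <- 1
  yCenter <- mean(train@targets)
  yScale <- stats::sd(train@targets)
  if (!is.finite(yScale) || yScale < .EPS_VAR) yScale <- 1
  std <- function(X) sweep(sweep(X, 2L, xCenter), 2L, xScale, "/")
  Xo <- std(Xo)
  XoVal <- std(val@cellInputs)
  y <- (train@targets - yCenter) / yScale

  set.seed(seed)
  layers <- .nnInit(ncol(Xo), ncol(Xd), p$omics_widths, p$head_widths)
  dOmicsOut <- utils::tail(p$omics_widths, 1L)
  adamM <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  adamV <- adamM
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  tStep <- 0L

  n <- nrow(Xo)
  batch <- min(p$batch_size, n)
  best <- Inf; bestLayers <- layers; bestEpoch <- 0L; wait <- 0L
  for (epoch in seq_len(p$max_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      fwd <- .nnForward(layers, Xo[idx, , drop = FALSE],
                        Xd[idx, , drop = FALSE],
                        dropout = p$dropout, training = TRUE)
      grads <- .nnBackward(layers, fwd, y[idx], p$dropout, dOmicsOut)
      tStep <- tStep + 1L
      corr <- sqrt(1 - b2^tStep) / (1 - b1^tStep)
      for (i in seq_along(layers)) {
        for (s in c("W", "b")) {
          g <- grads[[i]][[s]]
          adamM[[i]][[s]] <- b1 * adamM[[i]][[s]] + (1 - b1) * g
          adamV[[i]][[s]] <- b2 * adamV[[i]][[s]] + (1 - b2) * g^2
          layers[[i]][[s]] <- layers[[i]][[s]] -
            p$learning_rate * corr * adamM[[i]][[s]] /
            (sqrt(adamV[[i]][[s]]) + epsA)
        }
      }
    }
    vp <- .nnForward(layers, XoVal, val@drugInputs)$yhat * yScale + yCenter
    vmse <- mse(vp, val@targets)
    if (vmse < best - 1e-9) {
      best <- vmse; bestLayers <- layers; bestEpoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= p$patience) break
    }
  }
  new("TrainedModel", kind = "nn",
      fit = list(layers = bestLayers, xCenter = xCenter, xScale = xScale,
                 yCenter = yCenter, yScale = yScale, params = p),
      hyperparameters = p, validationMSE = best,
      stoppedAt = as.integer(bestEpoch), trials = data.frame())
}

# prediction path for a TrainedModel of kind "nn"
predictNN <- function(model, newdata) {
  f <- model@fit
  Xo <- sweep(sweep(newdata@cellInputs, 2L, f$xCenter), 2L, f$xScale, "/")
  .nnForward(f$layers, Xo, newdata@drugInputs)$yhat * f$yScale + f$yCenter
}
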