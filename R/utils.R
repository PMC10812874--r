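# internal helpers shared across modules

# deterministic sub-seed derivation; stays below 2^31
deriveSeed <- function(base, offset) {
  as.integer((as.double(base) %% 1e6) * 1009 + (as.double(offset) %% 1e6) + 1)
}

# population-SD row scaling guard tolerance
.EPS_VAR <- 1e-12

#' Mean squared error
#'
#' The loss used throughout: mean of squared prediction errors.
#'
#' @param predictions,targets numeric vectors of equal, positive length.
#' @return single numeric, \code{mean((predictions - targets)^2)}.
#' @examples
#' mse(c(0, 0), c(1, 3))  # 5
#' @export
mse <- function(predictions, targets) {
  if (length(predictions) != length(targets))
    stop("predictions and targets differ in length (", length(predictions),
         " vs ", length(targets), ")")
  if (!length(targets)) stop("mse needs at least one element")
  mean((predictions - targets)^2)
}

# md5 of a canonical JSON rendering, used to fingerprint experiment configs
hashConfig <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}
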