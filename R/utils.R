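# Internal helpers shared across modules.

#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats pnorm qf rexp rnorm runif sd setNames
#' @importFrom utils read.table write.table
NULL

# Condition helpers: config errors are caller mistakes (bad arguments,
# malformed manifests); data errors are violations found inside input data.
stopConfig <- function(...) {
  stop(errorCondition(paste0(...), class = c("gcnetConfigError", "error")))
}

stopData <- function(...) {
  stop(errorCondition(paste0(...), class = c("gcnetDataError", "error")))
}

#' Midranks of a metric vector
#'
#' Ranks a per-node metric so that rank 1 is the best node, tied values
#' receive the average of the positions they span (midranks), and `NA`
#' (undefined) values are placed after all defined values.  The midrank
#' convention guarantees that the ranks always sum to N(N+1)/2, which makes
#' downstream rank-order sums invariant to the input node order.
#'
#' @param x numeric metric vector, possibly named, possibly containing `NA`.
#' @param decreasing if `TRUE` (default) larger metric values are better
#'   (rank 1 = largest); if `FALSE` smaller values are better.
#' @return numeric vector of ranks in `[1, N]`, same names as `x`.
#' @export
#' @examples
#' midranks(c(a = 10, b = 3, c = 3))
midranks <- function(x, decreasing = TRUE) {
  v <- if (decreasing) -as.numeric(x) else as.numeric(x)
  r <- rank(v, na.last = "keep", ties.method = "average")
  nNA <- sum(is.na(r))
  if (nNA > 0L) {
    # undefined metrics share the trailing positions as a midrank block
    r[is.na(r)] <- sum(!is.na(r)) + (nNA + 1) / 2
  }
  names(r) <- names(x)
  r
}

#' Derive a stage seed from a global seed
#'
#' Deterministically combines a global integer seed with a stage tag
#' (e.g. `"patient03/walk"`) so that each stochastic stage of a pipeline
#' gets its own reproducible stream, and adding stages does not perturb the
#' streams of existing ones.  Uses a 31-multiplier polynomial string hash
#' modulo 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param tag character scalar naming the stage.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, tag) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopConfig("'seed' must be a single integer")
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + abs(as.numeric(seed))) %% 2147483647)
}

# Set the RNG for a stochastic operation without clobbering the caller's
# stream: the previous .Random.seed is restored on exit.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
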