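# Internal helpers shared across modules.

#' @useDynLib protoerp, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Consistent error vocabulary: validation errors carry class "protoerp_error".
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("protoerp_validation_error", "protoerp_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("protoerp_format_error", "protoerp_error", "error")))
}

stop_shape <- function(...) {
  stop(errorCondition(paste0(...), class = c("protoerp_shape_error", "protoerp_error", "error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Odd-rounded kernel length in samples for a kernel duration in seconds.
round_to_odd <- function(x) {
  k <- max(1L, as.integer(round(x)))
  if (k %% 2L == 0L) k + 1L else k
}
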