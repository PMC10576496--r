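#' @importFrom rlang abort warn .data
#' @importFrom stats lm coef qnorm dnorm pt quantile rnorm runif sd var
#' @importFrom utils head tail
NULL

# classed conditions so callers can test on error class, not message text
abort_reef <- function(class, message) {
  abort(message, class = c(paste0("reefmorph_", class), "reefmorph_error"))
}

stop_not_found       <- function(msg) abort_reef("not_found", msg)
stop_invalid         <- function(msg) abort_reef("invalid_argument", msg)
stop_unsupported     <- function(msg) abort_reef("unsupported_format", msg)
stop_malformed       <- function(msg) abort_reef("malformed_input", msg)
stop_empty           <- function(msg) abort_reef("empty_input", msg)
stop_degenerate      <- function(msg) abort_reef("degenerate_surface", msg)
stop_empty_result    <- function(msg) abort_reef("empty_result", msg)
stop_singular        <- function(msg) abort_reef("singular_design", msg)
stop_misaligned      <- function(msg) abort_reef("aligned_inputs", msg)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 &&
    abs(x - round(x)) < 1e-9
}

is_power_of_two <- function(x) {
  x >= 1 && abs(x - round(x)) < 1e-9 && bitwAnd(as.integer(round(x)),
                                                as.integer(round(x)) - 1L) == 0L
}

# fixed per-generator offsets keep the random streams independent, so adding
# a generator never perturbs another's draws for the same user seed
seed_stream <- function(seed, stream) {
  (as.integer(seed) + stream * 104729L) %% 2147483647L
}
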