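# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Structured conditions so callers (and tests) can distinguish failure modes.
sulf_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sulfscan_error", "error")))
}

validation_error <- function(...) sulf_error(paste0(...), "sulfscan_validation_error")
parse_error <- function(...) sulf_error(paste0(...), "sulfscan_parse_error")
insufficient_data_error <- function(...) sulf_error(paste0(...), "sulfscan_insufficient_data")
degenerate_input_error <- function(...) sulf_error(paste0(...), "sulfscan_degenerate_input")
io_error <- function(...) sulf_error(paste0(...), "sulfscan_io_error")

#' Derive a reproducible sub-seed for a named random stream
#'
#' A single root seed drives every generator in a pipeline run; each stage
#' draws from its own deterministic substream so that adding or removing a
#' stage does not perturb the others.
#'
#' @param seed Integer root seed.
#' @param stream Character stream label (e.g., `"survival"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(42, "survival")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  codes <- utf8ToInt(stream)
  offset <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + offset * 104729) %% 2147483647)
}

# Run `code` under `set.seed(seed)` and restore the caller's RNG state after.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}
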