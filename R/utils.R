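# internal helpers shared across modules

#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library functions never clobber the
# user's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  force(code)
}

#' Derive a per-stage seed from one global seed
#'
#' Pipeline stages (synthesis, pretraining, fine-tuning, ...) each consume a
#' seed derived from the run's global seed and the stage name, so any stage
#' can be re-run in isolation with identical randomness.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, keeps the result a valid 32-bit R seed
  h <- as.numeric(seed) %% m
  for (u in utf8ToInt(stage)) h <- (h * 31 + u) %% m
  as.integer(h %% (m - 1) + 1)
}

stop_line <- function(lineno, msg) {
  stop(sprintf("line %d: %s", lineno, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# numerically safe log
safe_log <- function(p) log(pmax(p, 1e-12))
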