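#' @importFrom rlang .data abort
#' @importFrom stats aov coef lm pnorm rnorm runif sd setNames
#' @importFrom utils read.delim write.csv read.csv
NULL

# Evaluate `code` with the global RNG seeded to `seed`, restoring the previous
# RNG state afterwards so library calls never perturb a caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic sub-seed for a named substream, kept well below 2^31.
sub_seed <- function(seed, stream) {
  offset <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) + offset * 1009L) %% 2000000011L
}

stop_domain <- function(msg, class) {
  abort(msg, class = c(class, "nyctinast_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
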