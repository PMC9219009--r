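# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log a message to stderr with a level prefix
#'
#' All pipeline logging goes to stderr so that stdout stays clean for data.
#'
#' @param level One of "INFO", "WARN", "ERROR".
#' @param ... Message parts, pasted with no separator.
#' @return Invisibly, the formatted line.
#' @keywords internal
arfnet_log <- function(level = "INFO", ...) {
  line <- sprintf("[%s] %s", level, paste0(...))
  message(line)
  invisible(line)
}

# Stable 31-bit hash of a label, used to split one user seed into independent
# per-generator streams: adding a generator never perturbs the others.
.label_hash <- function(label) {
  codes <- utf8ToInt(label)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483587
  h
}

#' Derive a deterministic sub-seed from a seed and a label
#'
#' @param seed Integer master seed.
#' @param label Character label of the consuming stream.
#' @return An integer seed in `[0, 2^31 - 60)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(seed) * 48271 + .label_hash(label)) %% 2147483587)
}

# Run code under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Coordinate convention: all genomic offsets in this package are 0-based
# half-open, stated once here and used everywhere.
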