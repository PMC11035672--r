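## Seed plumbing. Every stochastic operation in the package takes an explicit
## integer seed; sub-streams are derived by hashing (parent seed, labels) so
## that adding annotators or frames never perturbs existing streams.

#' Derive a child seed from a parent seed and labels
#'
#' Hashes the parent seed together with an arbitrary set of string/numeric
#' labels (annotator id, frame index, stage name, ...) into a reproducible
#' seed in `[1, 2^31 - 2]`. The hash is a 32-bit FNV-1a over the UTF-8 bytes
#' of the formatted components, so derived streams are stable across
#' platforms and R sessions.
#'
#' @param seed parent integer seed.
#' @param ... labels (coerced with `as.character`) identifying the sub-stream.
#' @return an integer seed suitable for `set.seed`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- vapply(list(seed, ...), function(x) paste(as.character(x), collapse = ","),
                  character(1))
  bytes <- utf8ToInt(paste(parts, collapse = "\x1f"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- mul_mod32(h, 16777619)
  }
  as.integer(h %% 2147483646) + 1L
}

# xor on doubles holding 32-bit unsigned values (bitwXor needs < 2^31)
bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor((a %/% 65536) %% 65536, (b %/% 65536) %% 65536)
  hi * 65536 + lo
}

# (a * b) mod 2^32 without losing precision in doubles: split a into 16-bit
# halves so every intermediate stays below 2^53
mul_mod32 <- function(a, b) {
  lo <- a %% 65536
  hi <- (a %/% 65536) %% 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
}

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never disturbs the
#' caller's RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
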