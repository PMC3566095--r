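#' @keywords internal
"_PACKAGE"

#' @importFrom stats dist cutree rnorm runif
#' @importFrom utils read.delim write.table head combn
#' @importFrom methods new is slot
NULL

#' Round half away from zero
#'
#' Display rounding used in validation tables: 0.125 becomes 0.13, as in
#' hand-rounded tables, rather than R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## 32-bit FNV-1a over a string, returned as a double in [0, 2^32).
## R has no unsigned 32-bit integer, so the multiply is split into
## 16-bit halves to stay inside the exact-double range.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor64(h, b)
    h <- mulmod32(h, 16777619)
  }
  h
}

bitwXor64 <- function(a, b) {
  # xor of doubles holding 32-bit values
  hi_a <- a %/% 65536; lo_a <- a %% 65536
  hi_b <- b %/% 65536; lo_b <- b %% 65536
  bitwXor(as.integer(hi_a), as.integer(hi_b)) * 65536 +
    bitwXor(as.integer(lo_a), as.integer(lo_b))
}

mulmod32 <- function(a, b) {
  hi <- a %/% 65536
  lo <- a %% 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
}

## Deterministic scoped RNG: run expr under a seed, restore global state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## Structured one-line logger; verbosity controlled by option.
vs_log <- function(..., level = "info") {
  if (isTRUE(getOption("ppargscreen.quiet", TRUE)) && level == "info") {
    return(invisible(NULL))
  }
  message(sprintf("[%s] %s", level, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == floor(x)
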