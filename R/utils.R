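# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonical unordered region pair
#'
#' Region pairs are stored unordered; the canonical form puts the
#' lexicographically smaller code first.
#' @param a,b character vectors of region codes (recycled together).
#' @return list with components `a` and `b`, canonically ordered.
#' @keywords internal
canonical_pair <- function(a, b) {
  swap <- as.character(b) < as.character(a)
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

pair_key <- function(a, b) {
  p <- canonical_pair(a, b)
  paste(p$a, p$b, sep = "|")
}

# Deterministic 31-bit string hash (polynomial rolling hash mod 2^31 - 1).
# Used to derive per-iteration RNG seeds from graph signatures; doubles stay
# below 2^53 so the arithmetic is exact on every platform.
hash31 <- function(x) {
  m <- 2147483647
  h <- 0
  for (v in utf8ToInt(x)) h <- (h * 31 + v) %% m
  as.integer(h)
}

# Derive a child seed from a base seed and a character tag.
derive_seed <- function(seed, tag) {
  hash31(paste0(as.integer(seed), ":", tag))
}

stop_jmenet <- function(fmt, ..., class = "jmenet_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}
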