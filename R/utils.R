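# Internal helpers: seeded evaluation, deterministic hashing, logging.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic fold hash over non-negative integers, mod 2^31 - 1.
# Exact in double arithmetic: 2^31 * 1000003 < 2^53.
MOD31 <- 2147483647

hash_fold <- function(xs, init = 17) {
  h <- init
  for (x in xs) h <- (h * 31 + (x %% MOD31)) %% MOD31
  h
}

# Stable string hash (for vocabulary checksums).
hash_string <- function(s) {
  hash_fold(utf8ToInt(paste(s, collapse = "\x1f")))
}

# Derive a per-stage seed from a global seed; stays below 2^31.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 9973) %% 2147483399 + 1)
}

# Locale-independent deterministic ordering of character vectors.
str_order <- function(x) order(x, method = "radix")
str_sort <- function(x) x[str_order(x)]

`%||%` <- function(a, b) if (is.null(a)) b else a

rxn_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
  invisible(NULL)
}

# Stable key for a label set (order-free set semantics).
set_key <- function(labels) paste(str_sort(unique(labels)), collapse = "\x1f")

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
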