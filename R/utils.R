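# Internal helpers: argument checks, seed plumbing, config hashing.

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg, class = "seizadapt_error")
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child-seed derivation: a fixed affine step modulo a Mersenne
# prime keeps every derived seed in [1, 2^31 - 2] and independent of how many
# siblings are derived (adding a subject never perturbs existing ones).
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  for (k in seq_len(index)) {
    s <- (s * 48271) %% m
  }
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Stable hash of a configuration list (used to guard window-archive merges).
# FNV-1a over the deparsed canonical form; returns a hex string.
config_hash <- function(x) {
  s <- paste(deparse(x[order(names(x))] , control = "exact"), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
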