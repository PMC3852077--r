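# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.  `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed (< 2^31) from a parent seed and an index.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * i) %% 2147483587L)
}

# Encode a binary vector (possibly a subset of loci) as a single number.
# Only used for fast equality lookups; values fit in doubles for L <= 40.
bit_code <- function(bits) {
  if (length(bits) == 0L) return(0)
  sum(bits * 2^(seq_along(bits) - 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) {
  stop(structure(class = c("xhsd_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
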