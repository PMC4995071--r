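# Internal helpers shared across modules.

# round-half-up at a given number of decimals; base round() is half-to-even,
# which disagrees with how shares are conventionally printed.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code with a fixed RNG seed and restore the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Largest-remainder apportionment of n items over the given shares; counts
# always sum to n, so quota sampling is exact and never flaky.
apportion <- function(n, shares) {
  stopifnot(n >= 0, all(shares >= 0))
  if (sum(shares) == 0) return(rep(0L, length(shares)))
  shares <- shares / sum(shares)
  raw <- n * shares
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(shares))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# permutation shuffle that is safe for length-0/1 vectors (unlike sample(x))
shuffle <- function(x) x[sample.int(length(x))]

new_df <- function(...) data.frame(..., stringsAsFactors = FALSE)
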