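# internal helpers

# evaluate `code` under a temporary RNG state seeded with `seed`;
# NULL seed means "use the current RNG stream"
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# weighted sampling by inverse-CDF lookup, vectorised; returns `size` indices
# drawn with replacement proportional to `w`
sample_weighted <- function(n_items, size, w) {
  cw <- cumsum(as.numeric(w))
  tot <- cw[n_items]
  if (tot <= 0) stop("all sampling weights are zero", call. = FALSE)
  findInterval(stats::runif(size) * tot, cw) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x
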