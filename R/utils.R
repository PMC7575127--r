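# Run expr under a given RNG seed, restoring the caller's RNG state after.
with_preserved_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic substream seed keyed by integer indices, kept below 2^31 so
# subsetting a generated dataset reproduces the same draws.
substream_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (i in idx) h <- (h * 69069 + (as.double(i) + 1) * 40503) %% 2147483647
  as.integer(h)
}

# Normal draw truncated at a physical lower bound (simple rejection).
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(pmax(rep(mean, n), lower))
  out <- stats::rnorm(n, mean, sd)
  for (tries in 1:100) {
    bad <- out < lower
    if (!any(bad)) break
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(out, lower)
}
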