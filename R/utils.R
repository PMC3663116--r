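## Run code under a local RNG state seeded with `seed`; restores the
## caller's .Random.seed on exit. With seed = NULL the code runs under the
## ambient RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a stream of distinct child seeds from one user-facing seed,
## staying inside the 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

## Monte-Carlo standard error of a (possibly autocorrelated) chain by the
## batch-means method.
batch_means_se <- function(x) {
  n <- length(x)
  if (n < 4) return(NA_real_)
  nb <- max(2L, floor(sqrt(n)))
  bs <- floor(n / nb)
  means <- vapply(seq_len(nb), function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
                  numeric(1))
  stats::sd(means) / sqrt(nb)
}
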