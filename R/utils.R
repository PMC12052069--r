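# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. NULL seed = use current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# sample() without the scalar-x surprise
resample <- function(x, n) x[sample.int(length(x), n)]

# derive a valid 32-bit seed from (seed, salt) pairs
derive_seed <- function(seed, salt) {
  s <- (as.numeric(seed) * 48271 + as.numeric(salt) * 16807) %% 2147483646
  as.integer(s) + 1L
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch), cached by n
gauss_legendre <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    out <- list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
    cache[[key]] <<- out
    out
  }
})

log1pexp <- function(x) {
  out <- x
  lo <- x <= 33
  out[lo] <- log1p(exp(x[lo]))
  out
}
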