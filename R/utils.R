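# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library code never perturbs user simulations.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.isPrime <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n != floor(n) || n < 2)
    return(FALSE)
  if (n < 4) return(TRUE)
  if (n %% 2 == 0) return(FALSE)
  i <- 3
  while (i * i <= n) {
    if (n %% i == 0) return(FALSE)
    i <- i + 2
  }
  TRUE
}

# Exact (a*x + b) mod p for doubles, p < 2^31, x < 2^31.
# a is split into 16-bit halves so every intermediate product stays below
# 2^47 and is therefore exact in double precision.
.hashLinear <- function(x, a, b, p) {
  stopifnot(p < 2^31)
  if (any(x >= 2^31 | x < 0))
    stop("hash input terms must lie in [0, 2^31)")
  a1 <- a %/% 65536
  a0 <- a %% 65536
  (((a1 * x) %% p * 65536) %% p + (a0 * x) %% p + b) %% p
}

# Canonical unordered-pair code for node indices i < j on a registry of
# size n; used for compact edge sets.
.pairCode <- function(i, j, n) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  (lo - 1) * n + hi
}

.decodePairs <- function(codes, n) {
  codes <- sort(codes)
  hi <- (codes - 1) %% n + 1
  lo <- (codes - 1) %/% n + 1
  cbind(lo, hi)
}

.assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}
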