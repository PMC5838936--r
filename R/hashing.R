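# k-mer encoding, linear hash families and (k,c)-sketches.

# The 25-letter amino-acid alphabet of the encoder: the 20 standard residues
# plus the ambiguity/rare letters B, O, U, X, Z, in sorted ASCII order
# (A = 0 ... Z = 24; J is not a valid residue letter). The order is part of
# the on-disk contract: sketches are only reproducible across runs if k-mer
# codes are.
.AA_LETTERS <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "O", "P", "Q", "R", "S", "T", "U", "V", "W", "X", "Y",
                 "Z")

.AA_DIGIT <- local({
  d <- rep(NA_real_, 127)
  d[utf8ToInt(paste(.AA_LETTERS, collapse = ""))] <- seq_along(.AA_LETTERS) - 1
  d
})

#' Encode and decode amino-acid k-mers as integers
#'
#' A k-mer is encoded positionally in base 25 over the fixed alphabet of
#' the 20 standard residues plus B, O, U, X, Z in ASCII order (`A` = 0,
#' `B` = 1, ..., `Z` = 24). The encoding is a bijection between length-`k`
#' strings and `[0, 25^k)`, so hash functions can operate on exact integer
#' terms.
#'
#' @param kmer single string of residue letters.
#' @param code non-negative integer code (vectorised).
#' @param k k-mer length to decode to.
#' @return `encodeKmer()`: a numeric code; `decodeKmer()`: character vector
#'   of k-mers.
#' @examples
#' encodeKmer("AAAAAA")   # 0
#' decodeKmer(2, k = 6)   # "AAAAAC"
#' @export
encodeKmer <- function(kmer) {
  stopifnot(is.character(kmer), length(kmer) == 1L, !is.na(kmer))
  d <- .AA_DIGIT[utf8ToInt(kmer)]
  if (anyNA(d))
    stop(sprintf("invalid residue letter in k-mer '%s'", kmer))
  sum(d * 25^(rev(seq_along(d)) - 1))
}

#' @rdname encodeKmer
#' @export
decodeKmer <- function(code, k) {
  k <- .assertCount(k, "k")
  stopifnot(is.numeric(code), all(code >= 0), all(code < 25^k))
  vapply(code, function(x) {
    digits <- integer(k)
    for (i in k:1) {
      digits[i] <- x %% 25
      x <- x %/% 25
    }
    paste(.AA_LETTERS[digits + 1], collapse = "")
  }, character(1))
}

#' k-mer term set of a sequence
#'
#' Encodes every length-`k` window of `x` and collapses duplicates. This is
#' the term set on which first-level sketches are computed. Sequences
#' shorter than `k` yield an empty set.
#'
#' @param x a single amino-acid string.
#' @param k window length (default 6).
#' @return sorted numeric vector of distinct k-mer codes.
#' @examples
#' kmerSet("MKVAMKV", k = 6)
#' @export
kmerSet <- function(x, k = 6L) {
  k <- .assertCount(k, "k")
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  n <- nchar(x)
  if (n < k) return(numeric(0))
  d <- .AA_DIGIT[utf8ToInt(x)]
  if (anyNA(d))
    stop(sprintf("invalid residue letter in sequence '%s'",
                 substr(x, 1, 20)))
  if (n == k) return(sum(d * 25^(rev(seq_len(k)) - 1)))
  # embed() row i is d[i+k-1], ..., d[i]: weight column j by 25^(j-1)
  codes <- drop(stats::embed(d, k) %*% 25^(seq_len(k) - 1))
  sort(unique(codes))
}

#' Construct hash functions
#'
#' `linearHash()` builds the linear permutation substitute
#' \eqn{x \mapsto (a x + b) \bmod p} with `p` prime; `tableHash()` builds a
#' lookup-table hash from explicitly assigned values, which is how worked
#' examples inject a prescribed ordering of terms.
#'
#' @param a,b integer coefficients, `1 <= a < p`, `0 <= b < p`.
#' @param p prime modulus, `< 2^31`.
#' @param values named numeric vector; names are decimal term codes.
#' @param index ordinal position within a family (informational).
#' @return a [LinearHash] or [TableHash] object.
#' @examples
#' fn <- linearHash(7, 3, 101)
#' hashValues(fn, 0:5)
#' @export
linearHash <- function(a, b, p, index = 0L) {
  new("LinearHash", a = as.numeric(a), b = as.numeric(b), p = as.numeric(p),
      index = as.integer(index))
}

#' @rdname linearHash
#' @export
tableHash <- function(values, index = 0L) {
  new("TableHash", values = values, index = as.integer(index))
}

#' @rdname hashValues
#' @export
setMethod("hashValues", "LinearHash", function(fn, x) {
  .hashLinear(x, fn@a, fn@b, fn@p)
})

#' @rdname hashValues
#' @export
setMethod("hashValues", "TableHash", function(fn, x) {
  v <- fn@values[as.character(x)]
  if (anyNA(v))
    stop("TableHash has no value for some term(s)")
  unname(v)
})

#' Generate a seed-reproducible family of linear hash functions
#'
#' Coefficients are drawn sequentially with a seeded RNG (`a` uniform in
#' `[1, p-1]`, `b` uniform in `[0, p-1]`), so the family of size `n` is a
#' prefix of the family of size `n + 1` from the same seed. The iterative
#' driver grows the family by regenerating it at a larger `n`.
#'
#' @param n family size.
#' @param prime prime modulus shared by all members (default `2^31 - 1`).
#' @param seed RNG seed.
#' @return a [HashFamily].
#' @examples
#' fam <- makeHashFamily(3, seed = 1)
#' identical(hashFunctions(fam),
#'           hashFunctions(makeHashFamily(5, seed = 1))[1:3])
#' @export
makeHashFamily <- function(n, prime = 2147483647, seed = 1L) {
  n <- .assertCount(n, "n")
  if (!.isPrime(prime)) stop("'prime' must be a prime number")
  if (prime >= 2^31) stop("'prime' must be < 2^31")
  fns <- .withSeed(seed, {
    lapply(seq_len(n), function(i) {
      a <- 1 + floor(stats::runif(1) * (prime - 1))
      b <- floor(stats::runif(1) * prime)
      linearHash(a, b, prime, index = i)
    })
  })
  new("HashFamily", seed = as.integer(seed), prime = as.numeric(prime),
      functions = fns)
}

#' @describeIn makeHashFamily list of member [HashFn] objects.
#' @param family a [HashFamily].
#' @export
hashFunctions <- function(family) {
  stopifnot(is(family, "HashFamily"))
  family@functions
}

#' The (k,c)-sketch of a term set
#'
#' Returns the `min(c, |terms|)` terms with the smallest hash values under
#' `fn`, ordered ascending by (hash value, term); ties on the hash value are
#' broken by the smaller term so that sketches are fully deterministic. Two
#' term sets are deemed similar under `fn` when their sketches are equal as
#' ordered tuples. Note the sketch stores the minimizing terms themselves,
#' not their hash values.
#'
#' @param terms numeric vector of distinct non-negative term codes (k-mer
#'   codes at level 1, region-registry codes at level 2).
#' @param fn a [HashFn].
#' @param c sketch width (default 2).
#' @return numeric vector of at most `c` terms; `numeric(0)` for an empty
#'   term set ("no sketch" - callers skip the node for this function).
#' @examples
#' sketchOf(c(3, 5, 9), linearHash(1, 0, 2147483647), c = 2)  # 3 5
#' @export
sketchOf <- function(terms, fn, c = 2L) {
  c <- .assertCount(c, "c")
  if (length(terms) == 0L) return(numeric(0))
  v <- hashValues(fn, terms)
  ord <- order(v, terms)
  terms[ord[seq_len(min(c, length(terms)))]]
}

# Sketch identity key used for bucketing: the exact ordered tuple of
# minimizing terms. Shorter sketches (term sets with < c elements) get a
# shorter key and therefore only ever match equally short sketches.
.sketchKey <- function(sk) {
  if (length(sk) == 0L) NA_character_ else paste(sk, collapse = "|")
}

.sketchKeys <- function(termsets, fn, c) {
  vapply(termsets, function(t) .sketchKey(sketchOf(t, fn, c)), character(1))
}
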