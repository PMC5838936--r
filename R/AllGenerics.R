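#' Graph and clustering accessors
#'
#' `nodes()` and `edges()` return the node identifiers and the two-column
#' edge matrix of a [SimilarityGraph]; `clusters()` returns the named list
#' of member sets of a [Clustering]; `modularity()` evaluates the partition
#' quality \eqn{Q} of a clustering on a graph.
#'
#' @param x,g a [SimilarityGraph] or [Clustering]
#' @param ... further arguments for methods
#' @return `nodes()`: character vector. `edges()`: character matrix with
#'   columns `from`, `to` (zero rows for edgeless graphs). `clusters()`:
#'   named list of character vectors.
#' @name graph-accessors
#' @aliases nodes edges clusters
NULL

#' @rdname graph-accessors
#' @export
setGeneric("nodes", function(x, ...) standardGeneric("nodes"))

#' @rdname graph-accessors
#' @export
setGeneric("edges", function(x, ...) standardGeneric("edges"))

#' @rdname graph-accessors
#' @export
setGeneric("clusters", function(x, ...) standardGeneric("clusters"))

#' Evaluate hash functions
#'
#' Applies a [HashFn] to a vector of non-negative integer terms and returns
#' the hash values. For [LinearHash] this is the exact evaluation of
#' \eqn{(a x + b) \bmod p}; for [TableHash] a lookup of the injected values.
#'
#' @param fn a [HashFn]
#' @param x numeric vector of term codes
#' @return numeric vector of hash values, same length as `x`
#' @examples
#' hashValues(linearHash(3, 1, 101), c(0, 1, 2))
#' @export
setGeneric("hashValues", function(fn, x) standardGeneric("hashValues"))

#' @rdname modularity
#' @export
setGeneric("modularity", function(g, partition, ...) standardGeneric("modularity"))
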