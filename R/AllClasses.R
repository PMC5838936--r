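#' @import methods
NULL

#' Hash functions over integer terms
#'
#' `HashFn` is the virtual parent of the hash functions used for min-wise
#' sketching. `LinearHash` is the working implementation, the linear
#' permutation substitute \eqn{x \mapsto (a x + b) \bmod p} with a large
#' prime modulus. `TableHash` assigns explicit hash values to an enumerated
#' set of terms; it exists so that tests and worked examples can inject an
#' arbitrary ordering of terms.
#'
#' @slot a,b,p numeric scalars of the linear map; `p` prime, `a` in
#'   `[1, p-1]`, `b` in `[0, p-1]`.
#' @slot index ordinal position of the function within its family (0 when
#'   free-standing).
#' @slot values (`TableHash`) named numeric vector mapping term codes
#'   (names, decimal strings) to hash values.
#' @aliases LinearHash-class TableHash-class
#' @seealso [linearHash()], [tableHash()], [hashValues()]
#' @exportClass HashFn
setClass("HashFn", representation("VIRTUAL", index = "integer"))

#' @exportClass LinearHash
setClass("LinearHash",
  contains = "HashFn",
  representation(a = "numeric", b = "numeric", p = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!.isPrime(object@p)) msg <- c(msg, "p must be prime")
    if (object@p >= 2^31) msg <- c(msg, "p must be < 2^31 for exact arithmetic")
    if (object@a < 1 || object@a >= object@p) msg <- c(msg, "a must be in [1, p-1]")
    if (object@b < 0 || object@b >= object@p) msg <- c(msg, "b must be in [0, p-1]")
    if (is.null(msg)) TRUE else msg
  })

#' @exportClass TableHash
setClass("TableHash",
  contains = "HashFn",
  representation(values = "numeric"),
  validity = function(object) {
    if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
      return("values must be uniquely named by term code")
    TRUE
  })

#' Seed-reproducible family of linear hash functions
#'
#' An ordered family of [LinearHash] functions drawn with a seeded RNG.
#' Regenerating with the same `(seed, prime, n)` yields identical
#' coefficients, and a family of size `n` is a prefix of the family of size
#' `n + 1` from the same seed; the iterative driver relies on this to add
#' hash functions without recomputing existing sketches.
#'
#' @slot seed integer RNG seed.
#' @slot prime numeric prime modulus shared by all members.
#' @slot functions list of [HashFn] objects.
#' @seealso [makeHashFamily()]
#' @exportClass HashFamily
setClass("HashFamily",
  representation(seed = "integer", prime = "numeric", functions = "list"),
  validity = function(object) {
    if (!all(vapply(object@functions, is, logical(1), "HashFn")))
      return("all family members must be HashFn objects")
    TRUE
  })

#' Undirected simple similarity graph on region identifiers
#'
#' Nodes are conserved-region identifiers; an edge records that at least one
#' hash function assigned the two regions an identical (k,c)-sketch. The
#' graph is simple: at most one edge per node pair, no self-loops. Edges are
#' stored canonically (`from < to` lexicographically on the node registry
#' order, rows sorted), so graphs built from permuted inputs are identical.
#'
#' @slot nodes character vector of node identifiers (sorted).
#' @slot edgeFrom,edgeTo parallel character vectors, one entry per edge.
#' @slot provenance optional list (one integer vector per edge) of the hash
#'   function indices that generated the edge; empty when not tracked.
#' @seealso [firstLevelGraph()], [secondLevelGraph()], [nodes()], [edges()]
#' @exportClass SimilarityGraph
setClass("SimilarityGraph",
  representation(nodes = "character", edgeFrom = "character",
                 edgeTo = "character", provenance = "list"),
  validity = function(object) {
    msg <- NULL
    if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node ids")
    if (length(object@edgeFrom) != length(object@edgeTo))
      msg <- c(msg, "edgeFrom/edgeTo length mismatch")
    if (any(object@edgeFrom == object@edgeTo)) msg <- c(msg, "self-loops not allowed")
    bad <- !(object@edgeFrom %in% object@nodes) | !(object@edgeTo %in% object@nodes)
    if (any(bad)) msg <- c(msg, "edge endpoint not among nodes")
    if (length(object@provenance) &&
        length(object@provenance) != length(object@edgeFrom))
      msg <- c(msg, "provenance must have one entry per edge")
    if (is.null(msg)) TRUE else msg
  })

#' A clustering of regions or proteins
#'
#' A named list of member sets. In non-overlapping mode (region clusters,
#' Louvain output) the member sets are pairwise disjoint; in overlapping
#' mode (protein clusters obtained by replacing each region with its parent
#' protein) a member may belong to several clusters.
#'
#' @slot clusters named list of character vectors (unique, non-empty).
#' @slot overlapping logical flag.
#' @seealso [Clustering()], [clusters()], [filterClusters()], [f1Average()]
#' @exportClass Clustering
setClass("Clustering",
  representation(clusters = "list", overlapping = "logical"),
  validity = function(object) {
    msg <- NULL
    cl <- object@clusters
    if (is.null(names(cl)) || anyDuplicated(names(cl)))
      msg <- c(msg, "clusters must be uniquely named")
    if (any(lengths(cl) == 0L)) msg <- c(msg, "empty clusters not allowed")
    if (any(vapply(cl, anyDuplicated, integer(1)) > 0L))
      msg <- c(msg, "duplicated member within a cluster")
    if (!object@overlapping && length(cl)) {
      all_members <- unlist(cl, use.names = FALSE)
      if (anyDuplicated(all_members))
        msg <- c(msg, "member sets must be disjoint when overlapping = FALSE")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Result of comparing two clusterings
#'
#' Holds the size-weighted precision, recall and F1 in both directions and
#' their average, all in [0, 1]. `degenerate` flags comparisons where one
#' side was empty after the minimum-size filter (the average F1 is then 0).
#'
#' @seealso [f1Average()], [f1OneSided()]
#' @exportClass ComparisonResult
setClass("ComparisonResult",
  representation(precisionXY = "numeric", recallXY = "numeric", f1XY = "numeric",
                 precisionYX = "numeric", recallYX = "numeric", f1YX = "numeric",
                 f1Avg = "numeric", degenerate = "logical"))

#' Tuning parameters of the iterative clustering driver
#'
#' @slot k k-mer length for first-level sketches (default 6).
#' @slot c sketch width, the number of minimal terms kept per hash function
#'   (default 2).
#' @slot hStart initial hash-family size (default 41).
#' @slot hStep family-size increment per iteration (default 1).
#' @slot d comparison lag: the clustering at `h` is compared with the one at
#'   `h - d` (default 40).
#' @slot tau termination threshold on the average weighted F1 (default 0.9;
#'   the loop stops when F1 strictly exceeds `tau`).
#' @slot hMax safety cap on the family size (default 500).
#' @slot minClusterSize clusters smaller than this are ignored in all F1
#'   computations (default 10).
#' @slot louvainThreshold per-sweep modularity-gain threshold of the local
#'   move phase (default 1e-7).
#' @slot prime modulus of the linear hash functions (default 2^31 - 1).
#' @slot seed master RNG seed; the level-2 family uses `seed + 1`.
#' @seealso [coreClustParam()], [runCoreClust()]
#' @exportClass CoreClustParam
setClass("CoreClustParam",
  representation(k = "integer", c = "integer", hStart = "integer",
                 hStep = "integer", d = "integer", tau = "numeric",
                 hMax = "integer", minClusterSize = "integer",
                 louvainThreshold = "numeric", prime = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@d < 1L) msg <- c(msg, "d must be >= 1")
    if (object@hStart <= object@d) msg <- c(msg, "hStart must exceed d")
    if (object@hStep < 1L) msg <- c(msg, "hStep must be >= 1")
    if (object@tau > 1) msg <- c(msg, "tau must be <= 1")  # tau = 0 is legal
    if (object@hMax < object@hStart) msg <- c(msg, "hMax must be >= hStart")
    if (!.isPrime(object@prime)) msg <- c(msg, "prime must be prime")
    if (object@prime >= 2^31) msg <- c(msg, "prime must be < 2^31")
    if (is.null(msg)) TRUE else msg
  })

#' Similarity graphs plus the incremental sketch store
#'
#' The pair of similarity graphs (level 1 from region k-mer sketches,
#' level 2 from neighbor-set sketches) for a hash-family size `h`, together
#' with the cached sketches that allow the family to be grown without
#' recomputation ([extendSimilarityGraphs()]).
#'
#' @slot level1,level2 [SimilarityGraph] objects.
#' @slot h current family size.
#' @slot store environment with cached term sets, sketch keys per function,
#'   cumulative level-1 edge set, neighbor snapshots and level-2 sketches.
#' @seealso [buildSimilarityGraphs()], [extendSimilarityGraphs()]
#' @exportClass CoreGraphs
setClass("CoreGraphs",
  representation(level1 = "SimilarityGraph", level2 = "SimilarityGraph",
                 h = "integer", store = "environment"))

#' Result of the iterative clustering driver
#'
#' @slot regionClusters non-overlapping [Clustering] of region identifiers
#'   (Louvain communities of the final level-2 graph; isolated regions are
#'   singleton clusters).
#' @slot proteinClusters overlapping [Clustering] of parent proteins, or an
#'   empty clustering when region-to-protein mapping was unavailable.
#' @slot trace data.frame with one row per family size: `h`, level-1/2 edge
#'   counts, cluster count, and the termination F1 against `h - d` (NA when
#'   no comparison was possible).
#' @slot h family size at termination.
#' @slot converged FALSE when the loop hit `hMax` without meeting the
#'   termination condition.
#' @slot param the [CoreClustParam] used.
#' @seealso [runCoreClust()]
#' @exportClass CoreClustResult
setClass("CoreClustResult",
  representation(regionClusters = "Clustering", proteinClusters = "Clustering",
                 trace = "data.frame", h = "integer", converged = "logical",
                 param = "CoreClustParam"))

#' Specification of a synthetic protein-family data set
#'
#' Describes families of mutated copies of a shared consensus implanted
#' into random background proteins; see [generateSynthetic()]. Defaults are
#' the validation conditions used throughout this package: 20 families of
#' 30 copies, 120-residue regions, 5\% per-site substitution rate, one
#' two-family multi-domain architecture.
#'
#' @slot nFamilies number of domain families.
#' @slot copiesPerFamily mutated copies drawn per family.
#' @slot regionLength consensus length in residues.
#' @slot mutationRate per-site substitution probability in [0, 1).
#' @slot nProteins number of background host proteins.
#' @slot proteinLength length of each host protein.
#' @slot architectures list of integer vectors; each vector of family
#'   indices yields one extra protein carrying one fresh copy of every
#'   listed family (a multi-domain architecture).
#' @slot seed RNG seed.
#' @seealso [synthSpec()], [generateSynthetic()]
#' @exportClass SynthSpec
setClass("SynthSpec",
  representation(nFamilies = "integer", copiesPerFamily = "integer",
                 regionLength = "integer", mutationRate = "numeric",
                 nProteins = "integer", proteinLength = "integer",
                 architectures = "list", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@mutationRate < 0 || object@mutationRate >= 1)
      msg <- c(msg, "mutationRate must be in [0, 1)")
    if (object@regionLength < 1L) msg <- c(msg, "regionLength must be >= 1")
    if (object@proteinLength < object@regionLength)
      msg <- c(msg, "proteinLength must be >= regionLength")
    if (length(object@architectures) &&
        any(vapply(object@architectures,
                   function(a) any(a < 1L | a > object@nFamilies), logical(1))))
      msg <- c(msg, "architecture family index out of range")
    if (is.null(msg)) TRUE else msg
  })
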