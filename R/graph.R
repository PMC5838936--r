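# Similarity-graph construction from (k,c)-sketch buckets, at both levels,
# with an incremental sketch store for growing hash families.

#' @importFrom GenomicRanges seqnames
#' @importFrom S4Vectors mcols
NULL

# Normalize region input to a named character vector of sequences.
# Accepts a GRanges with names (region ids) and a `sequence` metadata
# column (as produced by readRegions/generateSynthetic), or a named
# character vector directly.
.regionSeqs <- function(regions) {
  if (is(regions, "GRanges")) {
    ids <- names(regions)
    if (is.null(ids)) stop("region GRanges must be named by region id")
    seqs <- S4Vectors::mcols(regions)$sequence
    if (is.null(seqs)) stop("region GRanges must carry a 'sequence' column")
    return(stats::setNames(as.character(seqs), ids))
  }
  if (is.character(regions)) {
    if (is.null(names(regions)) || anyDuplicated(names(regions)))
      stop("regions must be uniquely named by region id")
    return(regions)
  }
  stop("unsupported region container; use a GRanges or named character vector")
}

# Map of region id -> protein id, when the container knows it.
.regionProteins <- function(regions) {
  if (is(regions, "GRanges"))
    return(stats::setNames(as.character(GenomicRanges::seqnames(regions)),
                           names(regions)))
  NULL
}

#' Construct a similarity graph explicitly
#'
#' Builds a [SimilarityGraph] from node identifiers and an edge matrix,
#' canonicalising edge order and dropping duplicates. Mostly useful for
#' tests and small worked examples; pipelines use [firstLevelGraph()] and
#' [secondLevelGraph()].
#'
#' @param nodes character vector of node ids.
#' @param edgeMat two-column character matrix (or empty) of edges.
#' @return a [SimilarityGraph].
#' @export
similarityGraph <- function(nodes, edgeMat = NULL) {
  nodes <- sort(unique(as.character(nodes)))
  if (is.null(edgeMat) || NROW(edgeMat) == 0L)
    return(new("SimilarityGraph", nodes = nodes, edgeFrom = character(0),
               edgeTo = character(0), provenance = list()))
  reg <- stats::setNames(seq_along(nodes), nodes)
  i <- reg[as.character(edgeMat[, 1])]
  j <- reg[as.character(edgeMat[, 2])]
  if (anyNA(i) || anyNA(j)) stop("edge endpoint not among nodes")
  codes <- sort(unique(.pairCode(i, j, length(nodes))))
  .graphFromCodes(nodes, codes)
}

.graphFromCodes <- function(ids, codes, provByEdge = list()) {
  if (length(codes) == 0L)
    return(new("SimilarityGraph", nodes = ids, edgeFrom = character(0),
               edgeTo = character(0), provenance = provByEdge))
  pm <- .decodePairs(codes, length(ids))
  new("SimilarityGraph", nodes = ids, edgeFrom = ids[pm[, 1]],
      edgeTo = ids[pm[, 2]], provenance = provByEdge)
}

#' @rdname graph-accessors
#' @export
setMethod("nodes", "SimilarityGraph", function(x, ...) x@nodes)

#' @rdname graph-accessors
#' @export
setMethod("edges", "SimilarityGraph", function(x, ...) {
  cbind(from = x@edgeFrom, to = x@edgeTo)
})

#' @describeIn graph-accessors number of edges of a [SimilarityGraph].
#' @export
numEdges <- function(x) {
  stopifnot(is(x, "SimilarityGraph"))
  length(x@edgeFrom)
}

#' @describeIn graph-accessors named list of neighbor-id sets (sorted), one
#'   per node; isolated nodes get `character(0)`.
#' @export
neighborSets <- function(x) {
  stopifnot(is(x, "SimilarityGraph"))
  nb <- stats::setNames(rep(list(character(0)), length(x@nodes)), x@nodes)
  if (length(x@edgeFrom)) {
    half <- split(c(x@edgeTo, x@edgeFrom), c(x@edgeFrom, x@edgeTo))
    nb[names(half)] <- lapply(half, sort)
  }
  nb
}

setMethod("show", "SimilarityGraph", function(object) {
  cat(sprintf("SimilarityGraph: %d nodes, %d edges\n",
              length(object@nodes), length(object@edgeFrom)))
})

# Per-function bucketing: regions with identical sketch keys form a bucket;
# every bucket of size >= 2 contributes all pairwise edges (a clique).
# Returns pair codes on the registry 1..n. Buckets over 1e4 members are
# legal but quadratic, so they are flagged.
.bucketEdges <- function(keys, n) {
  buckets <- split(seq_len(n), keys)   # split() drops NA keys
  buckets <- buckets[lengths(buckets) >= 2L]
  if (length(buckets) == 0L) return(numeric(0))
  big <- lengths(buckets) > 10000L
  if (any(big))
    warning(sprintf("sketch bucket with %d members; edge generation is quadratic",
                    max(lengths(buckets))))
  out <- lapply(buckets, function(b) {
    pr <- utils::combn(b, 2L)
    .pairCode(pr[1L, ], pr[2L, ], n)
  })
  unique(unlist(out, use.names = FALSE))
}

# Shared core: graph from a list of term sets and a list of hash functions.
# Returns codes per function (list) so callers can track provenance or
# cache increments.
.codesPerFunction <- function(termsets, fns, c) {
  n <- length(termsets)
  lapply(fns, function(fn) .bucketEdges(.sketchKeys(termsets, fn, c), n))
}

.provenanceFromCodes <- function(codesByFn, allCodes) {
  idx <- lapply(codesByFn, function(co) match(co, allCodes))
  prov <- vector("list", length(allCodes))
  for (f in seq_along(idx))
    for (e in idx[[f]]) prov[[e]] <- c(prov[[e]], f)
  prov
}

#' First-level similarity graph from region k-mer sketches
#'
#' For each hash function independently, every region's k-mer set is
#' reduced to its (k,c)-sketch and regions are bucketed by the exact sketch
#' tuple; each bucket of two or more regions contributes all pairwise edges.
#' Buckets from different hash functions never merge before edge
#' generation; the union over functions is consolidated into a simple
#' graph. Regions shorter than `k` have no sketch and stay isolated.
#'
#' @param regions a GRanges from [readRegions()]/[generateSynthetic()], or a
#'   named character vector of region sequences.
#' @param family a [HashFamily] (or list of [HashFn], e.g. injected
#'   [tableHash()] functions operating on k-mer codes).
#' @param k k-mer length (default 6).
#' @param c sketch width (default 2).
#' @param provenance record, per edge, the indices of the hash functions
#'   that generated it (default FALSE).
#' @param termSets for expert use: bypass `regions`/`k` and supply the term
#'   sets directly as a named list of numeric vectors.
#' @return a [SimilarityGraph] whose nodes are all region ids.
#' @seealso [secondLevelGraph()], [buildSimilarityGraphs()]
#' @export
firstLevelGraph <- function(regions, family, k = 6L, c = 2L,
                            provenance = FALSE, termSets = NULL) {
  if (is.null(termSets)) {
    seqs <- .regionSeqs(regions)
    ids <- sort(names(seqs))
    termSets <- lapply(seqs[ids], kmerSet, k = k)
  } else {
    stopifnot(!is.null(names(termSets)))
    ids <- sort(names(termSets))
    termSets <- termSets[ids]
  }
  fns <- if (is(family, "HashFamily")) family@functions else family
  if (length(fns) == 0L) stop("hash family must be non-empty")
  if (all(lengths(termSets) == 0L))
    warning("no region yields any k-mer; graph is empty")
  codesByFn <- .codesPerFunction(termSets, fns, c)
  allCodes <- sort(unique(unlist(codesByFn, use.names = FALSE)))
  prov <- if (provenance) .provenanceFromCodes(codesByFn, allCodes) else list()
  .graphFromCodes(ids, allCodes, prov)
}

#' Second-level similarity graph from neighbor-set sketches
#'
#' Each node's term set is its set of neighbors in the first-level graph
#' (node names mapped to integers through a fixed sorted registry); term
#' sets are sketched, bucketed and cliqued per hash function exactly as at
#' level 1. The second-level family must differ from the first (a distinct
#' seed). Isolated nodes have an empty term set, hence no sketch, and
#' remain isolated.
#'
#' @param g a first-level [SimilarityGraph].
#' @param family a [HashFamily] (or list of [HashFn]) distinct from the
#'   level-1 family; table hashes must cover the registry codes
#'   `seq_along(sort(nodes(g)))`.
#' @param c sketch width (default 2).
#' @param provenance as in [firstLevelGraph()].
#' @return a [SimilarityGraph] on the same node set.
#' @export
secondLevelGraph <- function(g, family, c = 2L, provenance = FALSE) {
  stopifnot(is(g, "SimilarityGraph"))
  ids <- g@nodes
  reg <- stats::setNames(seq_along(ids), ids)
  nb <- neighborSets(g)
  termSets <- lapply(nb[ids], function(x) unname(reg[x]))
  fns <- if (is(family, "HashFamily")) family@functions else family
  if (length(fns) == 0L) stop("hash family must be non-empty")
  codesByFn <- .codesPerFunction(termSets, fns, c)
  allCodes <- sort(unique(unlist(codesByFn, use.names = FALSE)))
  prov <- if (provenance) .provenanceFromCodes(codesByFn, allCodes) else list()
  .graphFromCodes(ids, allCodes, prov)
}

## ---- incremental pipeline -------------------------------------------------

# The store environment caches, for the current family prefix of size h:
#   ids, N, registry      sorted region ids and their integer codes
#   termsets              k-mer term sets per region (fixed)
#   l1keys[[f]]           level-1 sketch key per region, function f
#   l1codesByFn[[f]]      level-1 edge codes contributed by function f
#   l1codes               cumulative level-1 edge codes (sorted)
#   nbrs[[i]]             neighbor registry codes of node i (the snapshot
#                         level-2 sketches were computed from)
#   l2keys[[f]]           level-2 sketch key per node, function f
#   l2codesByFn[[f]]      level-2 edge codes per function
#   k, c, prime, seed

.initStore <- function(regions, k, c, prime, seed) {
  seqs <- .regionSeqs(regions)
  ids <- sort(names(seqs))
  st <- new.env(parent = emptyenv())
  st$ids <- ids
  st$N <- length(ids)
  st$registry <- stats::setNames(seq_along(ids), ids)
  st$termsets <- lapply(seqs[ids], kmerSet, k = k)
  st$l1keys <- list()
  st$l1codesByFn <- list()
  st$l1codes <- numeric(0)
  st$nbrs <- rep(list(integer(0)), length(ids))
  st$l2keys <- list()
  st$l2codesByFn <- list()
  st$h <- 0L
  st$k <- as.integer(k); st$c <- as.integer(c)
  st$prime <- prime; st$seed <- as.integer(seed)
  st
}

.cloneStore <- function(st) {
  as.environment(as.list(st, all.names = TRUE))
}

# Grow the store from its current family size to newH. Level-1 sketches are
# computed only for the added functions (the family prefix property
# guarantees functions 1..h are unchanged). Level-2 sketches are recomputed,
# for all functions, only for nodes whose level-1 neighbor set changed; the
# added functions are evaluated for every node.
.growStore <- function(st, newH) {
  oldH <- st$h
  if (newH < oldH) stop("cannot shrink a sketch store")
  if (newH == oldH) return(invisible(st))
  fam1 <- makeHashFamily(newH, st$prime, st$seed)
  fam2 <- makeHashFamily(newH, st$prime, st$seed + 1L)
  if (oldH > 0L) {
    # guard against a store built under different parameters
    chk <- .sketchKeys(st$termsets, fam1@functions[[1L]], st$c)
    if (!identical(chk, st$l1keys[[1L]]))
      stop("sketch store is inconsistent with the hash-family prefix")
  }
  newIdx <- seq.int(oldH + 1L, newH)
  for (f in newIdx) {
    st$l1keys[[f]] <- .sketchKeys(st$termsets, fam1@functions[[f]], st$c)
    st$l1codesByFn[[f]] <- .bucketEdges(st$l1keys[[f]], st$N)
  }
  addedCodes <- setdiff(unique(unlist(st$l1codesByFn[newIdx], use.names = FALSE)),
                        st$l1codes)
  st$l1codes <- sort(c(st$l1codes, addedCodes))

  # refresh neighbor snapshots for endpoints of new level-1 edges
  changed <- integer(0)
  if (length(addedCodes)) {
    pm <- .decodePairs(addedCodes, st$N)
    changed <- sort(unique(c(pm[, 1], pm[, 2])))
    allPairs <- .decodePairs(st$l1codes, st$N)
    touch <- allPairs[, 1] %in% changed | allPairs[, 2] %in% changed
    sub <- allPairs[touch, , drop = FALSE]
    for (i in changed) st$nbrs[[i]] <- integer(0)
    if (nrow(sub)) {
      half <- split(c(sub[, 2], sub[, 1]), c(sub[, 1], sub[, 2]))
      for (nm in names(half)) {
        i <- as.integer(nm)
        if (i %in% changed) st$nbrs[[i]] <- sort(unique(half[[nm]]))
      }
    }
  }

  # level-2: changed nodes for existing functions, all nodes for new ones
  dirtyCols <- integer(0)
  if (length(changed) && oldH > 0L) {
    for (f in seq_len(oldH)) {
      ks <- st$l2keys[[f]]
      newKeys <- vapply(changed, function(i)
        .sketchKey(sketchOf(st$nbrs[[i]], fam2@functions[[f]], st$c)),
        character(1))
      if (!identical(unname(ks[changed]), newKeys)) {
        ks[changed] <- newKeys
        st$l2keys[[f]] <- ks
        dirtyCols <- c(dirtyCols, f)
      }
    }
  }
  for (f in newIdx) {
    st$l2keys[[f]] <- vapply(seq_len(st$N), function(i)
      .sketchKey(sketchOf(st$nbrs[[i]], fam2@functions[[f]], st$c)),
      character(1))
    dirtyCols <- c(dirtyCols, f)
  }
  for (f in dirtyCols)
    st$l2codesByFn[[f]] <- .bucketEdges(st$l2keys[[f]], st$N)
  st$h <- as.integer(newH)
  invisible(st)
}

.graphsFromStore <- function(st) {
  l1 <- .graphFromCodes(st$ids, st$l1codes)
  l2codes <- sort(unique(unlist(st$l2codesByFn, use.names = FALSE)))
  l2 <- .graphFromCodes(st$ids, l2codes)
  new("CoreGraphs", level1 = l1, level2 = l2, h = st$h, store = st)
}

#' Build both similarity graphs with an incremental sketch store
#'
#' Computes the level-1 (k-mer sketch) and level-2 (neighbor-set sketch)
#' similarity graphs for a hash family of size `h`, caching every sketch so
#' that [extendSimilarityGraphs()] can grow the family without recomputing
#' them. The level-2 family is derived from `seed + 1` so the two levels
#' use different hash functions.
#'
#' @inheritParams firstLevelGraph
#' @param h hash-family size.
#' @param prime prime modulus (default `2^31 - 1`).
#' @param seed RNG seed of the level-1 family.
#' @return a [CoreGraphs] object.
#' @examples
#' regs <- c(r1 = "MKVLLAGRSTWQ", r2 = "MKVLLAGRSTWQ", r3 = "PPPQQQRRRSSS")
#' cg <- buildSimilarityGraphs(regs, h = 5, seed = 1)
#' edges(cg@level1)
#' @export
buildSimilarityGraphs <- function(regions, h, k = 6L, c = 2L,
                                  prime = 2147483647, seed = 1L) {
  h <- .assertCount(h, "h")
  st <- .initStore(regions, k, c, prime, seed)
  .growStore(st, h)
  .graphsFromStore(st)
}

#' Extend similarity graphs to a larger hash family
#'
#' Grows the hash family of a [CoreGraphs] object from its current size to
#' `h`, reusing all cached sketches: level-1 sketches are computed only for
#' the added functions (the level-1 edge set can only grow), and level-2
#' sketches are recomputed, across all functions, only for nodes whose
#' neighbor set gained a member. The result is identical to a from-scratch
#' [buildSimilarityGraphs()] at size `h` with the same seeds.
#'
#' @param x a [CoreGraphs] object.
#' @param h new family size, `>=` the current one (equal is a no-op).
#' @return a new [CoreGraphs]; `x` is left untouched.
#' @export
extendSimilarityGraphs <- function(x, h) {
  stopifnot(is(x, "CoreGraphs"))
  h <- .assertCount(h, "h")
  if (h < x@h) stop("new family size must be >= the current one")
  if (h == x@h) return(x)
  st <- .cloneStore(x@store)
  .growStore(st, h)
  .graphsFromStore(st)
}

#' Write a similarity graph as an edge-list TSV
#'
#' One `node<TAB>node` row per edge, canonical order; a debugging aid.
#'
#' @param g a [SimilarityGraph].
#' @param path output file path.
#' @export
writeGraph <- function(g, path) {
  stopifnot(is(g, "SimilarityGraph"))
  utils::write.table(edges(g), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
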