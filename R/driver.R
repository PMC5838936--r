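# The iterative clustering driver: grow the hash family, rebuild graphs
# incrementally, cluster with Louvain, and stop when the clustering has
# stabilised relative to the one obtained d hash functions earlier.

#' Driver parameters
#'
#' Constructor for [CoreClustParam]; see that class for the meaning and
#' defaults of every field.
#'
#' @param k,c,hStart,hStep,d,tau,hMax,minClusterSize,louvainThreshold,prime,seed
#'   see [CoreClustParam].
#' @return a [CoreClustParam].
#' @export
coreClustParam <- function(k = 6L, c = 2L, hStart = 41L, hStep = 1L, d = 40L,
                           tau = 0.9, hMax = 500L, minClusterSize = 10L,
                           louvainThreshold = 1e-7, prime = 2147483647,
                           seed = 1L) {
  new("CoreClustParam", k = .assertCount(k, "k"), c = .assertCount(c, "c"),
      hStart = .assertCount(hStart, "hStart"),
      hStep = .assertCount(hStep, "hStep"), d = .assertCount(d, "d"),
      tau = tau, hMax = .assertCount(hMax, "hMax"),
      minClusterSize = .assertCount(minClusterSize, "minClusterSize"),
      louvainThreshold = louvainThreshold, prime = prime,
      seed = as.integer(seed))
}

setMethod("show", "CoreClustResult", function(object) {
  cat(sprintf(paste0("CoreClustResult: %d region clusters at h = %d (%s)\n"),
              nClusters(object@regionClusters), object@h,
              if (object@converged) "converged" else "NOT converged"))
  if (nClusters(object@proteinClusters))
    cat(sprintf("  %d protein clusters (overlapping)\n",
                nClusters(object@proteinClusters)))
})

# Louvain communities of the level-2 graph as a region clustering;
# isolated nodes come out as singleton clusters.
.clusterGraphs <- function(cg, param, h) {
  louvainCluster(cg@level2, threshold = param@louvainThreshold,
                 seed = param@seed + 7919L + h)
}

#' Iterative region clustering
#'
#' Runs the full pipeline on a set of conserved regions. Similarity graphs
#' are built for a growing family of hash functions, starting at
#' `hStart - d` so that every comparison partner exists, and extended
#' incrementally by `hStep`. At each family size `h` the level-2 graph is
#' clustered with Louvain; from `h = hStart` on, the clustering is compared
#' (average weighted F1 on clusters of at least `minClusterSize` regions)
#' with the one obtained at `h - d`, and the loop stops as soon as the
#' score strictly exceeds `tau` - the last generated clustering is the
#' output. If `hMax` is reached first, the result is flagged
#' non-converged. The termination check always uses the non-overlapping
#' region clusters; protein clusters are derived afterwards.
#'
#' @param regions a GRanges from [readRegions()]/[generateSynthetic()] (or
#'   a named character vector of region sequences, in which case protein
#'   clusters are skipped unless `regionProteins` is given).
#' @param param a [CoreClustParam].
#' @param regionProteins optional named character vector mapping region id
#'   to parent protein id; inferred automatically from a GRanges.
#' @param verbose print a per-iteration trace line (default FALSE).
#' @return a [CoreClustResult].
#' @examples
#' d <- generateSynthetic(synthSpec(nFamilies = 3, copiesPerFamily = 8,
#'                                  regionLength = 60, nProteins = 30,
#'                                  proteinLength = 120, seed = 5))
#' res <- runCoreClust(d$regions,
#'                     coreClustParam(hStart = 11, d = 10, minClusterSize = 5,
#'                                    seed = 5))
#' res@converged
#' @export
runCoreClust <- function(regions, param = coreClustParam(),
                         regionProteins = NULL, verbose = FALSE) {
  stopifnot(is(param, "CoreClustParam"))
  seqs <- .regionSeqs(regions)
  if (length(seqs) < 2L) stop("need at least two regions to cluster")
  if (is.null(regionProteins)) regionProteins <- .regionProteins(regions)

  h0 <- param@hStart - param@d      # warm-up start; >= 1 by param validity
  cg <- buildSimilarityGraphs(seqs, h = h0, k = param@k, c = param@c,
                              prime = param@prime, seed = param@seed)
  history <- new.env(parent = emptyenv())
  keepBack <- max(param@d, 60L)
  trace <- list()
  h <- h0
  converged <- FALSE
  cl <- NULL
  repeat {
    cl <- .clusterGraphs(cg, param, h)
    assign(as.character(h), cl, envir = history)
    rm(list = ls(history)[as.integer(ls(history)) < h - keepBack],
       envir = history)
    f1 <- NA_real_
    partner <- as.character(h - param@d)
    if (h >= param@hStart && exists(partner, envir = history)) {
      cmp <- f1Average(cl, get(partner, envir = history),
                       minSize = param@minClusterSize)
      f1 <- cmp@f1Avg
    }
    trace[[length(trace) + 1L]] <-
      data.frame(h = h, edges1 = numEdges(cg@level1),
                 edges2 = numEdges(cg@level2),
                 nClusters = nClusters(cl), f1 = f1)
    if (verbose)
      message(sprintf("h=%d: %d/%d edges, %d clusters, f1=%s", h,
                      numEdges(cg@level1), numEdges(cg@level2), nClusters(cl),
                      ifelse(is.na(f1), "-", sprintf("%.4f", f1))))
    if (!is.na(f1) && f1 > param@tau) {
      converged <- TRUE
      break
    }
    if (h >= param@hMax) {
      warning(sprintf("hit hMax = %d without meeting the termination condition",
                      param@hMax))
      break
    }
    h <- min(h + param@hStep, param@hMax)
    cg <- extendSimilarityGraphs(cg, h)
  }

  protCl <- new("Clustering", clusters = structure(list(), names = character(0)),
                overlapping = TRUE)
  if (!is.null(regionProteins))
    protCl <- extendToProteins(cl, regionProteins)
  new("CoreClustResult", regionClusters = cl, proteinClusters = protCl,
      trace = do.call(rbind, trace), h = as.integer(h), converged = converged,
      param = param)
}

#' Extend region clusters to (possibly overlapping) protein clusters
#'
#' Replaces each conserved region in a cluster by its originating protein
#' and deduplicates within each cluster. A protein whose regions fall into
#' different clusters appears in each of them, so the result may overlap;
#' the number of clusters is preserved.
#'
#' @param x a region [Clustering].
#' @param regions the region container the clustering was computed from (a
#'   named GRanges), or a named character vector mapping region id to
#'   protein id.
#' @return an overlapping [Clustering] of protein ids.
#' @export
extendToProteins <- function(x, regions) {
  stopifnot(is(x, "Clustering"))
  map <- if (is.character(regions)) regions else .regionProteins(regions)
  if (is.null(map) || is.null(names(map)))
    stop("need a named region-to-protein map")
  cl <- lapply(x@clusters, function(members) {
    p <- map[members]
    if (anyNA(p))
      stop(sprintf("unknown region id(s): %s",
                   paste(members[is.na(p)], collapse = ", ")))
    sort(unique(unname(p)))
  })
  new("Clustering", clusters = cl, overlapping = TRUE)
}
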