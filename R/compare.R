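# Size-weighted, two-sided F1 comparison of clusterings; also the
# termination statistic of the iterative driver.

#' Construct a clustering
#'
#' @param clusters named list of character vectors (cluster label to member
#'   ids); members within a cluster must be unique, clusters non-empty.
#' @param overlapping whether a member may appear in several clusters
#'   (protein clusters); defaults to FALSE (region partitions).
#' @return a [Clustering].
#' @examples
#' Clustering(list(c0 = c("a", "b"), c1 = c("c", "d")))
#' @export
Clustering <- function(clusters, overlapping = FALSE) {
  clusters <- lapply(clusters, as.character)
  new("Clustering", clusters = clusters, overlapping = overlapping)
}

#' @rdname graph-accessors
#' @export
setMethod("clusters", "Clustering", function(x, ...) x@clusters)

#' @describeIn graph-accessors number of clusters.
#' @export
nClusters <- function(x) {
  stopifnot(is(x, "Clustering"))
  length(x@clusters)
}

setMethod("show", "Clustering", function(object) {
  sz <- lengths(object@clusters)
  cat(sprintf("Clustering: %d clusters, %d memberships%s\n",
              length(sz), sum(sz),
              if (object@overlapping) " (overlapping)" else ""))
  if (length(sz))
    cat(sprintf("  sizes: min %d / median %s / max %d\n",
                min(sz), format(stats::median(sz)), max(sz)))
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf(paste0("ComparisonResult: F1 = %.4f%s\n",
                     "  X->Y precision %.4f recall %.4f F1 %.4f\n",
                     "  Y->X precision %.4f recall %.4f F1 %.4f\n"),
              object@f1Avg, if (object@degenerate) " (degenerate)" else "",
              object@precisionXY, object@recallXY, object@f1XY,
              object@precisionYX, object@recallYX, object@f1YX))
})

#' Drop clusters below a minimum size
#'
#' Clusters with fewer members than `minSize` are removed outright; their
#' members do not re-enter other clusters. All F1 computations here apply
#' this filter with `minSize = 10` by default at the driver level, so that
#' tiny clusters do not dominate the comparison.
#'
#' @param x a [Clustering].
#' @param minSize smallest retained cluster size (`>= 1`).
#' @return a [Clustering]; possibly empty.
#' @examples
#' cl <- Clustering(list(a = as.character(1:12), b = as.character(20:28)))
#' nClusters(filterClusters(cl, 10))  # 1
#' @export
filterClusters <- function(x, minSize) {
  stopifnot(is(x, "Clustering"))
  minSize <- .assertCount(minSize, "minSize")
  keep <- lengths(x@clusters) >= minSize
  new("Clustering", clusters = x@clusters[keep], overlapping = x@overlapping)
}

# Core one-sided computation on plain lists of member vectors.
.f1Sided <- function(X, Y) {
  sizeX <- unname(lengths(X))
  sizeY <- unname(lengths(Y))
  yMembers <- unlist(Y, use.names = FALSE)
  yIndex <- rep(seq_along(Y), sizeY)
  memberMap <- split(yIndex, yMembers)
  precN <- 0; recN <- 0
  for (i in seq_along(X)) {
    hits <- unlist(memberMap[X[[i]]], use.names = FALSE)
    if (length(hits)) {
      cnt <- tabulate(hits, nbins = length(Y))
      nz <- which(cnt > 0L)
      prec <- max(cnt[nz] / sizeY[nz])
      rec <- max(cnt[nz]) / sizeX[i]
    } else {
      prec <- 0; rec <- 0
    }
    precN <- precN + sizeX[i] * prec
    recN <- recN + sizeX[i] * rec
  }
  tot <- sum(sizeX)
  precision <- precN / tot
  recall <- recN / tot
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' One-sided weighted F1 between two clusterings
#'
#' For each cluster \eqn{X_i}, the best counterpart in \eqn{Y} is taken
#' separately for precision and recall:
#' \deqn{precision(X \to Y) = \frac{\sum_i |X_i| \max_j |X_i \cap Y_j| / |Y_j|}
#'       {\sum_i |X_i|}, \quad
#'       recall(X \to Y) = \frac{\sum_i |X_i| \max_j |X_i \cap Y_j| / |X_i|}
#'       {\sum_i |X_i|}}
#' and F1 is their harmonic mean (0 when both are 0). Weights make larger
#' clusters count more. Overlapping clusterings are accepted; the formulas
#' involve only set sizes and intersections.
#'
#' @param x,y [Clustering] objects (apply [filterClusters()] first if a
#'   minimum size is wanted); `x` must be non-empty.
#' @return named numeric vector `precision`, `recall`, `f1`.
#' @examples
#' X <- Clustering(list(a = c("a", "b"), b = c("c", "d")))
#' Y <- Clustering(list(u = c("a", "b", "c", "d")))
#' f1OneSided(X, Y)  # precision 0.5, recall 1, f1 2/3
#' @export
f1OneSided <- function(x, y) {
  stopifnot(is(x, "Clustering"), is(y, "Clustering"))
  if (nClusters(x) == 0L)
    stop("comparison undefined: left-hand clustering is empty")
  .f1Sided(x@clusters, y@clusters)
}

#' Average weighted F1 between two clusterings
#'
#' Both one-sided F1 scores are computed after filtering each clustering at
#' `minSize`, and averaged: \eqn{F1 = (F1_{X \to Y} + F1_{Y \to X}) / 2}.
#' The two-sided average guards against trivially over-complete clusterings
#' scoring perfectly one-sided. If either side is empty after filtering the
#' result is flagged degenerate and the average F1 is 0.
#'
#' @param x,y [Clustering] objects.
#' @param minSize minimum cluster size applied to both sides before either
#'   direction is computed (default 1 = no filtering).
#' @return a [ComparisonResult].
#' @examples
#' X <- Clustering(list(a = c("a", "b"), b = c("c", "d")))
#' Y <- Clustering(list(u = c("a", "b", "c", "d")))
#' f1Average(X, Y)@f1Avg  # 2/3
#' @export
f1Average <- function(x, y, minSize = 1L) {
  stopifnot(is(x, "Clustering"), is(y, "Clustering"))
  xf <- filterClusters(x, minSize)
  yf <- filterClusters(y, minSize)
  if (nClusters(xf) == 0L || nClusters(yf) == 0L)
    return(new("ComparisonResult", precisionXY = 0, recallXY = 0, f1XY = 0,
               precisionYX = 0, recallYX = 0, f1YX = 0, f1Avg = 0,
               degenerate = TRUE))
  xy <- .f1Sided(xf@clusters, yf@clusters)
  yx <- .f1Sided(yf@clusters, xf@clusters)
  new("ComparisonResult",
      precisionXY = unname(xy["precision"]), recallXY = unname(xy["recall"]),
      f1XY = unname(xy["f1"]),
      precisionYX = unname(yx["precision"]), recallYX = unname(yx["recall"]),
      f1YX = unname(yx["f1"]),
      f1Avg = unname((xy["f1"] + yx["f1"]) / 2), degenerate = FALSE)
}

#' Best-match report between two clusterings
#'
#' For each cluster of `x`, the cluster of `y` maximizing the intersection,
#' with the two containment fractions. A small debugging aid for inspecting
#' how one clustering refines another.
#'
#' @inheritParams f1OneSided
#' @return data.frame with columns `cluster`, `size`, `best`, `bestSize`,
#'   `intersection`, `fracOfX`, `fracOfY`.
#' @export
bestMatches <- function(x, y) {
  stopifnot(is(x, "Clustering"), is(y, "Clustering"))
  X <- x@clusters; Y <- y@clusters
  sizeY <- lengths(Y)
  yMembers <- unlist(Y, use.names = FALSE)
  yIndex <- rep(seq_along(Y), sizeY)
  memberMap <- split(yIndex, yMembers)
  rows <- lapply(seq_along(X), function(i) {
    hits <- unlist(memberMap[X[[i]]], use.names = FALSE)
    if (!length(hits))
      return(data.frame(cluster = names(X)[i], size = length(X[[i]]),
                        best = NA_character_, bestSize = NA_integer_,
                        intersection = 0L, fracOfX = 0, fracOfY = 0))
    cnt <- tabulate(hits, nbins = length(Y))
    j <- which.max(cnt)
    data.frame(cluster = names(X)[i], size = length(X[[i]]),
               best = names(Y)[j], bestSize = sizeY[j],
               intersection = cnt[j],
               fracOfX = cnt[j] / length(X[[i]]),
               fracOfY = cnt[j] / sizeY[j])
  })
  do.call(rbind, rows)
}
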