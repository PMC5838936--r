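# Louvain community detection driven by the modularity of a partition.

# Weighted modularity on an edge list. Non-loop edges appear once with
# from < to; self-loops (from == to) carry the aggregated intra-community
# weight and count twice in a node's degree, which is what makes the
# modularity of an aggregated graph equal that of the flat graph.
.modularityW <- function(n, from, to, w, memb) {
  m <- sum(w)
  if (m == 0) return(0)
  loops <- from == to
  deg <- numeric(n)
  ends <- c(from[!loops], to[!loops], from[loops], from[loops])
  wts <- c(w[!loops], w[!loops], w[loops], w[loops])  # loops count twice
  if (length(ends)) {
    s <- rowsum(wts, ends)
    deg[as.integer(rownames(s))] <- s[, 1]
  }
  intra <- sum(w[memb[from] == memb[to]])
  degC <- rowsum(deg, memb)
  intra / m - sum((degC / (2 * m))^2)
}

#' Modularity of a partition of a similarity graph
#'
#' Evaluates
#' \deqn{Q = \frac{1}{2m}\sum_{i \in V} e_{i\to C(i)} -
#'       \sum_{C \in P} \left(\frac{a_C}{2m}\right)^2}
#' where \eqn{m} is the total edge weight (1 per edge here), \eqn{e_{i\to
#' C(i)}} sums the edges between node \eqn{i} and its own community, and
#' \eqn{a_C} is the total degree of community \eqn{C}. The single-community
#' partition always scores 0; an edgeless graph is defined to score 0.
#'
#' @param g a [SimilarityGraph].
#' @param partition a [Clustering] covering exactly the nodes of `g`, or a
#'   vector of community labels named by node.
#' @param ... unused.
#' @return a number in [-1, 1].
#' @examples
#' g <- similarityGraph(c("a", "b", "c"),
#'                      cbind(c("a", "b", "a"), c("b", "c", "c")))
#' modularity(g, c(a = 1, b = 1, c = 1))  # 0
#' @name modularity
#' @export
setMethod("modularity", "SimilarityGraph", function(g, partition, ...) {
  ids <- g@nodes
  memb <- .membershipVector(partition, ids)
  reg <- stats::setNames(seq_along(ids), ids)
  .modularityW(length(ids), unname(reg[g@edgeFrom]), unname(reg[g@edgeTo]),
               rep(1, length(g@edgeFrom)), memb)
})

.membershipVector <- function(partition, ids) {
  if (is(partition, "Clustering")) {
    if (partition@overlapping)
      stop("modularity requires a non-overlapping partition")
    memb <- rep(NA_integer_, length(ids))
    names(memb) <- ids
    for (i in seq_along(partition@clusters))
      memb[partition@clusters[[i]]] <- i
  } else {
    if (is.null(names(partition)))
      stop("partition vector must be named by node")
    memb <- as.integer(factor(partition[ids]))
    names(memb) <- ids
  }
  if (anyNA(memb))
    stop("partition must cover exactly the nodes of the graph")
  unname(memb)
}

# One Louvain local-move phase on an edge list with explicit self-loops.
# Nodes are visited in a seeded-shuffled order; a node moves to the
# neighboring community with the largest strictly positive net modularity
# gain (ties broken by the lowest community label); the phase stops when a
# full sweep gains less than `threshold` in total.
.localMove <- function(n, from, to, w, selfw, threshold, maxSweeps = 100L) {
  m <- sum(w) + sum(selfw)
  nb <- vector("list", n)
  nbw <- vector("list", n)
  if (length(from)) {
    ends <- c(from, to)
    oth <- c(to, from)
    ww <- c(w, w)
    o <- order(ends)
    sp <- split(seq_along(ends)[o], ends[o])
    for (nm in names(sp)) {
      i <- as.integer(nm)
      nb[[i]] <- oth[sp[[nm]]]
      nbw[[i]] <- ww[sp[[nm]]]
    }
  }
  deg <- vapply(seq_len(n), function(i) sum(nbw[[i]]), numeric(1)) + 2 * selfw
  memb <- seq_len(n)
  commTot <- deg
  nMoves <- 0L
  if (m == 0) return(list(memb = memb, nMoves = 0L))
  for (sweep in seq_len(maxSweeps)) {
    gainTotal <- 0
    movedThisSweep <- 0L
    ord <- sample.int(n)
    for (i in ord) {
      if (length(nb[[i]]) == 0L) next
      ci <- memb[i]
      ki <- deg[i]
      commTot[ci] <- commTot[ci] - ki
      ncomm <- memb[nb[[i]]]
      cand <- sort(unique(c(ci, ncomm)))
      kByC <- vapply(cand, function(cc) sum(nbw[[i]][ncomm == cc]), numeric(1))
      gain <- kByC / m - ki * commTot[cand] / (2 * m * m)
      best <- which.max(gain)           # first max = lowest label (cand sorted)
      stayGain <- gain[match(ci, cand)]
      target <- cand[best]
      if (target != ci && gain[best] > stayGain) {
        memb[i] <- target
        commTot[target] <- commTot[target] + ki
        gainTotal <- gainTotal + (gain[best] - stayGain)
        movedThisSweep <- movedThisSweep + 1L
        nMoves <- nMoves + 1L
      } else {
        commTot[ci] <- commTot[ci] + ki
      }
    }
    if (movedThisSweep == 0L || gainTotal < threshold) break
  }
  # compact labels
  memb <- match(memb, sort(unique(memb)))
  list(memb = memb, nMoves = nMoves)
}

# Aggregate communities into super-nodes: intra-community weight (plus
# existing loops) becomes self-loop weight, inter-community edges are
# summed.
.aggregate <- function(memb, from, to, w, selfw) {
  nC <- max(memb)
  cf <- pmin(memb[from], memb[to])
  ct <- pmax(memb[from], memb[to])
  selfAgg <- numeric(nC)
  if (length(selfw)) {
    s <- rowsum(selfw, memb)
    selfAgg[as.integer(rownames(s))] <- s[, 1]
  }
  intra <- cf == ct
  if (any(intra)) {
    s <- rowsum(w[intra], cf[intra])
    selfAgg[as.integer(rownames(s))] <- selfAgg[as.integer(rownames(s))] + s[, 1]
  }
  if (any(!intra)) {
    code <- (cf[!intra] - 1) * nC + ct[!intra]
    s <- rowsum(w[!intra], code)
    codes <- as.numeric(rownames(s))
    newFrom <- (codes - 1) %/% nC + 1
    newTo <- (codes - 1) %% nC + 1
    list(n = nC, from = newFrom, to = newTo, w = s[, 1], selfw = selfAgg)
  } else {
    list(n = nC, from = integer(0), to = integer(0), w = numeric(0),
         selfw = selfAgg)
  }
}

.louvain <- function(n, from, to, threshold, seed, maxLevels = 20L) {
  membGlobal <- seq_len(n)
  w <- rep(1, length(from))
  selfw <- numeric(n)
  nn <- n
  .withSeed(seed, {
    for (level in seq_len(maxLevels)) {
      res <- .localMove(nn, from, to, w, selfw, threshold)
      if (res$nMoves == 0L) break
      membGlobal <- res$memb[membGlobal]
      agg <- .aggregate(res$memb, from, to, w, selfw)
      if (agg$n == nn) break
      nn <- agg$n; from <- agg$from; to <- agg$to; w <- agg$w; selfw <- agg$selfw
    }
  })
  membGlobal
}

#' Louvain clustering of a similarity graph
#'
#' Greedy modularity optimization alternating a seeded local-move phase and
#' graph aggregation, following the standard Louvain scheme: each node is
#' relocated to the neighboring community with the largest positive
#' modularity gain (lowest label on ties), a phase ends when a full sweep
#' gains less than `threshold`, communities are then contracted to
#' super-nodes (intra-community edges become self-loops) and the process
#' repeats until no node moves. Identical inputs and seed give identical
#' output. Isolated nodes end up as singleton communities.
#'
#' Greedy local moves depend on the sweep order and can land in a local
#' optimum, especially on small graphs; `restarts` independent seeded runs
#' are performed and the partition with the highest modularity is kept
#' (ties go to the earliest run), which keeps the result deterministic
#' while largely removing sweep-order variance.
#'
#' @param g a [SimilarityGraph].
#' @param threshold per-sweep total-gain threshold (default 1e-7).
#' @param seed RNG seed for the sweep order.
#' @param maxLevels cap on aggregation levels (default 20).
#' @param restarts number of seeded runs to take the best of (default 5).
#' @return a non-overlapping [Clustering] of the graph nodes; cluster
#'   labels `c1, c2, ...` are assigned by each community's smallest node
#'   id. The achieved modularity is attached as attribute `"modularity"`
#'   of the returned object's cluster list.
#' @examples
#' g <- similarityGraph(letters[1:4],
#'                      cbind(c("a", "a", "c"), c("b", "b", "d"))[c(1, 3), ])
#' louvainCluster(g, seed = 1)
#' @export
louvainCluster <- function(g, threshold = 1e-7, seed = 1L, maxLevels = 20L,
                           restarts = 5L) {
  stopifnot(is(g, "SimilarityGraph"), threshold > 0, restarts >= 1L)
  ids <- g@nodes
  if (length(ids) == 0L)
    return(new("Clustering", clusters = structure(list(), names = character(0)),
               overlapping = FALSE))
  reg <- stats::setNames(seq_along(ids), ids)
  from <- unname(reg[g@edgeFrom])
  to <- unname(reg[g@edgeTo])
  w1 <- rep(1, length(from))
  memb <- NULL
  bestQ <- -Inf
  for (r in seq_len(restarts)) {
    m <- .louvain(length(ids), from, to, threshold, seed + (r - 1L) * 131L,
                  maxLevels)
    q <- .modularityW(length(ids), from, to, w1, m)
    if (q > bestQ) {
      bestQ <- q
      memb <- m
    }
  }
  comm <- split(seq_along(ids), memb)
  comm <- comm[order(vapply(comm, min, numeric(1)))]
  cl <- lapply(comm, function(ix) ids[sort(ix)])
  names(cl) <- paste0("c", seq_along(cl))
  out <- new("Clustering", clusters = cl, overlapping = FALSE)
  attr(out@clusters, "modularity") <- bestQ
  out
}
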