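# Independent oracles and fixture builders shared across tests.

# ---- worked example: 8 regions, 2 hash functions, c = 2 --------------------
# Terms are "colors" standing in for k-mers; the two table hashes realize the
# orderings h1: red<blue<green<gray<yellow<purple and
# h2: yellow<gray<red<green<blue<purple. The instance is constructed so that
# the first-level graph has s2 adjacent to exactly {s1, s6, s7} and the
# second level (h1': s6<s1<s7<s2<s3<s4, h2': s6<s7<s3<s4<s1<s2) produces the
# {s2, s3, s4} triangle through h1' and nothing through h2'.
fig1Fixture <- function() {
  col <- c(red = 1, blue = 2, green = 3, gray = 4, yellow = 5, purple = 6)
  termSets <- list(
    s1 = unname(col[c("red", "gray")]),
    s2 = unname(col[c("red", "green", "gray")]),
    s3 = unname(col[c("red", "gray", "yellow")]),
    s4 = unname(col[c("red", "gray", "yellow", "purple")]),
    s5 = unname(col["blue"]),
    s6 = unname(col[c("red", "green", "yellow", "gray")]),
    s7 = unname(col[c("red", "green")]),
    s8 = unname(col[c("blue", "purple")]))
  h1 <- tableHash(stats::setNames(1:6, col[c("red", "blue", "green", "gray",
                                             "yellow", "purple")]), index = 1L)
  h2 <- tableHash(stats::setNames(1:6, col[c("yellow", "gray", "red", "green",
                                             "blue", "purple")]), index = 2L)
  # second-level hashes on region registry codes 1..8 (sorted region ids)
  h1b <- tableHash(stats::setNames(c(2, 4, 5, 6, 7, 1, 3, 8),
                                   as.character(1:8)), index = 1L)
  h2b <- tableHash(stats::setNames(c(5, 6, 3, 4, 7, 1, 2, 8),
                                   as.character(1:8)), index = 2L)
  level1Edges <- rbind(c("s1", "s2"), c("s1", "s3"), c("s1", "s4"),
                       c("s2", "s6"), c("s2", "s7"), c("s3", "s4"),
                       c("s3", "s6"), c("s4", "s6"), c("s6", "s7"))
  level2Edges <- rbind(c("s2", "s3"), c("s2", "s4"), c("s3", "s4"))
  list(termSets = termSets, level1Family = list(h1, h2),
       level2Family = list(h1b, h2b), level1Edges = level1Edges,
       level2Edges = level2Edges)
}

edgeKeySet <- function(g) {
  e <- edges(g)
  sort(paste(e[, 1], e[, 2], sep = "--"))
}

# ---- brute-force pairwise sketch-comparison graph oracle -------------------
# Edge iff some hash function gives the two term sets identical non-empty
# sketch tuples; checked for every pair directly, no bucketing.
bruteSketchGraph <- function(termSets, fns, c) {
  ids <- sort(names(termSets))
  termSets <- termSets[ids]
  keys <- sapply(fns, function(fn)
    vapply(termSets, function(t) {
      sk <- sketchOf(t, fn, c)
      if (length(sk)) paste(sk, collapse = "|") else NA_character_
    }, character(1)))
  keys <- matrix(keys, nrow = length(ids))
  out <- NULL
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    same <- !is.na(keys[i, ]) & !is.na(keys[j, ]) & keys[i, ] == keys[j, ]
    if (any(same)) out <- rbind(out, c(ids[j], ids[i]))
  }
  if (is.null(out)) character(0) else sort(paste(out[, 1], out[, 2], sep = "--"))
}

# Oracle neighbor sets from an oracle edge key set.
bruteNeighborTerms <- function(ids, edgeKeys) {
  reg <- stats::setNames(seq_along(ids), ids)
  nb <- stats::setNames(rep(list(numeric(0)), length(ids)), ids)
  for (ek in edgeKeys) {
    p <- strsplit(ek, "--", fixed = TRUE)[[1]]
    nb[[p[1]]] <- c(nb[[p[1]]], reg[[p[2]]])
    nb[[p[2]]] <- c(nb[[p[2]]], reg[[p[1]]])
  }
  lapply(nb, function(x) sort(unique(x)))
}

# ---- modularity / partition oracles ----------------------------------------
# Direct evaluation of Q from an edge matrix and a membership vector named
# by node; loop-free graphs, unit weights.
modularityOracle <- function(nodeIds, edgeMat, memb) {
  m <- NROW(edgeMat)
  if (m == 0) return(0)
  mf <- memb[edgeMat[, 1]]
  mt <- memb[edgeMat[, 2]]
  deg <- table(factor(c(edgeMat[, 1], edgeMat[, 2]), levels = nodeIds))
  degC <- tapply(as.numeric(deg), memb[nodeIds], sum)
  sum(mf == mt) / m - sum((degC / (2 * m))^2)
}

# All set partitions of 1..n as membership vectors (restricted growth).
allPartitions <- function(n) {
  out <- list()
  rec <- function(memb, nextLab) {
    i <- length(memb) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- memb
      return(invisible())
    }
    for (lab in seq_len(nextLab))
      rec(c(memb, lab), max(nextLab, lab + 1L))
  }
  rec(integer(0), 1L)
  out
}

exhaustiveBestQ <- function(nodeIds, edgeMat) {
  parts <- allPartitions(length(nodeIds))
  best <- -Inf
  for (p in parts) {
    memb <- stats::setNames(p, nodeIds)
    q <- modularityOracle(nodeIds, edgeMat, memb)
    if (q > best) best <- q
  }
  best
}

# ---- F1 oracle -------------------------------------------------------------
# Literal double-loop evaluation of the displayed weighted formulas.
naiveF1Sided <- function(X, Y) {
  num_p <- 0; num_r <- 0; den <- 0
  for (Xi in X) {
    bestP <- 0; bestR <- 0
    for (Yj in Y) {
      inter <- length(intersect(Xi, Yj))
      bestP <- max(bestP, inter / length(Yj))
      bestR <- max(bestR, inter / length(Xi))
    }
    num_p <- num_p + length(Xi) * bestP
    num_r <- num_r + length(Xi) * bestR
    den <- den + length(Xi)
  }
  p <- num_p / den; r <- num_r / den
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

# ---- data makers -----------------------------------------------------------
randomRegionSeqs <- function(n, len = 30L, alphabet = c("A", "C", "D", "E",
                                                        "F", "G", "H", "K")) {
  stats::setNames(
    replicate(n, paste(sample(alphabet, len, replace = TRUE), collapse = "")),
    sprintf("r%03d", seq_len(n)))
}

randomClustering <- function(members, nClust) {
  memb <- sample.int(nClust, length(members), replace = TRUE)
  cl <- split(members, memb)
  names(cl) <- paste0("k", names(cl))
  Clustering(lapply(cl, sort))
}

cliqueEdges <- function(ids) {
  t(utils::combn(ids, 2))
}
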