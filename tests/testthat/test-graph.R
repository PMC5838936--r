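test_that("the two-function worked example reproduces both graph levels", {
  fx <- fig1Fixture()
  g1 <- firstLevelGraph(NULL, fx$level1Family, c = 2, termSets = fx$termSets,
                        provenance = TRUE)
  expect_identical(edgeKeySet(g1),
                   sort(paste(fx$level1Edges[, 1], fx$level1Edges[, 2],
                              sep = "--")))
  # s2's edge to s6 comes from h1, the s1 edge from h2 (solid vs dashed)
  e <- edges(g1)
  prov <- g1@provenance
  expect_identical(prov[[which(e[, 1] == "s2" & e[, 2] == "s6")]], 1L)
  expect_identical(prov[[which(e[, 1] == "s1" & e[, 2] == "s2")]], 2L)
  expect_identical(sort(neighborSets(g1)$s2), c("s1", "s6", "s7"))

  g2 <- secondLevelGraph(g1, fx$level2Family, c = 2, provenance = TRUE)
  expect_identical(edgeKeySet(g2), c("s2--s3", "s2--s4", "s3--s4"))
  # all second-level edges stem from the first hash function; none from the
  # second, so no dashed edge is incident to s2
  expect_true(all(vapply(g2@provenance, identical, logical(1), 1L)))
  expect_identical(neighborSets(g2)$s5, character(0))
})

test_that("identical regions are always adjacent at level 1", {
  regs <- c(a = "MKVLLAGRSTWQCDEF", b = "MKVLLAGRSTWQCDEF", c = "PQRSTVWYACDEGHIK")
  g <- firstLevelGraph(regs, makeHashFamily(1, seed = 4))
  expect_true("a--b" %in% edgeKeySet(g))
})

test_that("bucketed construction equals the pairwise sketch oracle", {
  set.seed(21)
  for (rep in 1:6) {
    n <- sample(10:40, 1)
    h <- sample(3:12, 1)
    termSets <- lapply(stats::setNames(seq_len(n), sprintf("r%02d", seq_len(n))),
                       function(i) sort(sample.int(500, sample(3:25, 1))))
    fam <- makeHashFamily(h, seed = 100 + rep)
    g1 <- firstLevelGraph(NULL, fam, c = 2, termSets = termSets)
    expect_identical(edgeKeySet(g1),
                     bruteSketchGraph(termSets, hashFunctions(fam), 2))
    fam2 <- makeHashFamily(h, seed = 100 + rep + 1)
    g2 <- secondLevelGraph(g1, fam2)
    nbTerms <- bruteNeighborTerms(nodes(g1), edgeKeySet(g1))
    expect_identical(edgeKeySet(g2),
                     bruteSketchGraph(nbTerms, hashFunctions(fam2), 2))
  }
})

test_that("region input order does not change either graph", {
  set.seed(5)
  regs <- randomRegionSeqs(25, len = 25)
  a <- buildSimilarityGraphs(regs, h = 10, seed = 2)
  b <- buildSimilarityGraphs(regs[sample(length(regs))], h = 10, seed = 2)
  expect_identical(edges(a@level1), edges(b@level1))
  expect_identical(edges(a@level2), edges(b@level2))
})

test_that("level-1 edges grow monotonically with the family size", {
  set.seed(8)
  regs <- randomRegionSeqs(30, len = 25, alphabet = c("A", "C", "D", "E"))
  prev <- character(0)
  cg <- buildSimilarityGraphs(regs, h = 1, seed = 6)
  for (h in c(2, 5, 9, 14)) {
    cg <- extendSimilarityGraphs(cg, h)
    cur <- edgeKeySet(cg@level1)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("incremental extension equals a cold build, stores included", {
  set.seed(13)
  regs <- randomRegionSeqs(40, len = 30, alphabet = c("A", "C", "D", "E", "F"))
  warm <- buildSimilarityGraphs(regs, h = 7, seed = 31)
  for (h in c(8, 13, 20)) {
    ext <- extendSimilarityGraphs(warm, h)
    cold <- buildSimilarityGraphs(regs, h = h, seed = 31)
    expect_identical(edges(ext@level1), edges(cold@level1))
    expect_identical(edges(ext@level2), edges(cold@level2))
    expect_identical(ext@store$l1keys, cold@store$l1keys)
    expect_identical(ext@store$l2keys, cold@store$l2keys)
    expect_identical(ext@store$nbrs, cold@store$nbrs)
  }
  # no-op extension returns the graphs unchanged
  same <- extendSimilarityGraphs(warm, 7)
  expect_identical(edges(same@level1), edges(warm@level1))
  # the original object is untouched by extension
  expect_identical(warm@h, 7L)
  expect_error(extendSimilarityGraphs(warm, 3), ">=")
})

test_that("degenerate inputs are handled explicitly", {
  expect_warning(g <- firstLevelGraph(c(x = "MK", y = "VA"),
                                      makeHashFamily(2, seed = 1)),
                 "no region yields any k-mer")
  expect_identical(numEdges(g), 0L)
  # a path graph: its two leaves share the single middle neighbor, so any
  # hash function pairs them at level 2
  path <- similarityGraph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  g2 <- secondLevelGraph(path, makeHashFamily(1, seed = 99))
  expect_true("a--c" %in% edgeKeySet(g2))
})
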