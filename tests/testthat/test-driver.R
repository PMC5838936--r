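smallFamilies <- function(seed) {
  generateSynthetic(synthSpec(nFamilies = 3, copiesPerFamily = 8,
                              regionLength = 60, nProteins = 30,
                              proteinLength = 120, seed = seed))
}

# three well-separated, highly conserved families (2% substitution)
conservedFamilies <- function(seed, copies = 20L) {
  generateSynthetic(synthSpec(nFamilies = 3, copiesPerFamily = copies,
                              regionLength = 60, mutationRate = 0.02,
                              nProteins = 70, proteinLength = 120,
                              architectures = list(), seed = seed))
}

test_that("a zero threshold terminates at the first comparison", {
  d <- smallFamilies(5)
  res <- runCoreClust(d$regions,
                      coreClustParam(hStart = 6, d = 5, tau = 0,
                                     minClusterSize = 1, seed = 5))
  expect_true(res@converged)
  expect_identical(res@h, 6L)
  expect_identical(sum(!is.na(res@trace$f1)), 1L)
})

test_that("conserved families are recovered exactly, duplicates included", {
  d <- conservedFamilies(9)
  res <- runCoreClust(d$regions, coreClustParam(hStart = 11, d = 10,
                                                minClusterSize = 5, seed = 9))
  # ground truth recovered up to label renaming
  expect_true(res@converged)
  expect_true(setequal(lapply(clusters(res@regionClusters), sort),
                       lapply(clusters(d$truth), sort)))

  # duplicating every region must leave each duplicate with its original:
  # duplicates share their family neighborhood, hence level-2 sketches
  seqs <- coreClust:::.regionSeqs(d$regions)
  seqs2 <- c(seqs, stats::setNames(seqs, paste0(names(seqs), ".dup")))
  res2 <- runCoreClust(seqs2, coreClustParam(hStart = 11, d = 10,
                                             minClusterSize = 5, seed = 9))
  cl <- clusters(res2@regionClusters)
  assign <- stats::setNames(rep(names(cl), lengths(cl)), unlist(cl))
  expect_identical(unname(assign[names(seqs)]),
                   unname(assign[paste0(names(seqs), ".dup")]))
})

test_that("full runs are deterministic and match a cold restart at the same h", {
  d <- smallFamilies(5)
  p <- coreClustParam(hStart = 11, d = 10, minClusterSize = 5, seed = 5)
  r1 <- runCoreClust(d$regions, p)
  r2 <- runCoreClust(d$regions, p)
  expect_identical(clusters(r1@regionClusters), clusters(r2@regionClusters))
  expect_identical(r1@trace, r2@trace)
  expect_identical(clusters(r1@proteinClusters), clusters(r2@proteinClusters))

  # the clustering emitted at the terminal h equals a cold-start clustering
  # of graphs built from scratch at that family size
  cg <- buildSimilarityGraphs(d$regions, h = r1@h, k = p@k, c = p@c,
                              prime = p@prime, seed = p@seed)
  cold <- louvainCluster(cg@level2, threshold = p@louvainThreshold,
                         seed = p@seed + 7919L + r1@h)
  expect_identical(clusters(cold), clusters(r1@regionClusters))
})

test_that("hMax stops a non-converging run with a warning", {
  set.seed(2)
  seqs <- randomRegionSeqs(12, len = 20)
  expect_warning(
    res <- runCoreClust(seqs, coreClustParam(hStart = 3, d = 2, tau = 1,
                                             hMax = 6, minClusterSize = 1,
                                             seed = 2)),
    "hMax")
  expect_false(res@converged)
  expect_identical(res@h, 6L)
})

test_that("region clusters extend to possibly overlapping protein clusters", {
  cl <- Clustering(list(c0 = c("p1/1-50", "p1/60-110", "p2/1-50"),
                        c1 = c("p3/5-60")))
  map <- c("p1/1-50" = "p1", "p1/60-110" = "p1", "p2/1-50" = "p2",
           "p3/5-60" = "p1")
  pc <- extendToProteins(cl, map)
  expect_true(pc@overlapping)
  expect_identical(nClusters(pc), nClusters(cl))      # cluster count preserved
  expect_identical(clusters(pc)$c0, c("p1", "p2"))    # within-cluster dedup
  inBoth <- vapply(clusters(pc), function(m) "p1" %in% m, logical(1))
  expect_identical(sum(inBoth), 2L)                   # p1 appears in both
  expect_error(extendToProteins(cl, map[-1]), "unknown region")
})
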