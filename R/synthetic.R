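# Synthetic protein-family generator: families of mutated copies of a
# shared consensus implanted into random background proteins, with known
# ground-truth clustering.

.AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                  "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specify a synthetic family data set
#'
#' Defaults describe the validation conditions used throughout the package:
#' 20 families of 30 copies each, 120-residue consensus regions, 5\%
#' per-site substitution rate, 620 host proteins of 300 residues, and one
#' extra protein carrying copies of families 1 and 2 (a two-domain
#' architecture).
#'
#' @param nFamilies,copiesPerFamily,regionLength,mutationRate,nProteins,proteinLength,architectures,seed
#'   see [SynthSpec].
#' @return a [SynthSpec].
#' @export
synthSpec <- function(nFamilies = 20L, copiesPerFamily = 30L,
                      regionLength = 120L, mutationRate = 0.05,
                      nProteins = 620L, proteinLength = 300L,
                      architectures = list(c(1L, 2L)), seed = 1L) {
  new("SynthSpec", nFamilies = .assertCount(nFamilies, "nFamilies"),
      copiesPerFamily = .assertCount(copiesPerFamily, "copiesPerFamily"),
      regionLength = .assertCount(regionLength, "regionLength"),
      mutationRate = mutationRate,
      nProteins = .assertCount(nProteins, "nProteins"),
      proteinLength = .assertCount(proteinLength, "proteinLength"),
      architectures = lapply(architectures, as.integer),
      seed = as.integer(seed))
}

.randomPeptide <- function(n) {
  paste(sample(.AA_STANDARD, n, replace = TRUE), collapse = "")
}

# Point-mutate a consensus: each site substituted with probability mu,
# drawing uniformly from the 19 alternative standard residues. Expected
# per-site identity between two independent copies is (1-mu)^2 + mu^2/19.
.mutateCopy <- function(consensus, mu) {
  if (mu == 0) return(consensus)
  ch <- strsplit(consensus, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < mu)
  for (i in hit) {
    alt <- .AA_STANDARD[.AA_STANDARD != ch[i]]
    ch[i] <- alt[sample.int(19L, 1L)]
  }
  paste(ch, collapse = "")
}

# Place `lens` region lengths non-overlapping into a protein of length L:
# the free residues are cut into random gaps around the regions.
.placeRegions <- function(lens, L) {
  extra <- L - sum(lens)
  if (extra < 0) stop("protein too short to host its architecture")
  cuts <- sort(sample.int(extra + 1L, length(lens), replace = TRUE) - 1L)
  starts <- cuts + c(0L, cumsum(lens[-length(lens)])) + 1L
  starts
}

#' Generate a synthetic protein-family data set
#'
#' Per family, a random consensus of `regionLength` standard residues is
#' drawn; each copy applies i.i.d. substitutions at `mutationRate` and is
#' implanted at a random offset into a host protein whose background
#' residues are uniform over the 20-letter alphabet. Single-family copies
#' are spread over distinct hosts while hosts last; each architecture tuple
#' adds one extra protein carrying one fresh copy of every listed family
#' (all regions within a protein are non-overlapping). The ground truth
#' maps every implanted region to its family.
#'
#' @param spec a [SynthSpec].
#' @return list with elements `proteins` (named
#'   [Biostrings::AAStringSet]), `regions` (GRanges named by region id,
#'   with metadata columns `sequence` and `family`), `truth` (the
#'   ground-truth [Clustering] of region ids by family) and `spec`.
#'   Identical seeds give byte-identical outputs.
#' @examples
#' d <- generateSynthetic(synthSpec(nFamilies = 2, copiesPerFamily = 3,
#'                                  regionLength = 30, nProteins = 8,
#'                                  proteinLength = 80, seed = 7))
#' nClusters(d$truth)
#' @export
generateSynthetic <- function(spec) {
  stopifnot(is(spec, "SynthSpec"))
  .withSeed(spec@seed, {
    consensi <- vapply(seq_len(spec@nFamilies),
                       function(f) .randomPeptide(spec@regionLength),
                       character(1))
    # copy jobs: (family, host protein index); hosts drawn without
    # replacement while available, then with replacement
    nCopies <- spec@nFamilies * spec@copiesPerFamily
    fams <- rep(seq_len(spec@nFamilies), each = spec@copiesPerFamily)
    hosts <- if (nCopies <= spec@nProteins)
      sample.int(spec@nProteins, nCopies)
    else
      c(sample.int(spec@nProteins, spec@nProteins),
        sample.int(spec@nProteins, nCopies - spec@nProteins, replace = TRUE))
    jobs <- split(fams, hosts)  # host index (as character) -> families

    protIds <- sprintf("prot%04d", seq_len(spec@nProteins))
    archIds <- if (length(spec@architectures))
      sprintf("arch%02d", seq_along(spec@architectures)) else character(0)

    seqs <- character(0)
    rows <- list()
    emit <- function(pid, famList) {
      lens <- rep(spec@regionLength, length(famList))
      bg <- .randomPeptide(spec@proteinLength)
      if (length(famList) == 0L) return(bg)
      starts <- .placeRegions(lens, spec@proteinLength)
      ch <- strsplit(bg, "", fixed = TRUE)[[1]]
      for (q in seq_along(famList)) {
        f <- famList[[q]]
        cp <- .mutateCopy(consensi[f], spec@mutationRate)
        s <- starts[q]; e <- s + spec@regionLength - 1L
        ch[s:e] <- strsplit(cp, "", fixed = TRUE)[[1]]
        rows[[length(rows) + 1L]] <<- data.frame(
          protein_id = pid, start = s, end = e,
          region_id = sprintf("%s/%d-%d", pid, s, e), family = f)
      }
      paste(ch, collapse = "")
    }
    for (ip in seq_len(spec@nProteins)) {
      famList <- jobs[[as.character(ip)]]
      if (is.null(famList)) famList <- integer(0)
      seqs[protIds[ip]] <- emit(protIds[ip], famList)
    }
    for (ia in seq_along(spec@architectures))
      seqs[archIds[ia]] <- emit(archIds[ia], spec@architectures[[ia]])

    tab <- do.call(rbind, rows)
    proteins <- Biostrings::AAStringSet(seqs)
    regions <- makeRegions(tab[, c("protein_id", "start", "end", "region_id")],
                           proteins, minLength = 1L)
    S4Vectors::mcols(regions)$family <- tab$family
    truth <- Clustering(lapply(split(tab$region_id, tab$family), sort),
                        overlapping = FALSE)
    names(truth@clusters) <- sprintf("family%02d", as.integer(names(clusters(truth))))
    list(proteins = proteins, regions = regions, truth = truth, spec = spec)
  })
}
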