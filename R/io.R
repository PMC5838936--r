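# Reading protein FASTA and region-coordinate tables; clustering TSV I/O.

#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet subseq
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased and named by the FASTA header token up to the
#' first whitespace. Duplicate identifiers and empty files are errors.
#'
#' @param path FASTA file (gzip accepted).
#' @return an [Biostrings::AAStringSet] named by protein id.
#' @export
readProteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L)
    stop(sprintf("no sequences found in '%s'", path))
  ids <- sub("\\s.*$", "", names(aa))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate protein id(s) in '%s': %s", path,
                 paste(unique(dup), collapse = ", ")))
  if (any(IRanges::width(aa) == 0L))
    stop("zero-length protein sequence in FASTA")
  aa <- Biostrings::AAStringSet(toupper(as.character(aa)))
  names(aa) <- ids
  aa
}

#' Write proteins to FASTA
#'
#' @param proteins a named [Biostrings::AAStringSet].
#' @param path output path.
#' @export
writeProteins <- function(proteins, path) {
  Biostrings::writeXStringSet(proteins, path)
  invisible(path)
}

#' Read a conserved-region table
#'
#' Reads a TSV with columns `protein_id`, `start`, `end` (1-based
#' inclusive, the domain-annotation convention) and optional `region_id`;
#' a header line is detected automatically and `#` comment lines are
#' skipped. Regions spanning fewer than `minLength` residues are dropped
#' (use `minLength = 50` for machine-predicted regions, where short hits
#' tend to be random exact matches; pre-delimited domain coordinates are
#' kept in full by the default of 1). Missing region ids are synthesized as
#' `"proteinid/start-end"`. Region sequences are sliced from the parent
#' proteins.
#'
#' @param path TSV path.
#' @param proteins the parent proteins, from [readProteins()].
#' @param minLength minimum region length retained (default 1).
#' @return a [GenomicRanges::GRanges] named by region id, with `seqnames`
#'   the protein id and metadata column `sequence`.
#' @export
readRegions <- function(path, proteins, minLength = 1L) {
  minLength <- .assertCount(minLength, "minLength")
  raw <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, header = FALSE,
                           colClasses = "character", blank.lines.skip = TRUE)
  if (nrow(raw) == 0L) stop(sprintf("no region rows in '%s'", path))
  if (ncol(raw) < 3L) stop("region table needs columns protein_id, start, end")
  # header detection: a non-numeric 'start' field on the first row
  if (is.na(suppressWarnings(as.numeric(raw[1, 2])))) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0L) stop(sprintf("no region rows in '%s'", path))
  df <- data.frame(protein_id = raw[[1]],
                   start = suppressWarnings(as.integer(raw[[2]])),
                   end = suppressWarnings(as.integer(raw[[3]])),
                   region_id = if (ncol(raw) >= 4L) raw[[4]] else NA_character_,
                   stringsAsFactors = FALSE)
  makeRegions(df, proteins, minLength = minLength)
}

#' @describeIn readRegions build the region container from an in-memory
#'   data.frame with the same columns.
#' @param df data.frame with columns `protein_id`, `start`, `end` and
#'   optionally `region_id`.
#' @export
makeRegions <- function(df, proteins, minLength = 1L) {
  minLength <- .assertCount(minLength, "minLength")
  ids <- names(proteins)
  seqs <- as.character(proteins)
  plen <- stats::setNames(nchar(seqs), ids)
  for (r in seq_len(nrow(df))) {
    p <- df$protein_id[r]
    if (!p %in% ids)
      stop(sprintf("row %d: protein '%s' absent from FASTA", r, p))
    if (is.na(df$start[r]) || is.na(df$end[r]))
      stop(sprintf("row %d: non-numeric coordinates", r))
    if (df$start[r] > df$end[r])
      stop(sprintf("row %d: start %d exceeds end %d", r, df$start[r], df$end[r]))
    if (df$start[r] < 1L || df$end[r] > plen[p])
      stop(sprintf("row %d: [%d, %d] out of bounds for protein '%s' (length %d)",
                   r, df$start[r], df$end[r], p, plen[p]))
  }
  keep <- (df$end - df$start + 1L) >= minLength
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L)
    stop(sprintf("no region of length >= %d", minLength))
  noId <- is.na(df$region_id) | df$region_id == ""
  df$region_id[noId] <- sprintf("%s/%d-%d", df$protein_id[noId],
                                df$start[noId], df$end[noId])
  dup <- df$region_id[duplicated(df$region_id)]
  if (length(dup))
    stop(sprintf("duplicate region id(s): %s", paste(unique(dup), collapse = ", ")))
  sq <- substr(seqs[df$protein_id], df$start, df$end)
  gr <- GenomicRanges::GRanges(seqnames = df$protein_id,
                               ranges = IRanges::IRanges(df$start, df$end))
  names(gr) <- df$region_id
  S4Vectors::mcols(gr)$sequence <- unname(sq)
  gr
}

#' Write a region table as TSV
#'
#' Columns `protein_id`, `start`, `end`, `region_id`, with a header line;
#' round-trips through [readRegions()].
#'
#' @param regions a GRanges from [readRegions()] or [generateSynthetic()].
#' @param path output path.
#' @export
writeRegions <- function(regions, path) {
  stopifnot(is(regions, "GRanges"))
  df <- data.frame(protein_id = as.character(GenomicRanges::seqnames(regions)),
                   start = IRanges::start(regions),
                   end = IRanges::end(regions),
                   region_id = names(regions))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Clustering TSV input and output
#'
#' The on-disk format is one `member_id<TAB>cluster_id` row per membership
#' (so a protein belonging to two overlapping clusters yields two rows),
#' with a header line. `writeClustering()` sorts rows so output is
#' byte-reproducible; the pair round-trips losslessly.
#'
#' @param x a [Clustering].
#' @param path file path.
#' @param overlapping whether the file may assign a member to several
#'   clusters (default FALSE).
#' @return `readClustering()`: a [Clustering].
#' @export
writeClustering <- function(x, path) {
  stopifnot(is(x, "Clustering"))
  if (nClusters(x) == 0L) stop("refusing to write an empty clustering")
  df <- data.frame(member_id = unlist(x@clusters, use.names = FALSE),
                   cluster_id = rep(names(x@clusters), lengths(x@clusters)))
  df <- df[order(df$cluster_id, df$member_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClustering
#' @export
readClustering <- function(path, overlapping = FALSE) {
  raw <- utils::read.table(path, sep = "\t", comment.char = "#", header = FALSE,
                           colClasses = "character", blank.lines.skip = TRUE)
  if (identical(unname(unlist(raw[1, ])), c("member_id", "cluster_id")))
    raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0L) stop(sprintf("no memberships in '%s'", path))
  cl <- split(raw[[1]], raw[[2]])
  cl <- lapply(cl, function(v) sort(unique(v)))
  Clustering(cl[order(names(cl))], overlapping = overlapping)
}
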