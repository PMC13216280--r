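#' @include AllGenerics.R
NULL

# reverse complement on plain strings; N is its own complement
revComp <- function(x) {
  vapply(x, function(u) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(u, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

rotations <- function(u) {
  n <- nchar(u)
  vapply(seq_len(n) - 1L, function(i) {
    paste0(substring(u, i + 1L, n), substring(u, 1L, i))
  }, character(1))
}

#' Canonical representative of a tandem-repeat unit
#'
#' The representative is the lexicographically first string among all cyclic
#' rotations of the unit and all cyclic rotations of its reverse complement
#' (byte order, so A < C < G < N < T). It is therefore invariant under
#' rotation and strand choice: the trimer unit TGC (rotations TGC, GCT, CTG;
#' reverse-complement rotations GCA, CAG, AGC) canonicalizes to AGC. N is
#' treated as its own complement. Input is uppercased first.
#'
#' @param unit character vector of units over A, C, G, T, N.
#' @return character vector of canonical units, same length as \code{unit}.
#' @examples
#' canonicalUnit("TGC")  # "AGC"
#' @export
canonicalUnit <- function(unit) {
  unit <- toupper(unit)
  bad <- grepl("[^ACGTN]", unit)
  if (any(bad))
    stop("invalid alphabet in unit(s): ",
         paste(utils::head(unit[bad], 3), collapse = ", "))
  if (any(nchar(unit) == 0)) stop("empty unit")
  vapply(unit, function(u) {
    cand <- c(rotations(u), rotations(revComp(u)))
    sort(cand, method = "radix")[1]
  }, character(1), USE.NAMES = FALSE)
}

newRepeatCatalog <- function(gr) {
  if (is.null(mcols(gr)$canonical_unit))
    mcols(gr)$canonical_unit <- canonicalUnit(mcols(gr)$consensus_unit)
  new("RepeatCatalog", annotations = gr)
}

#' Build a RepeatCatalog from annotation columns
#'
#' @param seq_id,start,end sequence name and 1-based closed coordinates.
#' @param consensus_unit consensus unit per annotation (uppercased).
#' @param copy_number,score optional per-annotation values.
#' @param seqlengths optional named vector of sequence lengths (enables
#'   bounds checks).
#' @return RepeatCatalog with canonical units filled.
#' @export
RepeatCatalog <- function(seq_id, start, end, consensus_unit,
                          copy_number = (end - start + 1) / nchar(consensus_unit),
                          score = 2 * (end - start + 1), seqlengths = NULL) {
  consensus_unit <- toupper(consensus_unit)
  gr <- GRanges(seq_id, IRanges(start, end),
                unit_length = nchar(consensus_unit),
                copy_number = copy_number,
                consensus_unit = consensus_unit,
                score = score)
  if (!is.null(seqlengths)) {
    sl <- seqlengths[GenomeInfoDb::seqlevels(gr)]
    names(sl) <- GenomeInfoDb::seqlevels(gr)
    seqlengths(gr) <- sl
  }
  newRepeatCatalog(gr)
}

#' Read a TandemRepeatFinder .dat file
#'
#' Parses the whitespace-separated record dialect (per-sequence
#' \code{Sequence:} headers; records with start, end, period, copy number,
#' consensus size, percent matches, percent indels, score, four base
#' percentages, entropy, consensus and repeat region). TRF's 1-based
#' inclusive coordinates map directly onto the internal GRanges; file
#' writers convert back. \code{unit_length} is the consensus length.
#'
#' @param path .dat file path.
#' @param seqlengths optional named vector of sequence lengths.
#' @return RepeatCatalog (records in file order).
#' @export
readTRFDat <- function(path, seqlengths = NULL) {
  lines <- readLines(path)
  cur <- NA_character_
  recs <- vector("list", length(lines))
  n <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "Sequence:")) {
      cur <- trimws(sub("^Sequence:", "", ln))
      cur <- strsplit(cur, "[[:space:]]+")[[1]][1]
      next
    }
    if (startsWith(ln, "Parameters:")) next
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    # skip TRF preamble lines (program banner, version, copyright)
    if (is.na(suppressWarnings(as.numeric(f[1])))) {
      if (is.na(cur)) next
      stop(sprintf("malformed record at line %d: %s", i, lines[i]))
    }
    if (is.na(cur))
      stop(sprintf("record before any 'Sequence:' header at line %d", i))
    if (length(f) < 14)
      stop(sprintf("malformed record at line %d: expected >= 14 fields, got %d",
                   i, length(f)))
    num <- suppressWarnings(as.numeric(f[1:13]))
    if (any(is.na(num)))
      stop(sprintf("malformed record at line %d: non-numeric field", i))
    n <- n + 1L
    recs[[n]] <- list(seq_id = cur, start = num[1], end = num[2],
                      copy_number = num[4], score = num[8],
                      consensus = toupper(f[14]))
  }
  if (n == 0L) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(unit_length = integer(), copy_number = numeric(),
                           consensus_unit = character(),
                           canonical_unit = character(), score = numeric())
    return(new("RepeatCatalog", annotations = gr))
  }
  recs <- recs[seq_len(n)]
  RepeatCatalog(seq_id = vapply(recs, `[[`, "", "seq_id"),
                start = vapply(recs, `[[`, 0, "start"),
                end = vapply(recs, `[[`, 0, "end"),
                consensus_unit = vapply(recs, `[[`, "", "consensus"),
                copy_number = vapply(recs, `[[`, 0, "copy_number"),
                score = vapply(recs, `[[`, 0, "score"),
                seqlengths = seqlengths)
}

#' Write a catalog in TandemRepeatFinder .dat dialect
#'
#' Emits one \code{Sequence:} header per sequence and one record per
#' annotation with 1-based inclusive coordinates; round-trips through
#' \code{\link{readTRFDat}} without coordinate drift.
#'
#' @param catalog RepeatCatalog.
#' @param path output path.
#' @export
writeTRFDat <- function(catalog, path) {
  gr <- annotations(catalog)
  con <- file(path, "w")
  on.exit(close(con))
  for (sq in unique(as.character(seqnames(gr)))) {
    writeLines(paste("Sequence:", sq), con)
    g <- gr[seqnames(gr) == sq]
    m <- mcols(g)
    writeLines(sprintf("%d %d %d %.1f %d %d %d %d %d %d %d %d %.2f %s %s",
                       start(g), end(g), m$unit_length, m$copy_number,
                       m$unit_length, 100L, 0L, as.integer(m$score),
                       25L, 25L, 25L, 25L, 2.0, m$consensus_unit,
                       m$consensus_unit), con)
  }
  invisible(path)
}

#' Remove overlapping annotations, longer intervals first
#'
#' TandemRepeatFinder re-reports the same array at multiple unit sizes;
#' overlaps are resolved by prioritizing longer annotation intervals and
#' shortening the smaller ones. Intervals are processed per sequence in
#' decreasing length (ties: smaller start, then higher score, then input
#' order); each later interval is trimmed to the portion not already
#' covered, a smaller interval split by a larger one keeps both flanks, and
#' intervals trimmed to nothing are dropped. Trimming never changes
#' \code{unit_length} or \code{canonical_unit}; \code{copy_number} is
#' rescaled to the trimmed width.
#'
#' @param catalog RepeatCatalog.
#' @return RepeatCatalog with pairwise non-overlapping annotations per
#'   sequence, sorted by position.
#' @export
resolveOverlaps <- function(catalog) {
  gr <- annotations(catalog)
  if (length(gr) == 0) return(catalog)
  sl <- seqlengths(gr)
  known <- !is.na(sl[as.character(seqnames(gr))])
  if (any(known & end(gr) > sl[as.character(seqnames(gr))]))
    stop("annotation end exceeds sequence length")
  sq <- as.character(seqnames(gr))
  # annotations overlapping nothing pass straight through; only overlap
  # groups enter the priority loop
  selfHits <- findOverlaps(gr, gr)
  touched <- unique(queryHits(selfHits)[queryHits(selfHits) != subjectHits(selfHits)])
  keepIdx <- setdiff(seq_along(gr), touched)
  keepStart <- start(gr)[keepIdx]
  keepEnd <- end(gr)[keepIdx]
  for (s in unique(sq[touched])) {
    idx <- touched[sq[touched] == s]
    ord <- idx[order(-width(gr)[idx], start(gr)[idx], -mcols(gr)$score[idx],
                     idx)]
    accepted <- IRanges()
    for (i in ord) {
      left <- IRanges::setdiff(IRanges(start(gr)[i], end(gr)[i]), accepted)
      if (length(left) == 0) next
      keepIdx <- c(keepIdx, rep(i, length(left)))
      keepStart <- c(keepStart, start(left))
      keepEnd <- c(keepEnd, end(left))
      accepted <- reduce(c(accepted, left))
    }
  }
  out <- GRanges(sq[keepIdx], IRanges(keepStart, keepEnd),
                 seqinfo = GenomeInfoDb::seqinfo(gr))
  m <- mcols(gr)[keepIdx, , drop = FALSE]
  m$copy_number <- width(out) / m$unit_length
  mcols(out) <- m
  out <- sort(out)
  new("RepeatCatalog", annotations = out)
}

#' Summary statistics of a resolved catalog
#'
#' @param catalog RepeatCatalog (expected non-overlapping).
#' @return list with \code{n_annotations}, \code{total_bp},
#'   \code{n_sequences}, and \code{unit_length_histogram} (a named count
#'   table keyed by unit length).
#' @export
catalogStats <- function(catalog) {
  gr <- annotations(catalog)
  hist <- table(mcols(gr)$unit_length)
  list(n_annotations = length(gr),
       total_bp = if (length(gr)) sum(width(gr)) else 0L,
       n_sequences = length(unique(as.character(seqnames(gr)))),
       unit_length_histogram = hist)
}

#' Write the resolved catalog as TSV (0-based half-open coordinates)
#'
#' @param catalog RepeatCatalog.
#' @param path output path.
#' @param header optional character vector of comment lines (without "#").
#' @export
writeCatalogTSV <- function(catalog, path, header = NULL) {
  gr <- annotations(catalog)
  df <- data.frame(seq_id = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   unit_length = mcols(gr)$unit_length,
                   copy_number = mcols(gr)$copy_number,
                   consensus_unit = mcols(gr)$consensus_unit,
                   canonical_unit = mcols(gr)$canonical_unit,
                   score = mcols(gr)$score,
                   stringsAsFactors = FALSE)
  writeTSVWithHeader(df, path, header)
}

#' Read a catalog TSV written by \code{\link{writeCatalogTSV}}
#' @param path TSV path.
#' @param seqlengths optional named sequence lengths.
#' @export
readCatalogTSV <- function(path, seqlengths = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(readTRFDat(textConnection(character())))
  RepeatCatalog(df$seq_id, df$start + 1L, df$end, df$consensus_unit,
                copy_number = df$copy_number, score = df$score,
                seqlengths = seqlengths)
}

#' Write the catalog as BED6 (name = canonical unit)
#' @param catalog RepeatCatalog.
#' @param path output path.
#' @export
writeCatalogBED <- function(catalog, path) {
  gr <- annotations(catalog)
  bed <- granges(gr)
  mcols(bed)$name <- mcols(gr)$canonical_unit
  sc <- mcols(gr)$score
  mcols(bed)$score <- pmin(pmax(as.numeric(sc), 0), 1000)
  rtracklayer::export(bed, path, format = "BED")
  invisible(path)
}

# shared TSV writer with "#"-prefixed provenance header lines
writeTSVWithHeader <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
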