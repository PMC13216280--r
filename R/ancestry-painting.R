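#' @include kmer-markers.R
NULL

#' Annotate exact marker k-mer hits on the assembly
#'
#' Every window matching a library member on either strand (canonical
#' comparison, perfect matches only) contributes the interval
#' [position, position + k); per parent, hit intervals are unioned across
#' all libraries and k sizes. The a1 and a2 interval sets may overlap each
#' other; both are retained.
#'
#' @param assembly DNAStringSet.
#' @param libraries list of \linkS4class{KmerLibrary} (any mix of parents
#'   and k sizes, e.g. from \code{\link{buildMarkerSet}}).
#' @return list with GRanges elements \code{a1} and \code{a2} (reduced
#'   interval unions).
#' @export
annotateKmerHits <- function(assembly, libraries) {
  if (length(libraries) == 0) stop("no libraries given")
  hitRanges <- list(a1 = list(), a2 = list())
  seqs <- setNames(toupper(as.character(assembly)), names(assembly))
  for (lib in libraries) {
    kmers <- kmerMembers(lib)$kmer
    if (length(kmers) == 0) next
    k <- kmerSize(lib)
    for (sq in names(seqs)) {
      st <- cpp_kmer_hit_starts(seqs[[sq]], kmers, k)
      if (length(st) == 0) next
      hitRanges[[parentLabel(lib)]][[length(hitRanges[[parentLabel(lib)]]) + 1L]] <-
        GRanges(sq, IRanges(st, width = k))
    }
  }
  sl <- setNames(Biostrings::width(assembly), names(assembly))
  collect <- function(lst) {
    gr <- if (length(lst) == 0) GRanges() else suppressWarnings(do.call(c, lst))
    seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
    reduce(sort(gr))
  }
  list(a1 = collect(hitRanges$a1), a2 = collect(hitRanges$a2))
}

#' Partition a sequence into equally sized bins close to a target size
#'
#' The bin count is n = max(1, round(length/target)) and edges fall at
#' floor(i * length / n), so bins tile the sequence exactly and differ in
#' length by at most 1 bp — avoiding a short ragged final bin (edge
#' effects).
#'
#' @param sequence_length sequence length in bp (>= 1).
#' @param target_bin target bin size in bp (default 500 kb).
#' @return IRanges of bins (1-based closed).
#' @export
binGenome <- function(sequence_length, target_bin = 500000L) {
  stopifnot(sequence_length >= 1, target_bin >= 1)
  n <- max(1, round(as.numeric(sequence_length) / as.numeric(target_bin)))
  edges <- floor((0:n) * as.numeric(sequence_length) / n)
  IRanges(start = edges[-(n + 1)] + 1L, end = edges[-1])
}

#' Per-bin a1/a2 tagged bp and extended-real log2 ratio
#'
#' For every bin, a1_bp and a2_bp are the overlap lengths of the tagged
#' interval unions with the bin. The log2 ratio follows the five-case
#' rule: finite log2(a1_bp/a2_bp) when both are positive, +Inf when
#' a2_bp = 0 < a1_bp, -Inf when a1_bp = 0 < a2_bp, 0 when the positive
#' counts are equal, and undefined (NA, flagged) when both are 0.
#'
#' @param tagged list with GRanges \code{a1} and \code{a2}
#'   (\code{\link{annotateKmerHits}}).
#' @param seqlengths named vector of sequence lengths.
#' @param bin_size target bin size in bp.
#' @return \linkS4class{BinRatioTrack} (display values unfilled, NA).
#' @export
binRatios <- function(tagged, seqlengths, bin_size = 500000L) {
  binsL <- lapply(names(seqlengths), function(sq)
    GRanges(sq, binGenome(seqlengths[[sq]], bin_size)))
  bins <- suppressWarnings(do.call(c, binsL))
  seqlengths(bins) <- seqlengths[GenomeInfoDb::seqlevels(bins)]
  overlapBp <- function(gr) {
    out <- numeric(length(bins))
    if (length(gr) == 0) return(out)
    h <- findOverlaps(bins, gr, ignore.strand = TRUE)
    if (length(h) == 0) return(out)
    w <- width(pintersect(bins[queryHits(h)], gr[subjectHits(h)]))
    agg <- tapply(w, queryHits(h), sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
    out
  }
  a1 <- overlapBp(tagged$a1)
  a2 <- overlapBp(tagged$a2)
  ratio <- ifelse(a1 > 0 & a2 > 0, log2(a1 / a2),
                  ifelse(a1 > 0, Inf, ifelse(a2 > 0, -Inf, NA_real_)))
  mcols(bins) <- DataFrame(a1_bp = a1, a2_bp = a2, log2_ratio = ratio,
                           display_value = NA_real_,
                           undefined = a1 == 0 & a2 == 0)
  new("BinRatioTrack", bins = bins)
}

#' Fill display values for infinite log2 ratios
#'
#' Finite ratios copy through. Per sequence, +Inf bins display as
#' trunc(max finite + 0.5) + 0.1 and -Inf bins as
#' trunc(min finite - 0.5) - 0.1 (truncation toward zero); when a sequence
#' has no finite ratio, 0 is used as both max and min. Undefined bins
#' display 0 and keep their flag. Display values are for visualization
#' only; \code{\link{segmentAncestry}} ignores them.
#'
#' @param track BinRatioTrack.
#' @return BinRatioTrack with \code{display_value} filled.
#' @export
displayTransform <- function(track) {
  gr <- track@bins
  m <- mcols(gr)
  disp <- m$log2_ratio
  for (sq in unique(as.character(seqnames(gr)))) {
    i <- which(as.character(seqnames(gr)) == sq)
    r <- m$log2_ratio[i]
    fin <- r[is.finite(r)]
    mx <- if (length(fin)) max(fin) else 0
    mn <- if (length(fin)) min(fin) else 0
    disp[i][is.infinite(r) & r > 0] <- trunc(mx + 0.5) + 0.1
    disp[i][is.infinite(r) & r < 0] <- trunc(mn - 0.5) - 0.1
  }
  disp[m$undefined] <- 0
  mcols(gr)$display_value <- disp
  new("BinRatioTrack", bins = gr)
}

#' Segment a ratio track into parental-origin blocks at zero crossings
#'
#' Each bin gets a sign from its raw log2 ratio (+ for positive or +Inf,
#' - for negative or -Inf, neutral for 0 or undefined); neutral bins
#' inherit the previous signed bin's sign (leading neutrals inherit the
#' first signed bin's sign). A candidate crossing between adjacent bins of
#' opposite sign is accepted only when both flanking bins carry at least
#' \code{min_tag_bp} of tagged sequence (a1_bp + a2_bp each); accepted
#' crossings cut the sequence into segments labeled a1 (+) or a2 (-). A
#' sequence with no signed bin yields one "unassigned" segment.
#'
#' @param track BinRatioTrack.
#' @param min_tag_bp minimum tagged bp in both flanking bins (default 50).
#' @return GRanges of segments with metadata \code{parent}, \code{n_bins},
#'   \code{a1_bp}, \code{a2_bp}; per sequence the segments are ordered,
#'   non-overlapping, and alternate in parent label.
#' @export
segmentAncestry <- function(track, min_tag_bp = 50) {
  gr <- track@bins
  segs <- list()
  for (sq in unique(as.character(seqnames(gr)))) {
    b <- gr[as.character(seqnames(gr)) == sq]
    m <- mcols(b)
    sign0 <- ifelse(is.na(m$log2_ratio), 0,
                    ifelse(m$log2_ratio > 0, 1, ifelse(m$log2_ratio < 0, -1, 0)))
    if (all(sign0 == 0)) {
      segs[[length(segs) + 1L]] <- GRanges(sq, IRanges(start(b)[1], end(b)[length(b)]),
                                           parent = "unassigned",
                                           n_bins = length(b),
                                           a1_bp = sum(m$a1_bp), a2_bp = sum(m$a2_bp))
      next
    }
    sgn <- sign0
    first <- which(sgn != 0)[1]
    if (first > 1) sgn[seq_len(first - 1)] <- sgn[first]
    for (i in seq_along(sgn)[-1]) if (sgn[i] == 0) sgn[i] <- sgn[i - 1]
    tagged <- m$a1_bp + m$a2_bp
    cut <- logical(length(b) - 1)
    for (i in seq_len(length(b) - 1)) {
      if (sgn[i] != sgn[i + 1] &&
          tagged[i] >= min_tag_bp && tagged[i + 1] >= min_tag_bp)
        cut[i] <- TRUE
    }
    bounds <- c(0L, which(cut), length(b))
    for (j in seq_len(length(bounds) - 1)) {
      i0 <- bounds[j] + 1L
      i1 <- bounds[j + 1]
      lab <- if (sgn[i0] > 0) "a1" else "a2"
      segs[[length(segs) + 1L]] <- GRanges(sq, IRanges(start(b)[i0], end(b)[i1]),
                                           parent = lab, n_bins = i1 - i0 + 1L,
                                           a1_bp = sum(m$a1_bp[i0:i1]),
                                           a2_bp = sum(m$a2_bp[i0:i1]))
    }
  }
  out <- suppressWarnings(do.call(c, segs))
  sl <- seqlengths(gr)
  seqlengths(out) <- sl[GenomeInfoDb::seqlevels(out)]
  out
}

#' Write ancestry segments as BED6
#'
#' Name is the parent label; score is round(1000 * |mean display value|)
#' over the segment's bins, clipped to [0, 1000]. Unassigned segments are
#' excluded by default.
#'
#' @param segments GRanges from \code{\link{segmentAncestry}}.
#' @param track the BinRatioTrack the segments came from (after
#'   \code{\link{displayTransform}}); used for the score.
#' @param path output path.
#' @param include_unassigned keep "unassigned" segments (default FALSE).
#' @export
writePaintBED <- function(segments, track, path, include_unassigned = FALSE) {
  if (!include_unassigned)
    segments <- segments[mcols(segments)$parent != "unassigned"]
  bins <- track@bins
  score <- vapply(seq_along(segments), function(i) {
    h <- findOverlaps(segments[i], bins)
    dv <- mcols(bins)$display_value[subjectHits(h)]
    if (all(is.na(dv))) 0 else min(1000, round(1000 * abs(mean(dv, na.rm = TRUE))))
  }, numeric(1))
  bed <- granges(segments)
  mcols(bed)$name <- mcols(segments)$parent
  mcols(bed)$score <- score
  rtracklayer::export(bed, path, format = "BED")
  invisible(path)
}

#' Write the per-bin track as TSV (0-based half-open bins)
#' @param track BinRatioTrack.
#' @param path output path.
#' @param header optional comment lines.
#' @export
writeTrackTSV <- function(track, path, header = NULL) {
  gr <- track@bins
  m <- mcols(gr)
  df <- data.frame(seq_id = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   a1_bp = m$a1_bp, a2_bp = m$a2_bp,
                   log2_ratio = m$log2_ratio,
                   display_value = m$display_value,
                   stringsAsFactors = FALSE)
  writeTSVWithHeader(df, path, header)
}

#' Read a track TSV written by \code{\link{writeTrackTSV}}
#' @param path TSV path.
#' @return BinRatioTrack.
#' @export
readTrackTSV <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  gr <- GRanges(df$seq_id, IRanges(df$start + 1L, df$end))
  sl <- tapply(df$end, df$seq_id, max)
  seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  mcols(gr) <- DataFrame(a1_bp = df$a1_bp, a2_bp = df$a2_bp,
                         log2_ratio = as.numeric(df$log2_ratio),
                         display_value = as.numeric(df$display_value),
                         undefined = df$a1_bp == 0 & df$a2_bp == 0)
  new("BinRatioTrack", bins = gr)
}
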