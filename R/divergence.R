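#' @include coverage.R
NULL

#' Per-alignment sequence identity percentage
#'
#' As printed in the source formula this is
#' (mismatches / alignment length) x 100 — which is the mismatch
#' percentage despite its "identity" name; with \code{as_identity = TRUE}
#' the complement (100 minus that) is returned. Both variants are exposed
#' because the as-printed value of e.g. 250 mismatches over 1000 bp is
#' 25.0 while the corresponding identity is 75.0.
#'
#' @param mismatches number of mismatching columns (0..alignment_length).
#' @param alignment_length alignment length in bp (> 0).
#' @param as_identity return 100 minus the as-printed value.
#' @return percentage (vectorized).
#' @export
alignmentIdentityPercent <- function(mismatches, alignment_length,
                                     as_identity = FALSE) {
  if (any(alignment_length <= 0)) stop("alignment_length must be positive")
  if (any(mismatches < 0 | mismatches > alignment_length))
    stop("mismatches must be in [0, alignment_length]")
  v <- mismatches / alignment_length * 100
  if (as_identity) 100 - v else v
}

#' Per-bin median of alignment values along one sequence
#'
#' Each alignment's value is attributed to every bin it overlaps; the
#' per-bin median is reported (even counts: mean of the middle pair).
#' Empty bins are NA.
#'
#' @param alignments data.frame with columns \code{start}, \code{end}
#'   (1-based closed on the target) and \code{value}.
#' @param sequence_length target sequence length in bp.
#' @param bin target bin size (default 500 kb).
#' @return data.frame with \code{start}, \code{end} (0-based half-open),
#'   \code{median_value}, \code{n_alignments} per bin.
#' @export
medianIdentityTrack <- function(alignments, sequence_length, bin = 500000L) {
  bins <- binGenome(sequence_length, bin)
  al <- IRanges(alignments$start, alignments$end)
  h <- findOverlaps(bins, al)
  med <- rep(NA_real_, length(bins))
  nal <- integer(length(bins))
  if (length(h) > 0) {
    sp <- split(alignments$value[subjectHits(h)], queryHits(h))
    idx <- as.integer(names(sp))
    med[idx] <- vapply(sp, median, numeric(1))
    nal[idx] <- lengths(sp)
  }
  data.frame(start = start(bins) - 1L, end = end(bins),
             median_value = med, n_alignments = nal)
}

#' LTR retrotransposon insertion age from terminal-repeat divergence
#'
#' Age = Distance / (2 x mutation rate) x 1e-6 million years, with
#' Distance = 1 - LTR identity; the factor 2 reflects that both long
#' terminal repeats accumulate substitutions independently after
#' insertion. Default mutation rate 1.3e-8 substitutions/site/year.
#'
#' @param ltr_identity identity fraction between the 5' and 3' LTR, in
#'   [0, 1] (vectorized).
#' @param mutation_rate substitutions per site per year.
#' @return insertion age in million years (Myr).
#' @examples
#' ltrInsertionAge(0.974)  # 1.0 Myr
#' @export
ltrInsertionAge <- function(ltr_identity, mutation_rate = 1.3e-8) {
  if (any(ltr_identity < 0 | ltr_identity > 1))
    stop("ltr_identity must be in [0, 1]")
  stopifnot(mutation_rate > 0)
  (1 - ltr_identity) / (2 * mutation_rate) * 1e-6
}

#' Percentage of switched bases in a phased assembly
#'
#' 100 x n_switched / n_total, rounded half-to-even to 3 decimals (the
#' reporting convention: 122,753 switched of 5,886,045 phased SNPs gives
#' 2.085).
#'
#' @param n_switched SNPs assigned to the wrong phase.
#' @param n_total total phased SNPs compared (> 0).
#' @return percentage rounded to 3 decimals.
#' @export
switchErrorPercent <- function(n_switched, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_switched < 0 | n_switched > n_total))
    stop("n_switched must be in [0, n_total]")
  round(100 * n_switched / n_total, 3)
}

#' Read a PAF alignment file (the columns the identity track needs)
#'
#' Keeps query/target names and coordinates, the residue-match count
#' (column 10) and alignment block length (column 11); mismatches are
#' derived as block length minus matches.
#'
#' @param path PAF path.
#' @param min_length drop alignments with block length below this
#'   (default 10 kb, the track's primary-alignment cutoff).
#' @return data.frame with \code{query}, \code{target}, \code{start},
#'   \code{end} (1-based closed target coords), \code{matches},
#'   \code{alignment_length}, \code{mismatches}.
#' @export
readPAF <- function(path, min_length = 10000L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(query = character(), target = character(),
                      start = integer(), end = integer(),
                      matches = integer(), alignment_length = integer(),
                      mismatches = integer()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(f, length, 0L) < 12
  if (any(short)) stop("malformed PAF line ", which(short)[1])
  df <- data.frame(query = vapply(f, `[[`, "", 1),
                   target = vapply(f, `[[`, "", 6),
                   start = as.integer(vapply(f, `[[`, "", 8)) + 1L,
                   end = as.integer(vapply(f, `[[`, "", 9)),
                   matches = as.integer(vapply(f, `[[`, "", 10)),
                   alignment_length = as.integer(vapply(f, `[[`, "", 11)),
                   stringsAsFactors = FALSE)
  df$mismatches <- df$alignment_length - df$matches
  df[df$alignment_length >= min_length, , drop = FALSE]
}
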