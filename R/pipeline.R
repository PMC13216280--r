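#' @include synthetic-data.R
NULL

#' Run the full ancestry-painting pipeline on a phased assembly
#'
#' Convenience wrapper chaining tandem-repeat detection (or a supplied
#' catalog), canonicalization, overlap resolution, unit clustering,
#' phase-specificity flagging, provisional partitioning, marker-library
#' selection, exact-hit annotation, binning and segmentation, with all
#' parameters taken from a \code{\link{simulationPreset}}-shaped
#' configuration.
#'
#' @param assembly DNAStringSet of the phased assembly.
#' @param phase_of_sequence named vector mapping seq_id to
#'   "phase1"/"phase2".
#' @param config parameter list (\code{\link{simulationPreset}}).
#' @param catalog optional RepeatCatalog; when NULL the naive
#'   perfect-tandem detector is run with the configured unit lengths.
#' @return list with \code{catalog}, \code{clusters}, \code{partition},
#'   \code{libraries}, \code{tagged}, \code{track} (display-transformed)
#'   and \code{segments}.
#' @export
paintPipeline <- function(assembly, phase_of_sequence, config,
                          catalog = NULL) {
  sl <- setNames(Biostrings::width(assembly), names(assembly))
  if (is.null(catalog))
    catalog <- findPerfectTandems(assembly, config$tandem_unit_lengths,
                                  config$tandem_min_copies)
  catalog <- resolveOverlaps(catalog)
  clusters <- clusterUnits(catalog, config$identity_threshold)
  clusters <- phaseSpecificity(clusters, phase_of_sequence,
                               s_min = config$s_min, b_min = config$b_min)
  partition <- provisionalPartition(clusters, sl,
                                    merge_distance = config$merge_distance)
  libraries <- buildMarkerSet(partition, assembly,
                              k_sizes = config$k_sizes,
                              min_freq_a1 = config$min_freq_a1,
                              min_freq_a2 = config$min_freq_a2,
                              min_abs_log2fc = config$min_abs_log2fc)
  tagged <- annotateKmerHits(assembly, libraries)
  track <- binRatios(tagged, sl, bin_size = config$bin_size)
  track <- displayTransform(track)
  segments <- segmentAncestry(track, min_tag_bp = config$min_tag_bp)
  list(catalog = catalog, clusters = clusters, partition = partition,
       libraries = libraries, tagged = tagged, track = track,
       segments = segments)
}

#' Compare recovered ancestry segments to planted truth
#'
#' A truth block counts as assessable when it spans at least
#' \code{min_bins} bins. It is recovered when the same-label predicted
#' segment with the largest overlap has both boundaries within one bin of
#' the truth boundaries. A predicted segment of at least 2 bins is
#' spurious when half or more of its span lies inside truth blocks of the
#' opposite label.
#'
#' @param segments GRanges from \code{\link{segmentAncestry}}.
#' @param truth GRanges with \code{parent} labels (a1/a2).
#' @param bin_size painting bin size in bp.
#' @param min_bins minimum truth-block span, in bins, to assess
#'   (default 3).
#' @return list with \code{n_blocks}, \code{n_recovered},
#'   \code{max_boundary_offset} (bp, NA when nothing assessed) and
#'   \code{n_spurious}.
#' @export
compareSegmentsToTruth <- function(segments, truth, bin_size, min_bins = 3) {
  assess <- truth[width(truth) >= min_bins * bin_size]
  nRec <- 0L
  maxOff <- NA_real_
  for (i in seq_along(assess)) {
    tb <- assess[i]
    cand <- segments[as.character(seqnames(segments)) == as.character(seqnames(tb)) &
                     mcols(segments)$parent == mcols(tb)$parent]
    if (length(cand) == 0) next
    ov <- pmax(0L, pmin(end(cand), end(tb)) - pmax(start(cand), start(tb)) + 1L)
    best <- cand[which.max(ov)]
    off <- max(abs(start(best) - start(tb)), abs(end(best) - end(tb)))
    if (max(ov) > 0 && off <= bin_size) {
      nRec <- nRec + 1L
      maxOff <- max(maxOff, off, na.rm = TRUE)
    }
  }
  nSpur <- 0L
  big <- segments[mcols(segments)$n_bins >= 2 &
                  mcols(segments)$parent %in% c("a1", "a2")]
  for (i in seq_along(big)) {
    sg <- big[i]
    opp <- truth[as.character(seqnames(truth)) == as.character(seqnames(sg)) &
                 mcols(truth)$parent != mcols(sg)$parent]
    if (length(opp) == 0) next
    ovb <- sum(pmax(0L, pmin(end(opp), end(sg)) - pmax(start(opp), start(sg)) + 1L))
    if (ovb >= 0.5 * width(sg)) nSpur <- nSpur + 1L
  }
  list(n_blocks = length(assess), n_recovered = nRec,
       max_boundary_offset = maxOff, n_spurious = nSpur)
}
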