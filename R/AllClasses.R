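#' @include haplorigin-package.R
NULL

#' RepeatCatalog: tandem-repeat annotations with canonical units
#'
#' Holds one tandem-repeat annotation per range (GRanges, 1-based closed
#' internally; all file interfaces convert) with metadata columns
#' \code{unit_length}, \code{copy_number}, \code{consensus_unit},
#' \code{canonical_unit} (rotation- and strand-invariant representative,
#' filled by \code{\link{canonicalUnit}}) and \code{score}.
#'
#' @slot annotations GRanges with the metadata columns listed above.
#' @export
setClass("RepeatCatalog", representation(annotations = "GRanges"))

setValidity("RepeatCatalog", function(object) {
  gr <- object@annotations
  need <- c("unit_length", "copy_number", "consensus_unit", "canonical_unit", "score")
  missing <- setdiff(need, colnames(mcols(gr)))
  if (length(missing) > 0)
    return(paste("missing annotation columns:", paste(missing, collapse = ", ")))
  if (length(gr) == 0) return(TRUE)
  if (any(mcols(gr)$unit_length != nchar(mcols(gr)$consensus_unit)))
    return("unit_length must equal nchar(consensus_unit)")
  cu <- mcols(gr)$canonical_unit
  if (any(!is.na(cu) & nchar(cu) != nchar(mcols(gr)$consensus_unit)))
    return("canonical_unit must have the same length as consensus_unit")
  sl <- seqlengths(gr)
  known <- !is.na(sl[as.character(seqnames(gr))])
  if (any(known & end(gr) > sl[as.character(seqnames(gr))]))
    return("annotation end exceeds sequence length")
  TRUE
})

#' RepeatClusterSet: satellite families of canonical units
#'
#' Produced by \code{\link{clusterUnits}} and progressively filled by
#' \code{\link{clusterProfiles}} and \code{\link{phaseSpecificity}}.
#' Clusters are numbered 1..n in decreasing order of total member bp.
#'
#' @slot catalog RepeatCatalog the clustering was computed from.
#' @slot membership integer, one cluster id per catalog annotation.
#' @slot table DataFrame with one row per cluster: \code{cluster_id},
#'   \code{n_units}, \code{n_annotations}, \code{total_bp}, and after
#'   \code{phaseSpecificity} also \code{bp_phase1}, \code{bp_phase2},
#'   \code{specificity}, \code{flagged_parent} (\code{"a1"}, \code{"a2"} or
#'   \code{NA}).
#' @slot units list of character vectors: member canonical units per cluster.
#' @slot profiles data.frame of binned member locations
#'   (\code{cluster_id}, \code{seq_id}, \code{bin}, \code{bin_start},
#'   \code{bin_end}, \code{bp}) or NULL before \code{clusterProfiles}.
#' @export
setClass("RepeatClusterSet",
         representation(catalog = "RepeatCatalog", membership = "integer",
                        table = "DataFrame", units = "list",
                        profiles = "ANY"))

setValidity("RepeatClusterSet", function(object) {
  n <- nrow(object@table)
  if (length(object@units) != n) return("units list length must match table rows")
  if (length(object@membership) != length(object@catalog@annotations))
    return("membership length must match catalog size")
  if (n > 0 && any(lengths(object@units) == 0)) return("clusters must have member units")
  if (n > 1 && is.unsorted(-object@table$total_bp)) return("clusters must be ordered by total bp, descending")
  TRUE
})

#' KmerLibrary: lineage-enriched marker k-mers for one parent
#'
#' A parent-labeled set of canonical k-mers with their counts in each
#' parent's provisional source bins; every member passed the frequency and
#' log2-fold-change filters recorded in \code{thresholds}.
#'
#' @slot k integer k-mer length.
#' @slot parent \code{"a1"} or \code{"a2"}.
#' @slot members DataFrame with columns \code{kmer}, \code{count_a1},
#'   \code{count_a2}.
#' @slot thresholds named list (\code{min_freq_a1}, \code{min_freq_a2},
#'   \code{min_abs_log2fc}) recorded at selection time.
#' @export
setClass("KmerLibrary",
         representation(k = "integer", parent = "character",
                        members = "DataFrame", thresholds = "list"))

setValidity("KmerLibrary", function(object) {
  if (length(object@k) != 1 || object@k < 1) return("k must be a single positive integer")
  if (!object@parent %in% c("a1", "a2")) return("parent must be 'a1' or 'a2'")
  m <- object@members
  if (!all(c("kmer", "count_a1", "count_a2") %in% colnames(m)))
    return("members needs columns kmer, count_a1, count_a2")
  if (nrow(m) > 0 && any(nchar(m$kmer) != object@k))
    return("all member k-mers must have length k")
  TRUE
})

#' BinRatioTrack: per-bin a1/a2 tag counts and log2 ratio for one sequence set
#'
#' Bins tile each sequence exactly (\code{\link{binGenome}}). The log2 ratio
#' is an extended real: \code{+Inf} iff a2_bp = 0 and a1_bp > 0, \code{-Inf}
#' iff a1_bp = 0 and a2_bp > 0, 0 iff the positive counts are equal, and
#' \code{NA} ("undefined") iff both are 0. \code{display_value} is filled by
#' \code{\link{displayTransform}} and is for visualization only;
#' segmentation always reads \code{log2_ratio}.
#'
#' @slot bins GRanges with metadata columns \code{a1_bp}, \code{a2_bp},
#'   \code{log2_ratio}, \code{display_value}, \code{undefined}.
#' @export
setClass("BinRatioTrack", representation(bins = "GRanges"))

setValidity("BinRatioTrack", function(object) {
  gr <- object@bins
  need <- c("a1_bp", "a2_bp", "log2_ratio", "display_value", "undefined")
  if (!all(need %in% colnames(mcols(gr)))) return("missing track columns")
  if (length(gr) == 0) return(TRUE)
  m <- mcols(gr)
  if (any(m$a1_bp < 0 | m$a2_bp < 0)) return("negative tagged bp")
  if (any(m$a1_bp > width(gr) | m$a2_bp > width(gr))) return("tagged bp exceeds bin length")
  bad <- (m$a1_bp == 0 & m$a2_bp == 0) != m$undefined
  if (any(bad)) return("undefined flag inconsistent with zero counts")
  pos <- !m$undefined
  r <- m$log2_ratio[pos]
  a1 <- m$a1_bp[pos]; a2 <- m$a2_bp[pos]
  if (any(is.infinite(r) & r > 0 & a2 != 0)) return("+Inf requires a2_bp = 0")
  if (any(is.infinite(r) & r < 0 & a1 != 0)) return("-Inf requires a1_bp = 0")
  for (sq in unique(as.character(seqnames(gr)))) {
    b <- gr[seqnames(gr) == sq]
    if (length(b) > 1 && any(start(b)[-1] != end(b)[-length(b)] + 1))
      return(sprintf("bins do not tile sequence %s", sq))
  }
  TRUE
})
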