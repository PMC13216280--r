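#' @include repeat-catalog.R
NULL

# union-find over 1..n
ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# global-alignment identity between two units: matching columns over an
# alignment of length max(nchar), gaps counted as mismatch. Computed as
# 1 - levenshtein/max(nchar) (utils::adist), which reproduces that
# definition for near-identical units (e.g. one substitution in 10 -> 0.9).
unitIdentity <- function(a, b) {
  d <- as.numeric(adist(a, b))
  1 - d / pmax(nchar(a), nchar(b))
}

#' Cluster canonical units into satellite families
#'
#' Identical canonical units always share a cluster. With
#' \code{identity_threshold < 1}, clusters are the connected components
#' (single linkage) of the graph linking unit pairs whose global-alignment
#' identity is at least the threshold; units of different lengths can then
#' cluster when the length-penalized identity still passes. Clusters are
#' numbered by total member bp, descending (ties: smaller first-annotation
#' index), so cluster 1 is the largest family.
#'
#' @param catalog RepeatCatalog with canonical units (typically after
#'   \code{\link{resolveOverlaps}}).
#' @param identity_threshold pairwise identity in (0, 1] required to link
#'   two distinct units; 1 means exact-match grouping only.
#' @return RepeatClusterSet.
#' @export
clusterUnits <- function(catalog, identity_threshold = 0.9) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  gr <- annotations(catalog)
  if (length(gr) == 0) {
    return(new("RepeatClusterSet", catalog = catalog, membership = integer(),
               table = DataFrame(cluster_id = integer(), n_units = integer(),
                                 n_annotations = integer(), total_bp = numeric()),
               units = list(), profiles = NULL))
  }
  cu <- mcols(gr)$canonical_unit
  uniq <- unique(cu)
  comp <- seq_along(uniq)
  if (identity_threshold < 1 && length(uniq) > 1) {
    dm <- adist(uniq)
    maxlen <- outer(nchar(uniq), nchar(uniq), pmax)
    idm <- 1 - dm / maxlen
    link <- which(idm >= identity_threshold & upper.tri(idm), arr.ind = TRUE)
    if (nrow(link) > 0) {
      for (e in seq_len(nrow(link))) {
        ra <- ufFind(comp, link[e, 1]); rb <- ufFind(comp, link[e, 2])
        if (ra != rb) comp[max(ra, rb)] <- min(ra, rb)
      }
      comp <- vapply(seq_along(comp), function(i) ufFind(comp, i), 0L)
    }
  }
  compOfAnnot <- comp[match(cu, uniq)]
  bp <- tapply(width(gr), compOfAnnot, sum)
  firstIdx <- tapply(seq_along(gr), compOfAnnot, min)
  ids <- as.integer(names(bp))
  ord <- order(-as.numeric(bp), as.integer(firstIdx))
  rank <- integer(max(ids))
  rank[ids[ord]] <- seq_along(ord)
  membership <- rank[compOfAnnot]
  unitsList <- lapply(ids[ord], function(cid) unique(cu[compOfAnnot == cid]))
  tab <- DataFrame(cluster_id = seq_along(ord),
                   n_units = lengths(unitsList),
                   n_annotations = as.integer(table(membership)[as.character(seq_along(ord))]),
                   total_bp = as.numeric(bp[ord]))
  new("RepeatClusterSet", catalog = catalog, membership = membership,
      table = tab, units = unitsList, profiles = NULL)
}

#' Profile family locations in genome bins
#'
#' For each of the \code{top_n} largest clusters, tallies the member bp per
#' (sequence, bin) as the overlap length of member annotations with each
#' bin; bin edges come from \code{\link{binGenome}} on each sequence.
#'
#' @param clusters RepeatClusterSet.
#' @param seqlengths named vector of sequence lengths.
#' @param bin_size target bin size in bp (default 500 kb).
#' @param top_n number of largest clusters to profile (default 200).
#' @return RepeatClusterSet with the \code{profiles} table filled.
#' @export
clusterProfiles <- function(clusters, seqlengths, bin_size = 500000L, top_n = 200L) {
  gr <- annotations(clusters@catalog)
  unknown <- setdiff(unique(as.character(seqnames(gr))), names(seqlengths))
  if (length(unknown) > 0)
    stop("annotation references unknown sequence(s): ",
         paste(unknown, collapse = ", "))
  binsL <- lapply(names(seqlengths), function(sq) {
    b <- binGenome(seqlengths[[sq]], bin_size)
    GRanges(sq, b, bin = seq_along(b))
  })
  bins <- suppressWarnings(do.call(c, binsL))
  keep <- clusters@membership <= min(top_n, nrow(clusters@table))
  g <- gr[keep]
  memb <- clusters@membership[keep]
  hits <- findOverlaps(g, bins)
  ov <- width(pintersect(g[queryHits(hits)], bins[subjectHits(hits)]))
  key <- data.frame(cluster_id = memb[queryHits(hits)],
                    seq_id = as.character(seqnames(bins))[subjectHits(hits)],
                    bin = mcols(bins)$bin[subjectHits(hits)],
                    bin_start = start(bins)[subjectHits(hits)] - 1L,
                    bin_end = end(bins)[subjectHits(hits)],
                    bp = ov, stringsAsFactors = FALSE)
  prof <- stats::aggregate(bp ~ cluster_id + seq_id + bin + bin_start + bin_end,
                           data = key, FUN = sum)
  prof <- prof[order(prof$cluster_id, prof$seq_id, prof$bin), , drop = FALSE]
  rownames(prof) <- NULL
  clusters@profiles <- prof
  clusters
}

#' Score per-phase specificity and flag parent-specific families
#'
#' Specificity of a family is the largest share of its member bp falling on
#' one phase (0.5..1 for two phases). A family is flagged parent-specific
#' for a phase when specificity >= \code{s_min} and total member bp >=
#' \code{b_min}; flagged phase1 families are labeled parent a1, phase2
#' families a2.
#'
#' @param clusters RepeatClusterSet.
#' @param phase_of_sequence named character vector mapping every seq_id to
#'   \code{"phase1"} or \code{"phase2"}.
#' @param s_min minimum specificity (default 0.9).
#' @param b_min minimum total member bp (default 50000).
#' @return RepeatClusterSet with \code{bp_phase1}, \code{bp_phase2},
#'   \code{specificity}, \code{flagged_parent} columns filled.
#' @export
phaseSpecificity <- function(clusters, phase_of_sequence, s_min = 0.9,
                             b_min = 50000) {
  gr <- annotations(clusters@catalog)
  ph <- phase_of_sequence[as.character(seqnames(gr))]
  if (any(is.na(ph)))
    stop("sequences without phase label: ",
         paste(unique(as.character(seqnames(gr))[is.na(ph)]), collapse = ", "))
  n <- nrow(clusters@table)
  bp1 <- bp2 <- numeric(n)
  for (cid in seq_len(n)) {
    w <- width(gr)[clusters@membership == cid]
    p <- ph[clusters@membership == cid]
    bp1[cid] <- sum(w[p == "phase1"])
    bp2[cid] <- sum(w[p == "phase2"])
  }
  tot <- bp1 + bp2
  spec <- ifelse(tot > 0, pmax(bp1, bp2) / tot, NA_real_)
  flag <- rep(NA_character_, n)
  pass <- !is.na(spec) & spec >= s_min & tot >= b_min
  flag[pass & bp1 >= bp2] <- "a1"
  flag[pass & bp2 > bp1] <- "a2"
  tb <- clusters@table
  tb$bp_phase1 <- bp1
  tb$bp_phase2 <- bp2
  tb$specificity <- spec
  tb$flagged_parent <- flag
  clusters@table <- tb
  clusters
}

#' Derive the provisional parental partition from flagged families
#'
#' The a1 (resp. a2) source bins are the union of member-annotation
#' intervals of families flagged for that parent, each extended by
#' \code{merge_distance} on both sides, merged, and clipped to sequence
#' bounds; intervals claimed by both parents are dropped from both sides.
#' These bins are the k-mer source regions for
#' \code{\link{buildMarkerSet}}.
#'
#' @param clusters RepeatClusterSet after \code{\link{phaseSpecificity}}.
#' @param seqlengths named vector of sequence lengths.
#' @param merge_distance extension in bp (default: painting bin size).
#' @return GRanges of non-overlapping bins with metadata column
#'   \code{parent} ("a1"/"a2"), sorted by position.
#' @export
provisionalPartition <- function(clusters, seqlengths, merge_distance = 500000L) {
  tb <- clusters@table
  if (!"flagged_parent" %in% colnames(tb))
    stop("run phaseSpecificity() first")
  gr <- annotations(clusters@catalog)
  sideBins <- function(parent) {
    cids <- tb$cluster_id[!is.na(tb$flagged_parent) & tb$flagged_parent == parent]
    if (length(cids) == 0)
      stop(sprintf("insufficient lineage signal: no cluster flagged for %s", parent))
    g <- granges(gr[clusters@membership %in% cids])
    g <- GRanges(seqnames(g),
                 IRanges(pmax(1L, start(g) - merge_distance),
                         pmin(seqlengths[as.character(seqnames(g))],
                              end(g) + merge_distance)))
    reduce(g)
  }
  a1 <- sideBins("a1")
  a2 <- sideBins("a2")
  both <- GenomicRanges::intersect(a1, a2, ignore.strand = TRUE)
  a1 <- GenomicRanges::setdiff(a1, both, ignore.strand = TRUE)
  a2 <- GenomicRanges::setdiff(a2, both, ignore.strand = TRUE)
  mcols(a1)$parent <- rep("a1", length(a1))
  mcols(a2)$parent <- rep("a2", length(a2))
  sort(c(a1, a2))
}

#' Write the per-cluster table as TSV
#' @param clusters RepeatClusterSet.
#' @param path output path.
#' @param header optional comment lines.
#' @export
writeClusterTSV <- function(clusters, path, header = NULL) {
  writeTSVWithHeader(as.data.frame(clusters@table), path, header)
}

#' Write the provisional partition as BED (name = parent label)
#' @param partition GRanges from \code{\link{provisionalPartition}}.
#' @param path output path.
#' @export
writePartitionBED <- function(partition, path) {
  bed <- granges(partition)
  mcols(bed)$name <- mcols(partition)$parent
  mcols(bed)$score <- rep(0, length(bed))
  rtracklayer::export(bed, path, format = "BED")
  invisible(path)
}
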