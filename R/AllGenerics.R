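#' @include AllClasses.R
NULL

#' @describeIn RepeatCatalog-class annotations as a GRanges
#' @param x object
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @export
setMethod("annotations", "RepeatCatalog", function(x) x@annotations)

#' Number of annotations in a catalog
#' @param x RepeatCatalog
#' @export
setMethod("length", "RepeatCatalog", function(x) length(x@annotations))

setMethod("show", "RepeatCatalog", function(object) {
  gr <- object@annotations
  cat(sprintf("RepeatCatalog with %d annotations on %d sequence(s); %d bp total\n",
              length(gr), length(unique(as.character(seqnames(gr)))),
              sum(width(gr))))
  if (length(gr) > 0) {
    cu <- mcols(gr)$canonical_unit
    cat(sprintf("  %d distinct canonical units; unit lengths %s\n",
                length(unique(cu[!is.na(cu)])),
                paste(sort(unique(mcols(gr)$unit_length)), collapse = ", ")))
  }
})

#' @describeIn RepeatClusterSet-class per-cluster summary table
#' @param x object
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @export
setMethod("clusterTable", "RepeatClusterSet", function(x) x@table)

#' @describeIn RepeatClusterSet-class cluster id per catalog annotation
#' @export
setGeneric("clusterMembership", function(x) standardGeneric("clusterMembership"))
#' @export
setMethod("clusterMembership", "RepeatClusterSet", function(x) x@membership)

#' @describeIn RepeatClusterSet-class member canonical units per cluster
#' @export
setGeneric("memberUnits", function(x) standardGeneric("memberUnits"))
#' @export
setMethod("memberUnits", "RepeatClusterSet", function(x) x@units)

#' @describeIn RepeatClusterSet-class binned member-location profiles
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))
#' @export
setMethod("profileTable", "RepeatClusterSet", function(x) x@profiles)

setMethod("show", "RepeatClusterSet", function(object) {
  tb <- object@table
  cat(sprintf("RepeatClusterSet with %d cluster(s) over %d annotations\n",
              nrow(tb), length(object@membership)))
  if ("flagged_parent" %in% colnames(tb)) {
    fl <- table(tb$flagged_parent[!is.na(tb$flagged_parent)])
    cat(sprintf("  flagged parent-specific: %s\n",
                if (length(fl) == 0) "none"
                else paste(sprintf("%s=%d", names(fl), as.integer(fl)), collapse = ", ")))
  }
})

#' @describeIn KmerLibrary-class member table (kmer, count_a1, count_a2)
#' @param x object
#' @export
setGeneric("kmerMembers", function(x) standardGeneric("kmerMembers"))
#' @export
setMethod("kmerMembers", "KmerLibrary", function(x) x@members)

#' @describeIn KmerLibrary-class k-mer length
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))
#' @export
setMethod("kmerSize", "KmerLibrary", function(x) x@k)

#' @describeIn KmerLibrary-class parent label ("a1"/"a2")
#' @export
setGeneric("parentLabel", function(x) standardGeneric("parentLabel"))
#' @export
setMethod("parentLabel", "KmerLibrary", function(x) x@parent)

#' @export
setMethod("length", "KmerLibrary", function(x) nrow(x@members))

setMethod("show", "KmerLibrary", function(object) {
  cat(sprintf("KmerLibrary: parent %s, k = %d, %d member k-mer(s)\n",
              object@parent, object@k, nrow(object@members)))
  th <- object@thresholds
  if (length(th) > 0)
    cat(sprintf("  thresholds: %s\n",
                paste(sprintf("%s=%s", names(th), unlist(th)), collapse = ", ")))
})

#' @describeIn BinRatioTrack-class bins as a GRanges with track columns
#' @param x object
#' @export
setGeneric("trackBins", function(x) standardGeneric("trackBins"))
#' @export
setMethod("trackBins", "BinRatioTrack", function(x) x@bins)

#' @export
setMethod("length", "BinRatioTrack", function(x) length(x@bins))

setMethod("show", "BinRatioTrack", function(object) {
  gr <- object@bins
  r <- mcols(gr)$log2_ratio
  cat(sprintf("BinRatioTrack: %d bin(s) on %d sequence(s); %d +Inf, %d -Inf, %d undefined\n",
              length(gr), length(unique(as.character(seqnames(gr)))),
              sum(is.infinite(r) & r > 0, na.rm = TRUE),
              sum(is.infinite(r) & r < 0, na.rm = TRUE),
              sum(mcols(gr)$undefined)))
})
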