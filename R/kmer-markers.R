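#' @include repeat-clustering.R
NULL

# extract interval sequences as plain uppercase character strings
extractIntervalSeqs <- function(assembly, gr) {
  if (length(gr) == 0) return(character())
  sq <- as.character(seqnames(gr))
  bad <- !sq %in% names(assembly)
  if (any(bad)) stop("interval on unknown sequence: ", unique(sq[bad])[1])
  vapply(seq_along(gr), function(i) {
    toupper(as.character(Biostrings::subseq(assembly[[sq[i]]],
                                            start(gr)[i], end(gr)[i])))
  }, character(1))
}

#' Count canonical k-mers over sequences or intervals
#'
#' Every length-k window over A/C/G/T contributes one count to its
#' canonical form (the lexicographically smaller of the window and its
#' reverse complement); windows containing any other character are
#' skipped. Counts are additive over input intervals; sequences shorter
#' than k contribute nothing. Counting streams over the input and holds
#' only the k-mer/count association.
#'
#' @param sequences character vector of sequences, or a DNAStringSet.
#' @param k k-mer length (1..64; the counting kernel packs k-mers 2-bit).
#' @return named numeric vector: canonical k-mer -> count.
#' @export
countKmers <- function(sequences, k) {
  stopifnot(k >= 1)
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  cpp_count_kmers(toupper(sequences), as.integer(k))
}

#' Select lineage-enriched k-mers by frequency and log2-fold change
#'
#' A k-mer enters the a1 library iff its a1-bin count >= \code{min_freq_a1}
#' and log2(count_a1/count_a2) >= \code{min_abs_log2fc}, where a zero
#' opposite count gives an infinite fold change (which passes);
#' symmetrically for a2 with \code{min_freq_a2} and the negated fold
#' change. No k-mer can satisfy both sides, so the two libraries are
#' disjoint by construction (asserted). Thresholds are recorded in each
#' library's provenance block.
#'
#' @param counts_a1,counts_a2 named count vectors from
#'   \code{\link{countKmers}}, built with the same k.
#' @param min_freq_a1 minimum a1-bin frequency (default 400).
#' @param min_freq_a2 minimum a2-bin frequency (default 250).
#' @param min_abs_log2fc minimum absolute log2-fold change (default 4.25).
#' @param k k-mer length; inferred from the counts when NULL.
#' @return list of two \linkS4class{KmerLibrary} objects (\code{a1},
#'   \code{a2}).
#' @export
selectEnrichedKmers <- function(counts_a1, counts_a2, min_freq_a1 = 400,
                                min_freq_a2 = 250, min_abs_log2fc = 4.25,
                                k = NULL) {
  if (min_freq_a1 <= 0 || min_freq_a2 <= 0 || min_abs_log2fc <= 0)
    stop("thresholds must be positive")
  keys <- union(names(counts_a1), names(counts_a2))
  if (is.null(k)) {
    if (length(keys) == 0) stop("cannot infer k from empty counts")
    k <- nchar(keys[1])
  }
  c1 <- ifelse(is.na(counts_a1[keys]), 0, counts_a1[keys])
  c2 <- ifelse(is.na(counts_a2[keys]), 0, counts_a2[keys])
  lfc <- ifelse(c1 > 0 & c2 == 0, Inf,
                ifelse(c1 == 0 & c2 > 0, -Inf, log2(c1 / c2)))
  inA1 <- c1 >= min_freq_a1 & lfc >= min_abs_log2fc
  inA2 <- c2 >= min_freq_a2 & -lfc >= min_abs_log2fc
  stopifnot(!any(inA1 & inA2))
  th <- list(min_freq_a1 = min_freq_a1, min_freq_a2 = min_freq_a2,
             min_abs_log2fc = min_abs_log2fc)
  mk <- function(sel, parent) {
    new("KmerLibrary", k = as.integer(k), parent = parent,
        members = DataFrame(kmer = keys[sel], count_a1 = unname(c1[sel]),
                            count_a2 = unname(c2[sel])),
        thresholds = th)
  }
  list(a1 = mk(inA1, "a1"), a2 = mk(inA2, "a2"))
}

#' Build marker libraries for all k sizes from the provisional partition
#'
#' For each k, canonical k-mers are counted only inside the respective
#' parent's provisional source bins and filtered with
#' \code{\link{selectEnrichedKmers}}. Libraries are kept per k (two per
#' size); downstream painting unions their hit intervals.
#'
#' @param partition GRanges from \code{\link{provisionalPartition}}.
#' @param assembly DNAStringSet of the phased assembly.
#' @param k_sizes integer vector of k-mer lengths (default 20, 30, 40, 50).
#' @param min_freq_a1,min_freq_a2,min_abs_log2fc selection thresholds.
#' @return list of \linkS4class{KmerLibrary} objects, two per k, named
#'   like \code{"a1.k20"}.
#' @export
buildMarkerSet <- function(partition, assembly, k_sizes = c(20L, 30L, 40L, 50L),
                           min_freq_a1 = 400, min_freq_a2 = 250,
                           min_abs_log2fc = 4.25) {
  binsA1 <- partition[mcols(partition)$parent == "a1"]
  binsA2 <- partition[mcols(partition)$parent == "a2"]
  if (length(binsA1) == 0 || length(binsA2) == 0)
    stop("insufficient lineage signal: empty provisional bins for one parent")
  seqA1 <- extractIntervalSeqs(assembly, binsA1)
  seqA2 <- extractIntervalSeqs(assembly, binsA2)
  out <- list()
  for (k in k_sizes) {
    # joint counting keeps only frequency-filter candidates (with exact
    # counts on both sides), so the selection below is unchanged while the
    # k-mer/count association stays small
    cand <- cpp_count_kmers_pair(seqA1, seqA2, as.integer(k),
                                 min_freq_a1, min_freq_a2)
    libs <- selectEnrichedKmers(setNames(cand$count_a1, cand$kmer),
                                setNames(cand$count_a2, cand$kmer),
                                min_freq_a1, min_freq_a2, min_abs_log2fc,
                                k = k)
    out[[sprintf("a1.k%d", k)]] <- libs$a1
    out[[sprintf("a2.k%d", k)]] <- libs$a2
  }
  out
}

#' Write a marker library (tab-separated, with provenance header)
#'
#' Format: header lines \code{# k=}, \code{# parent=}, \code{# thresholds=}
#' followed by one record per line \code{kmer<TAB>count_a1<TAB>count_a2}.
#' Round-trips bit-exactly through \code{\link{readKmerLibrary}}.
#'
#' @param library KmerLibrary.
#' @param path output path.
#' @export
writeKmerLibrary <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  th <- library@thresholds
  writeLines(c(sprintf("# k=%d", library@k),
               sprintf("# parent=%s", library@parent),
               sprintf("# thresholds=%s",
                       paste(sprintf("%s:%.10g", names(th), unlist(th)),
                             collapse = ","))), con)
  m <- library@members
  if (nrow(m) > 0)
    writeLines(sprintf("%s\t%.10g\t%.10g", m$kmer, m$count_a1, m$count_a2), con)
  invisible(path)
}

#' Read a marker library written by \code{\link{writeKmerLibrary}}
#' @param path library file path.
#' @return KmerLibrary.
#' @export
readKmerLibrary <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  getv <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, "="))]
    if (length(ln) != 1) stop("missing header field: ", key)
    sub(paste0("^# ", key, "="), "", ln)
  }
  k <- as.integer(getv("k"))
  parent <- getv("parent")
  thparts <- strsplit(strsplit(getv("thresholds"), ",")[[1]], ":")
  th <- lapply(thparts, function(p) as.numeric(p[2]))
  names(th) <- vapply(thparts, `[[`, "", 1)
  if (length(body) == 0) {
    members <- DataFrame(kmer = character(), count_a1 = numeric(),
                         count_a2 = numeric())
  } else {
    f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    members <- DataFrame(kmer = f[, 1], count_a1 = as.numeric(f[, 2]),
                         count_a2 = as.numeric(f[, 3]))
  }
  new("KmerLibrary", k = k, parent = parent, members = members,
      thresholds = th)
}
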