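#' @include ancestry-painting.R
NULL

#' Diagnostic k-mers for an introgressed region
#'
#' Members are the canonical k-mers of the region minus all canonical
#' k-mers of the rest of the assembly (every sequence of both phases, the
#' region excised; the two flanks are treated as separate pieces so no
#' artificial junction k-mers arise). N-containing windows are skipped.
#'
#' @param assembly DNAStringSet (both phases).
#' @param region GRanges of length 1, the introgressed region.
#' @param k k-mer length (default 31).
#' @return list with \code{k}, \code{region}, \code{members} (character
#'   vector of canonical k-mers) and \code{background_excluded} (number of
#'   region k-mers discarded for occurring elsewhere).
#' @export
diagnosticKmers <- function(assembly, region, k = 31L) {
  stopifnot(length(region) == 1)
  sq <- as.character(seqnames(region))
  if (!sq %in% names(assembly)) stop("region on unknown sequence: ", sq)
  len <- Biostrings::width(assembly)[match(sq, names(assembly))]
  if (start(region) < 1 || end(region) > len) stop("region out of bounds")
  if (k > width(region)) stop("k larger than region length")
  seqs <- setNames(toupper(as.character(assembly)), names(assembly))
  regionSeq <- substr(seqs[[sq]], start(region), end(region))
  rest <- unname(seqs[names(seqs) != sq])
  left <- substr(seqs[[sq]], 1, start(region) - 1)
  right <- substr(seqs[[sq]], end(region) + 1, len)
  rest <- c(rest, left, right)
  rest <- rest[nchar(rest) > 0]
  res <- cpp_diagnostic_kmers(regionSeq, rest, as.integer(k))
  if (length(res$members) == 0)
    stop("region not diagnosable: every region k-mer occurs elsewhere")
  list(k = as.integer(k), region = region,
       members = sort(as.character(res$members), method = "radix"),
       background_excluded = res$background_excluded)
}

#' Score reads for diagnostic k-mer carriage
#'
#' A read counts as a carrier iff it contains at least \code{min_hits}
#' windows whose canonical form is a member k-mer. Streaming: reads are
#' processed in chunks, so memory is constant in read count.
#'
#' @param reads character vector, DNAStringSet, or path to a FASTQ(.gz)
#'   file.
#' @param kit diagnostic set from \code{\link{diagnosticKmers}}.
#' @param min_hits minimum member windows per carrier read (default 1).
#' @param chunk_size reads per chunk when streaming from a file.
#' @return list with \code{reads_with_kmer}, \code{total_reads},
#'   \code{proportion} (0 when no reads).
#' @export
scoreReads <- function(reads, kit, min_hits = 1L, chunk_size = 100000L) {
  k <- kit$k
  members <- kit$members
  nCarrier <- 0L
  nTotal <- 0L
  scoreChunk <- function(chunk) {
    hits <- cpp_read_hit_counts(toupper(chunk), members, k)
    nCarrier <<- nCarrier + sum(hits >= min_hits)
    nTotal <<- nTotal + length(chunk)
  }
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    con <- if (grepl("\\.gz$", reads)) gzfile(reads, "r") else file(reads, "r")
    on.exit(close(con))
    repeat {
      lines <- readLines(con, n = 4L * chunk_size)
      if (length(lines) == 0) break
      scoreChunk(lines[seq(2, length(lines), by = 4)])
    }
  } else {
    if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
    scoreChunk(reads)
  }
  list(reads_with_kmer = as.integer(nCarrier), total_reads = as.integer(nTotal),
       proportion = if (nTotal == 0) 0 else nCarrier / nTotal)
}

#' Cluster individuals into 0/1/2 introgression-copy classes
#'
#' One-dimensional k-means (k = 3) on carrier proportions with
#' deterministic centers initialized at (min, median, max); classes are
#' ordered by final center, lowest = 0 copies. When fewer than 3 distinct
#' proportions exist the clustering is degenerate: all individuals are
#' "unassigned" (with a warning).
#'
#' @param genotypes data.frame with columns \code{individual_id},
#'   \code{reads_with_kmer}, \code{total_reads}, \code{proportion}.
#' @param seed RNG seed (the initialization is deterministic; the seed
#'   fixes any tie-breaking inside kmeans).
#' @return list with \code{genotypes} (input plus \code{copy_class}) and
#'   \code{centers} (sorted cluster centers, or NULL when degenerate).
#' @export
clusterCopyClasses <- function(genotypes, seed = 1L) {
  stopifnot(nrow(genotypes) >= 3, all(genotypes$total_reads > 0))
  p <- genotypes$proportion
  if (length(unique(p)) < 3) {
    warning("fewer than 3 distinct proportions; all individuals unassigned")
    genotypes$copy_class <- rep("unassigned", nrow(genotypes))
    return(list(genotypes = genotypes, centers = NULL))
  }
  set.seed(seed)
  if (nrow(genotypes) == 3) {
    # one individual per class: each defines its own center
    classOf <- rank(p, ties.method = "first") - 1L
    centers <- sort(p)
  } else {
    init <- matrix(c(min(p), median(p), max(p)), ncol = 1)
    km <- kmeans(matrix(p, ncol = 1), centers = init, iter.max = 100L)
    ord <- order(km$centers[, 1])
    classOf <- match(km$cluster, ord) - 1L
    centers <- sort(km$centers[, 1])
  }
  genotypes$copy_class <- as.character(classOf)
  list(genotypes = genotypes, centers = centers)
}

#' Chi-square goodness-of-fit test for copy-class segregation
#'
#' Pearson goodness of fit of the (n0, n1, n2) class counts against an
#' expected ratio, 1:2:1 by default (the F2 expectation for a codominant
#' locus); df = 2.
#'
#' @param class_counts integer vector (n0, n1, n2).
#' @param expected_ratio expected ratio (default c(1, 2, 1)).
#' @return list with \code{chi_square}, \code{df}, \code{p_value},
#'   \code{expected}.
#' @export
segregationTest <- function(class_counts, expected_ratio = c(1, 2, 1)) {
  stopifnot(length(class_counts) == length(expected_ratio))
  if (any(expected_ratio <= 0)) stop("expected ratio entries must be positive")
  if (sum(class_counts) <= 0) stop("no individuals to test")
  ht <- suppressWarnings(chisq.test(class_counts,
                                    p = expected_ratio / sum(expected_ratio)))
  list(chi_square = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = unname(ht$expected))
}

#' Write genotype table as TSV
#' @param genotypes data.frame from \code{\link{clusterCopyClasses}}.
#' @param path output path.
#' @param header optional comment lines.
#' @export
writeGenotypeTSV <- function(genotypes, path, header = NULL) {
  writeTSVWithHeader(genotypes, path, header)
}

#' Parse a 1-based inclusive "seq:start-end" region string into a GRanges
#' @param x region string, e.g. "chr08.1:1000000-27000000".
#' @export
parseRegion <- function(x) {
  m <- regmatches(x, regexec("^(.+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4) stop("malformed region string: ", x)
  GRanges(m[2], IRanges(as.numeric(gsub(",", "", m[3])),
                        as.numeric(gsub(",", "", m[4]))))
}
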