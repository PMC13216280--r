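#' @include introgression.R
NULL

#' Read a window-count table
#'
#' Expects columns \code{seq_id}, \code{start}, \code{end} (0-based
#' half-open) followed by one count column per sample.
#'
#' @param path TSV path.
#' @return list with \code{windows} (data.frame seq_id/start/end) and
#'   \code{counts} (numeric matrix, one column per sample).
#' @export
readWindowCounts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("seq_id", "start", "end") %in% colnames(df)))
  samples <- setdiff(colnames(df), c("seq_id", "start", "end"))
  list(windows = df[, c("seq_id", "start", "end")],
       counts = as.matrix(df[, samples, drop = FALSE]))
}

#' Normalize window read counts to coverage and to a reference individual
#'
#' Each sample's per-window count is first normalized to its sequencing
#' coverage (divided by library size) and then to the reference
#' individual's rate in the same window:
#' normalized(w, s) = (count(w,s)/lib(s)) / (count(w,ref)/lib(ref)).
#' The reported value is log2(normalized); samples with 0 reads in a
#' window give -Inf (flagged), and windows where the reference has 0
#' reads are undefined (NA).
#'
#' @param counts numeric matrix, windows x samples.
#' @param library_size named vector of total reads per sample; defaults
#'   to column sums of \code{counts}.
#' @param reference_sample reference column name.
#' @return list with \code{normalized} (ratio scale) and \code{log2}
#'   matrices, both windows x samples.
#' @export
normalizeCounts <- function(counts, library_size = colSums(counts),
                            reference_sample) {
  if (!reference_sample %in% colnames(counts))
    stop("unknown reference sample: ", reference_sample)
  if (!all(colnames(counts) %in% names(library_size)))
    stop("library_size missing for some samples")
  rate <- sweep(counts, 2, library_size[colnames(counts)], "/")
  refRate <- rate[, reference_sample]
  norm <- sweep(rate, 1, refRate, "/")
  norm[refRate == 0, ] <- NA_real_
  lg <- log2(norm)
  list(normalized = norm, log2 = lg)
}

#' Per-window log2-fold contrast between two sample groups
#'
#' Group means are taken on the unlogged normalized values; the contrast
#' is log2(mean_a / mean_b) per window. Undefined windows (reference had
#' no reads) stay NA; a zero group mean gives a flagged infinite value.
#'
#' @param normalized matrix of normalized values
#'   (\code{\link{normalizeCounts}}).
#' @param group_a,group_b character vectors of sample names.
#' @return numeric vector of per-window contrasts (extended reals).
#' @export
groupContrast <- function(normalized, group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  missing <- setdiff(c(group_a, group_b), colnames(normalized))
  if (length(missing) > 0)
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  ma <- rowMeans(normalized[, group_a, drop = FALSE])
  mb <- rowMeans(normalized[, group_b, drop = FALSE])
  if (all(is.na(ma)) || all(is.na(mb)))
    stop("a group has no valid windows")
  ifelse(is.na(ma) | is.na(mb), NA_real_,
         ifelse(ma > 0 & mb > 0, log2(ma / mb),
                ifelse(ma > 0, Inf, ifelse(mb > 0, -Inf, NA_real_))))
}

#' Write normalized values and a group contrast as TSV
#' @param windows data.frame (seq_id, start, end).
#' @param normalized matrix from \code{\link{normalizeCounts}}.
#' @param contrast optional per-window contrast vector.
#' @param path output path.
#' @param header optional comment lines.
#' @export
writeContrastTSV <- function(windows, normalized, contrast = NULL, path,
                             header = NULL) {
  df <- cbind(windows, as.data.frame(normalized))
  if (!is.null(contrast)) df$log2_contrast <- contrast
  writeTSVWithHeader(df, path, header)
}
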