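mkLib <- function(kmers, parent, k = nchar(kmers[1])) {
  new("KmerLibrary", k = as.integer(k), parent = parent,
      members = S4Vectors::DataFrame(kmer = kmers,
                                     count_a1 = rep(0, length(kmers)),
                                     count_a2 = rep(0, length(kmers))),
      thresholds = list())
}

# build a one-sequence track directly from per-bin a1/a2 tag counts
mkTrack <- function(a1, a2, bin = 100L) {
  n <- length(a1)
  gr <- GRanges("s", IRanges(start = (seq_len(n) - 1L) * bin + 1L,
                             width = bin))
  GenomeInfoDb::seqlengths(gr) <- c(s = n * bin)
  ratio <- ifelse(a1 > 0 & a2 > 0, log2(a1 / a2),
                  ifelse(a1 > 0, Inf, ifelse(a2 > 0, -Inf, NA_real_)))
  mcols(gr) <- S4Vectors::DataFrame(a1_bp = a1, a2_bp = a2,
                                    log2_ratio = ratio,
                                    display_value = NA_real_,
                                    undefined = a1 == 0 & a2 == 0)
  new("BinRatioTrack", bins = gr)
}

test_that("annotateKmerHits tags perfect matches on both strands and unions overlaps", {
  asm <- DNAStringSet(c(s = "AAAAATTTTT"))
  tagged <- annotateKmerHits(asm, list(mkLib("AAAAA", "a1")))
  # TTTTT matches via reverse complement; union covers the whole sequence
  expect_equal(sum(width(tagged$a1)), 10L)
  expect_equal(length(tagged$a2), 0L)

  # zero-member libraries tag nothing
  tagged <- annotateKmerHits(asm, list(mkLib(character(0), "a1", k = 5)))
  expect_equal(sum(width(tagged$a1)), 0L)

  # overlapping hits count union bp, not summed bp
  s <- paste0(strrep("AC", 15), randomSeq(30))
  asm <- DNAStringSet(c(s = s))
  lib <- mkLib(names(countKmers(strrep("AC", 15), 20)), "a1")
  tagged <- annotateKmerHits(asm, list(lib))
  expect_equal(sum(width(tagged$a1)), 30L)
})

test_that("annotateKmerHits agrees with a matchPDict-based oracle", {
  set.seed(21)
  seq <- randomSeq(3000)
  asm <- DNAStringSet(c(s = seq))
  # pull real windows so hits exist, plus decoys
  st <- sample(2980, 25)
  kmers <- unique(canonicalUnit(substring(seq, st, st + 19)))
  kmers <- names(countKmers(substring(seq, st, st + 19), 20))
  lib <- mkLib(kmers, "a1")
  tagged <- annotateKmerHits(asm, list(lib))

  pd <- Biostrings::PDict(DNAStringSet(kmers))
  subj <- DNAString(seq)
  fwd <- unlist(Biostrings::matchPDict(pd, subj))
  rev <- unlist(Biostrings::matchPDict(pd, Biostrings::reverseComplement(subj)))
  revR <- IRanges(3000 - end(rev) + 1, 3000 - start(rev) + 1)
  want <- reduce(c(IRanges(start(fwd), end(fwd)), revR))
  expect_equal(as.data.frame(ranges(tagged$a1))[, 1:2],
               as.data.frame(want)[, 1:2])
})

test_that("binGenome makes near-equal bins that tile exactly", {
  b <- binGenome(1000000, 500000)
  expect_equal(length(b), 2L)
  expect_equal(width(b), c(500000L, 500000L))

  b <- binGenome(1234567, 500000)
  expect_equal(width(b), c(617283L, 617284L))

  expect_equal(length(binGenome(100, 500000)), 1L)

  set.seed(3)
  for (i in 1:200) {
    len <- sample(1:5000000, 1)
    tgt <- sample(1:1000000, 1)
    b <- binGenome(len, tgt)
    expect_equal(sum(width(b)), len)
    expect_equal(start(b)[1], 1L)
    expect_true(all(diff(width(b)) %in% -1:1))
    if (length(b) > 1) expect_equal(start(b)[-1], end(b)[-length(b)] + 1L)
  }
})

test_that("binRatios applies the five-case extended-real rule", {
  tagged <- list(a1 = GRanges("s", IRanges(1, 4000)),
                 a2 = GRanges("s", IRanges(1, 1000)))
  tr <- binRatios(tagged, c(s = 10000L), bin_size = 10000L)
  expect_equal(mcols(trackBins(tr))$log2_ratio, 2)

  tagged <- list(a1 = GRanges("s", IRanges(1, 3000)), a2 = GRanges())
  tr <- binRatios(tagged, c(s = 10000L), bin_size = 10000L)
  expect_equal(mcols(trackBins(tr))$log2_ratio, Inf)

  tagged <- list(a1 = GRanges(), a2 = GRanges())
  tr <- binRatios(tagged, c(s = 10000L), bin_size = 10000L)
  expect_true(is.na(mcols(trackBins(tr))$log2_ratio))
  expect_true(mcols(trackBins(tr))$undefined)

  tagged <- list(a1 = GRanges("s", IRanges(1, 500)),
                 a2 = GRanges("s", IRanges(1001, 1500)))
  tr <- binRatios(tagged, c(s = 10000L), bin_size = 10000L)
  expect_equal(mcols(trackBins(tr))$log2_ratio, 0)
})

test_that("displayTransform maps infinities just outside the finite range", {
  # finite range {-2.9, 0.4, 2.9}: +Inf -> 3.1, -Inf -> -3.1
  tr <- mkTrack(a1 = c(10, 100 * 2^0.4, 100 * 2^2.9, 140, 0),
                a2 = c(10 * 2^2.9, 100, 100, 0, 70), bin = 1000L)
  tr2 <- displayTransform(tr)
  dv <- mcols(trackBins(tr2))$display_value
  r <- mcols(trackBins(tr2))$log2_ratio
  expect_equal(dv[is.finite(r)], r[is.finite(r)])
  expect_equal(dv[r == Inf], 3.1)
  expect_equal(dv[r == -Inf], -3.1)

  # no finite bins: fallback uses 0, +Inf -> 0.1
  tr <- mkTrack(a1 = c(5, 7), a2 = c(0, 0))
  dv <- mcols(trackBins(displayTransform(tr)))$display_value
  expect_equal(dv, c(0.1, 0.1))

  # no infinite bins: display equals the ratio
  tr <- mkTrack(a1 = c(10, 40), a2 = c(20, 10))
  dv <- mcols(trackBins(displayTransform(tr)))$display_value
  expect_equal(dv, mcols(trackBins(tr))$log2_ratio)

  # undefined bins display 0 and keep their flag
  tr <- mkTrack(a1 = c(10, 0), a2 = c(5, 0))
  tr2 <- displayTransform(tr)
  expect_equal(mcols(trackBins(tr2))$display_value[2], 0)
  expect_true(mcols(trackBins(tr2))$undefined[2])
})

test_that("segmentAncestry cuts at tag-filtered zero crossings", {
  # signs + + + - -, all well tagged: 2 segments, boundary at bin 3|4
  tr <- mkTrack(a1 = c(100, 100, 100, 10, 10), a2 = c(10, 10, 10, 100, 100))
  seg <- segmentAncestry(tr, min_tag_bp = 50)
  expect_equal(length(seg), 2L)
  expect_identical(mcols(seg)$parent, c("a1", "a2"))
  expect_equal(end(seg)[1], 300L)
  expect_equal(start(seg)[2], 301L)
  expect_equal(mcols(seg)$n_bins, c(3L, 2L))

  # the dissenting bin has only 10 bp of tags: both crossings rejected
  tr <- mkTrack(a1 = c(100, 100, 0, 100, 100), a2 = c(10, 10, 10, 10, 10))
  seg <- segmentAncestry(tr, min_tag_bp = 50)
  expect_equal(length(seg), 1L)
  expect_identical(mcols(seg)$parent, "a1")

  # all positive: one segment spanning the sequence
  tr <- mkTrack(a1 = c(100, 100, 100), a2 = c(1, 1, 1))
  seg <- segmentAncestry(tr)
  expect_equal(length(seg), 1L)
  expect_equal(width(seg), 300L)

  # neutral bins inherit the previous signed bin; leading neutrals the first
  tr <- mkTrack(a1 = c(0, 100, 100, 50, 10), a2 = c(0, 10, 10, 50, 100))
  seg <- segmentAncestry(tr, min_tag_bp = 50)
  expect_equal(length(seg), 2L)
  expect_equal(end(seg)[1], 400L)  # zero bin 4 stays with the + run

  # no signed bin at all: single unassigned segment
  tr <- mkTrack(a1 = c(0, 0), a2 = c(0, 0))
  seg <- segmentAncestry(tr)
  expect_identical(mcols(seg)$parent, "unassigned")
})

test_that("segmentation reads raw ratios, not display values", {
  tr <- mkTrack(a1 = c(100, 100, 0, 0), a2 = c(0, 0, 80, 90))
  before <- segmentAncestry(tr)
  after <- segmentAncestry(displayTransform(tr))
  expect_equal(as.data.frame(before), as.data.frame(after))
})

test_that("track TSV and paint BED round-trip", {
  tr <- displayTransform(mkTrack(a1 = c(100, 0, 3), a2 = c(10, 90, 3)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTrackTSV(tr, path, header = "test")
  back <- readTrackTSV(path)
  expect_equal(as.data.frame(trackBins(back)), as.data.frame(trackBins(tr)))

  seg <- segmentAncestry(tr)
  bed <- withr::local_tempfile(fileext = ".bed")
  writePaintBED(seg, tr, bed)
  lines <- readLines(bed)
  expect_equal(length(lines), length(seg))
  expect_match(lines[1], "\ta1\t|\ta2\t")

  # empty segments produce an empty file
  writePaintBED(seg[0], tr, bed)
  expect_equal(length(readLines(bed)), 0L)
})
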