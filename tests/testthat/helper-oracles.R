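# Independent brute-force oracles and small fixture builders. These stay
# deliberately separate from the package's implementation paths: string
# handling is done with substring/chartr loops, interval arithmetic with
# plain position vectors.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
  library(S4Vectors)
})

oracleRevComp <- function(u) {
  chars <- rev(strsplit(u, "", fixed = TRUE)[[1]])
  paste(vapply(chars, function(c) {
    switch(c, A = "T", C = "G", G = "C", T = "A", N = "N")
  }, character(1)), collapse = "")
}

# exhaustive candidate enumeration for the canonical unit
oracleCanonicalUnit <- function(u) {
  n <- nchar(u)
  rots <- function(x) {
    vapply(seq_len(n), function(i) {
      paste0(substring(x, i, n), substring(x, 1, i - 1))
    }, character(1))
  }
  cand <- c(rots(u), rots(oracleRevComp(u)))
  sort(cand, method = "radix")[1]
}

# window-by-window canonical k-mer counting with substring
oracleCountKmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(integer(0))
  out <- new.env()
  for (i in seq_len(n - k + 1)) {
    w <- substring(seq, i, i + k - 1)
    if (grepl("[^ACGT]", w)) next
    rc <- oracleRevComp(w)
    key <- if (w <= rc) w else rc
    out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) + 1
  }
  unlist(as.list(out))
}

# straightforward loop applying the three enrichment-filter conditions
oracleSelect <- function(c1, c2, f1, f2, fc) {
  keys <- union(names(c1), names(c2))
  a1 <- character(0); a2 <- character(0)
  for (key in keys) {
    x1 <- if (key %in% names(c1)) c1[[key]] else 0
    x2 <- if (key %in% names(c2)) c2[[key]] else 0
    l <- if (x2 == 0 && x1 > 0) Inf else if (x1 == 0 && x2 > 0) -Inf else log2(x1 / x2)
    if (x1 >= f1 && l >= fc) a1 <- c(a1, key)
    if (x2 >= f2 && -l >= fc) a2 <- c(a2, key)
  }
  list(a1 = sort(a1), a2 = sort(a2))
}

# vectorized canonical forms of fixed-width windows (for larger oracles)
oracleCanonicalWindows <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  w <- substring(seq, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
  w <- w[!grepl("[^ACGT]", w)]
  if (length(w) == 0) return(character(0))
  cols <- lapply(seq_len(k), function(i) substring(w, i, i))
  rc <- do.call(paste0, lapply(rev(cols), function(x) chartr("ACGT", "TGCA", x)))
  ifelse(w <= rc, w, rc)
}

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

makeCatalog <- function(seq_id, start0, end0, unit = "ACG", score = NULL,
                        seqlengths = NULL) {
  # 0-based half-open inputs, as in the interval examples
  if (is.null(score)) score <- 2 * (end0 - start0)
  RepeatCatalog(seq_id, start0 + 1L, end0, rep(unit, length(start0)),
                score = score, seqlengths = seqlengths)
}

# scaled-down configuration for fast unit tests (the desk preset is used
# by the acceptance suite)
microPreset <- function(seed = 1L) {
  cfg <- simulationPreset("desk", seed = seed)
  cfg$chromosome_length <- 300000L
  cfg$array_length <- 10000L
  cfg$mini_length <- 200L
  cfg$mini_spacing <- 5000L
  cfg$bin_size <- 10000L
  cfg$merge_distance <- 10000L
  cfg$window_size <- 50000L
  cfg$min_freq_a1 <- 30
  cfg$min_freq_a2 <- 20
  cfg$b_min <- 15000
  cfg$pop_chrom_length <- 60000L
  cfg$population_n <- 30L
  cfg
}

makeMicroHybrid <- function(seed = 1L) {
  cfg <- microPreset(seed)
  par <- simulateParents(cfg)
  hyb <- simulateHybridAssembly(par, defaultAncestryPlan(cfg))
  list(cfg = cfg, parents = par, hybrid = hyb)
}
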