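#' @include divergence.R
NULL

DESK_UNIT_P1 <- "ACCGTGATC"
DESK_UNIT_P2 <- "ACTGCTAGG"

#' Simulation presets
#'
#' Named parameter sets for the synthetic hybrid-genome generator.
#' \code{"desk"} is the scaled-down validation setting used throughout the
#' test suite: 2 chromosomes of 3 Mb per phase, 2\% per-branch divergence
#' from a shared ancestor, one private 9-bp satellite unit per parent
#' planted as three 30 kb arrays plus dispersed 300 bp mini-arrays every
#' ~20 kb (a lineage-specific family that is both clustered and
#' dispersed, so marker k-mers tile the chromosomes), a parent-2
#' introgression on chr2 phase 1 at fractions 0.4-0.6, 50 kb painting
#' bins, and count-denominated k-mer thresholds rescaled to 100/60
#' (preserving the 400:250 asymmetry of the full-scale setting) with all
#' bp-denominated thresholds unchanged. \code{"paper"} carries the
#' full-scale parameter values (500 kb bins, frequency filters 400/250,
#' 5 Mb coverage windows) for use on real-sized assemblies.
#'
#' @param preset \code{"desk"} or \code{"paper"}.
#' @param seed integer seed; every generator output is a pure function of
#'   the returned configuration.
#' @return named list of simulation and analysis parameters.
#' @export
simulationPreset <- function(preset = c("desk", "paper"), seed = 1L) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    seed = as.integer(seed),
    n_chromosomes = 2L,
    chromosome_length = 3000000L,
    parental_divergence = 0.02,
    satellite_units = c(parent1 = DESK_UNIT_P1, parent2 = DESK_UNIT_P2),
    # big arrays: (chromosome, fraction) per parent; kept clear of the
    # default introgression zone on chr2 (fractions 0.4-0.6)
    array_length = 30000L,
    array_positions = list(
      parent1 = data.frame(chrom = c(1L, 1L, 2L), frac = c(0.10, 0.80, 0.15)),
      parent2 = data.frame(chrom = c(1L, 2L, 2L), frac = c(0.30, 0.70, 0.90))),
    mini_length = 300L,
    mini_spacing = 20000L,
    introgression = list(seq = "chr2_p1", from = 0.4, to = 0.6,
                         donor = "parent2"),
    read_length = 100L,
    depth = 2,
    error_rate = 0,
    population_n = 128L,
    copy_ratio = c(1, 2, 1),
    pop_chrom_length = 150000L,
    pop_introgression = c(0.4, 0.6),
    # analysis parameters
    bin_size = 50000L,
    merge_distance = 50000L,
    window_size = 100000L,
    min_freq_a1 = 100,
    min_freq_a2 = 60,
    min_abs_log2fc = 4.25,
    k_sizes = c(20L, 30L, 40L, 50L),
    min_tag_bp = 50,
    s_min = 0.9,
    b_min = 50000,
    identity_threshold = 0.9,
    tandem_unit_lengths = c(5L, 7L, 9L, 11L, 13L),
    tandem_min_copies = 5L,
    top_n = 200L)
  if (preset == "paper") {
    base$chromosome_length <- 200000000L
    base$n_chromosomes <- 10L
    base$bin_size <- 500000L
    base$merge_distance <- 500000L
    base$window_size <- 5000000L
    base$min_freq_a1 <- 400
    base$min_freq_a2 <- 250
  }
  stopifnot(base$parental_divergence >= 0, base$parental_divergence < 1)
  base$satellite_units[] <- canonicalUnit(base$satellite_units)
  if (base$satellite_units[["parent1"]] == base$satellite_units[["parent2"]])
    stop("parental satellite units must differ")
  base
}

# sequences are held as integer base codes (0..3 = A,C,G,T) while being
# built; decoding goes through raw bytes for speed
decodeBases <- function(codes) {
  rawToChar(as.raw(c(65L, 67L, 71L, 84L)[codes + 1L]))
}

encodeBases <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
}

# mutate base codes at per-site rate m (substitutions only, always to a
# different base: shift by 1..3 mod 4, uniform over the alternatives)
mutateBases <- function(codes, m) {
  if (m <= 0) return(list(codes = codes, positions = integer()))
  idx <- which(runif(length(codes)) < m)
  if (length(idx) > 0) {
    codes[idx] <- (codes[idx] + sample.int(3L, length(idx), replace = TRUE)) %% 4L
  }
  list(codes = codes, positions = idx)
}

# overwrite tandem arrays of `unit` into the code vector at each 1-based
# start (all of common length len); single vectorized assignment
plantArrays <- function(codes, unit, starts, len) {
  if (length(starts) == 0) return(codes)
  tandem <- rep_len(encodeBases(unit), len)
  idx <- rep(as.integer(starts), each = len) + rep(seq_len(len) - 1L,
                                                   times = length(starts))
  codes[idx] <- rep(tandem, times = length(starts))
  codes
}

#' Simulate two diverged parental genomes with private satellite families
#'
#' A random ancestral background is mutated independently into parent 1
#' and parent 2 at the configured per-branch substitution rate
#' (substitutions only; exact k-mer matching is the downstream mechanism,
#' so indels are excluded). Each parent then receives its private
#' satellite family: large arrays at the configured (chromosome,
#' fraction) anchors and dispersed mini-arrays on a jittered grid, all
#' overwriting background so chromosome lengths and coordinates stay
#' aligned between parents. Deterministic per seed.
#'
#' @param config list from \code{\link{simulationPreset}}.
#' @return list with \code{parents} (list of two DNAStringSet),
#'   \code{satellites} (GRanges on parent coordinates with \code{parent},
#'   \code{unit}, \code{kind}) and \code{mutations} (per-parent list of
#'   per-chromosome substitution positions).
#' @export
simulateParents <- function(config) {
  set.seed(config$seed)
  L <- config$chromosome_length
  nchrom <- config$n_chromosomes
  if (config$array_length > L) stop("satellite array exceeds chromosome length")
  parentBases <- list(parent1 = list(), parent2 = list())
  mutations <- list(parent1 = list(), parent2 = list())
  sat <- list()
  for (ch in seq_len(nchrom)) {
    anc <- sample.int(4L, L, replace = TRUE) - 1L
    for (p in c("parent1", "parent2")) {
      mu <- mutateBases(anc, config$parental_divergence)
      bases <- mu$codes
      mutations[[p]][[ch]] <- mu$positions
      unit <- config$satellite_units[[p]]
      # big arrays anchored at fixed fractions
      ap <- config$array_positions[[p]]
      ap <- ap[ap$chrom == ch, , drop = FALSE]
      arrayRanges <- IRanges()
      if (nrow(ap) > 0) {
        at <- pmin(pmax(1L, as.integer(floor(ap$frac * L))),
                   L - config$array_length + 1L)
        bases <- plantArrays(bases, unit, at, config$array_length)
        arrayRanges <- IRanges(at, width = config$array_length)
        sat[[length(sat) + 1L]] <-
          GRanges(paste0("chr", ch), arrayRanges, parent = p, unit = unit,
                  kind = "array")
      }
      # dispersed mini-arrays on a jittered grid, skipping the big arrays
      if (config$mini_length <= 0) {
        parentBases[[p]][[ch]] <- bases
        next
      }
      jitMax <- min(8000L, max(0L, config$mini_spacing - config$mini_length - 100L))
      grid <- seq(min(10000L, max(1L, L %/% 30L)),
                  L - config$mini_length - jitMax - 1L,
                  by = config$mini_spacing)
      jit <- as.integer(floor(runif(length(grid), 0, jitMax)))
      at <- grid + jit
      miniR <- IRanges(at, width = config$mini_length)
      drop <- IRanges::overlapsAny(miniR, arrayRanges)
      miniR <- miniR[!drop]
      bases <- plantArrays(bases, unit, start(miniR), config$mini_length)
      sat[[length(sat) + 1L]] <-
        GRanges(paste0("chr", ch), miniR, parent = p, unit = unit,
                kind = "mini")
      parentBases[[p]][[ch]] <- bases
    }
  }
  toDSS <- function(lst) {
    DNAStringSet(setNames(vapply(lst, decodeBases, character(1)),
                          paste0("chr", seq_along(lst))))
  }
  list(parents = list(parent1 = toDSS(parentBases$parent1),
                      parent2 = toDSS(parentBases$parent2)),
       satellites = sort(suppressWarnings(do.call(c, sat))),
       mutations = mutations)
}

#' Default desk-scale ancestry plan
#'
#' chr1: parent-pure phases; chr2: phase 1 carries the configured donor
#' introgression, phase 2 is pure parent 2. Fractions are converted to bp
#' at build time.
#'
#' @param config list from \code{\link{simulationPreset}}.
#' @return named list: per assembly sequence a data.frame with
#'   \code{from}, \code{to} (fractions) and \code{parent}.
#' @export
defaultAncestryPlan <- function(config) {
  intro <- config$introgression
  plan <- list()
  for (ch in seq_len(config$n_chromosomes)) {
    for (phase in 1:2) {
      nm <- sprintf("chr%d_p%d", ch, phase)
      native <- if (phase == 1) "parent1" else "parent2"
      if (!is.null(intro) && nm == intro$seq) {
        plan[[nm]] <- data.frame(
          from = c(0, intro$from, intro$to),
          to = c(intro$from, intro$to, 1),
          parent = c(native, intro$donor, native))
      } else {
        plan[[nm]] <- data.frame(from = 0, to = 1, parent = native)
      }
    }
  }
  plan
}

#' Assemble a phased hybrid mosaic from the two parents
#'
#' Each assembly sequence is the concatenation of the designated parents'
#' segments (fraction intervals tiling [0,1], converted to bp on the
#' common parent coordinate system). The returned truth GRanges records
#' every junction exactly, with parents relabeled a1 (parent 1) / a2
#' (parent 2).
#'
#' @param parents list from \code{\link{simulateParents}}.
#' @param plan list from \code{\link{defaultAncestryPlan}} (or same
#'   shape); names must follow \code{"chr<i>_p<phase>"}.
#' @return list with \code{assembly} (DNAStringSet), \code{truth}
#'   (GRanges with \code{parent} in a1/a2) and \code{phase_of_sequence}
#'   (named vector).
#' @export
simulateHybridAssembly <- function(parents, plan) {
  seqs <- character(0)
  truth <- list()
  phase <- character(0)
  for (nm in names(plan)) {
    ch <- as.integer(sub("^chr([0-9]+)_p[12]$", "\\1", nm))
    ph <- sub("^chr[0-9]+_p", "phase", nm)
    pl <- plan[[nm]]
    if (abs(pl$from[1]) > 1e-9 || abs(pl$to[nrow(pl)] - 1) > 1e-9 ||
        (nrow(pl) > 1 && any(abs(pl$from[-1] - pl$to[-nrow(pl)]) > 1e-9)))
      stop("plan intervals must tile [0, 1] for ", nm)
    L <- Biostrings::width(parents$parents$parent1)[ch]
    cuts <- unique(c(0L, as.integer(floor(pl$to * L))))
    pieces <- character(nrow(pl))
    for (i in seq_len(nrow(pl))) {
      a <- cuts[i] + 1L
      b <- cuts[i + 1]
      src <- parents$parents[[pl$parent[i]]][[ch]]
      pieces[i] <- as.character(Biostrings::subseq(src, a, b))
      truth[[length(truth) + 1L]] <-
        GRanges(nm, IRanges(a, b),
                parent = ifelse(pl$parent[i] == "parent1", "a1", "a2"))
    }
    seqs[nm] <- paste(pieces, collapse = "")
    phase[nm] <- ph
  }
  assembly <- DNAStringSet(seqs)
  truth <- suppressWarnings(do.call(c, truth))
  seqlengths(truth) <-
    setNames(Biostrings::width(assembly), names(assembly))[GenomeInfoDb::seqlevels(truth)]
  list(assembly = assembly, truth = truth, phase_of_sequence = phase)
}

#' Simulate uniform error-prone reads from a genome and count them in windows
#'
#' Reads are drawn uniformly from all sequences of \code{genome}
#' proportional to length, at \code{depth}-fold coverage per sequence
#' copy; per-base substitution errors at \code{error_rate}. Exact source
#' positions are logged and tallied into a window-count vector (windows
#' from \code{\link{binGenome}}), enabling error-free count tables for
#' the coverage-contrast analysis.
#'
#' @param genome DNAStringSet (e.g. the two chromosome copies of one
#'   individual).
#' @param depth fold coverage per sequence.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @param window_size window size for the count table.
#' @return list with \code{reads} (character), \code{sources}
#'   (data.frame seq_id/start), \code{windows} (data.frame with counts).
#' @export
simulateReads <- function(genome, depth, read_length, error_rate = 0,
                          seed = 1L, window_size = 100000L) {
  stopifnot(depth > 0)
  set.seed(seed)
  reads <- list()
  src <- list()
  win <- list()
  for (nm in names(genome)) {
    L <- Biostrings::width(genome)[match(nm, names(genome))]
    n <- round(depth * L / read_length)
    starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
    s <- as.character(genome[[nm]])
    rd <- substring(s, starts, starts + read_length - 1L)
    if (error_rate > 0) {
      chars <- strsplit(paste(rd, collapse = ""), "", fixed = TRUE)[[1]]
      idx <- which(runif(length(chars)) < error_rate)
      if (length(idx) > 0) {
        alt <- c("A", "C", "G", "T")
        chars[idx] <- vapply(chars[idx],
                             function(b) sample(setdiff(alt, b), 1),
                             character(1), USE.NAMES = FALSE)
        rd <- substring(paste(chars, collapse = ""),
                        seq(1, length(chars), by = read_length),
                        seq(read_length, length(chars), by = read_length))
      }
    }
    reads[[nm]] <- rd
    src[[nm]] <- data.frame(seq_id = nm, start = starts)
    bins <- binGenome(L, window_size)
    binOf <- findInterval(starts, start(bins))
    cnt <- tabulate(binOf, nbins = length(bins))
    win[[nm]] <- data.frame(seq_id = nm, start = start(bins) - 1L,
                            end = end(bins), count = cnt)
  }
  list(reads = unname(unlist(reads)),
       sources = do.call(rbind, src),
       windows = do.call(rbind, win))
}

#' Write reads as FASTQ (optionally gzipped)
#' @param reads character vector of read sequences.
#' @param path output path; gzipped when it ends in .gz.
#' @param id_prefix read-name prefix.
#' @export
writeFASTQ <- function(reads, path, id_prefix = "read") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(reads) > 0) {
    recs <- sprintf("@%s_%d\n%s\n+\n%s", id_prefix, seq_along(reads), reads,
                    strrep("I", nchar(reads)))
    writeLines(recs, con)
  }
  invisible(path)
}

#' Simulate an introgression mapping population with ground truth
#'
#' A small recipient chromosome (parent 1 background with its dispersed
#' satellite family) and a donor homolog (parent 2) are simulated; the
#' "assembly" holds the introgression-carrying copy (phase 1) and the
#' recipient copy (phase 2). Each of \code{population_n} individuals
#' draws 0/1/2 introgression copies with probabilities 1:2:1 and receives
#' error-free uniform reads from its two chromosome copies.
#'
#' @param config list from \code{\link{simulationPreset}}.
#' @param seed overrides \code{config$seed} when non-NULL.
#' @return list with \code{assembly} (DNAStringSet: chrP_p1 carries the
#'   introgression), \code{region} (GRanges of the introgressed region on
#'   chrP_p1), \code{true_copies} (integer vector per individual),
#'   \code{reads} (list of per-individual read vectors).
#' @export
simulatePopulation <- function(config, seed = NULL) {
  cfg <- config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg$n_chromosomes <- 1L
  cfg$chromosome_length <- cfg$pop_chrom_length
  cfg$array_positions <- list(parent1 = data.frame(chrom = integer(),
                                                   frac = numeric()),
                              parent2 = data.frame(chrom = integer(),
                                                   frac = numeric()))
  sim <- simulateParents(cfg)
  L <- cfg$pop_chrom_length
  a <- as.integer(floor(cfg$pop_introgression[1] * L)) + 1L
  b <- as.integer(floor(cfg$pop_introgression[2] * L))
  recipient <- as.character(sim$parents$parent1[[1]])
  donorSeg <- as.character(Biostrings::subseq(sim$parents$parent2[[1]], a, b))
  carrier <- paste0(substr(recipient, 1, a - 1L), donorSeg,
                    substr(recipient, b + 1L, L))
  assembly <- DNAStringSet(c(chrP_p1 = carrier, chrP_p2 = recipient))
  region <- GRanges("chrP_p1", IRanges(a, b))
  cn <- sample(0:2, cfg$population_n, replace = TRUE,
               prob = cfg$copy_ratio / sum(cfg$copy_ratio))
  readSeeds <- sample.int(.Machine$integer.max, cfg$population_n)
  reads <- vector("list", cfg$population_n)
  for (i in seq_len(cfg$population_n)) {
    copies <- switch(as.character(cn[i]),
                     "0" = c(recipient, recipient),
                     "1" = c(recipient, carrier),
                     "2" = c(carrier, carrier))
    genome <- DNAStringSet(setNames(copies, c("copyA", "copyB")))
    reads[[i]] <- simulateReads(genome, cfg$depth, cfg$read_length,
                                cfg$error_rate, seed = readSeeds[i],
                                window_size = cfg$window_size)$reads
  }
  list(assembly = assembly, region = region, true_copies = cn, reads = reads)
}

#' Naive perfect-tandem detector (fixture substitute for a full annotator)
#'
#' Reports maximal runs of exact head-to-tail unit repetition with at
#' least \code{min_copies} copies for each requested unit length;
#' brute-force and exact, with consensus = the repeating unit. The score
#' is 2 x array length (a match-score-2 convention).
#'
#' @param sequences DNAStringSet or named character vector.
#' @param unit_lengths integer vector of unit lengths to scan (small,
#'   <= 50).
#' @param min_copies minimum copy count (default 5).
#' @return RepeatCatalog.
#' @export
findPerfectTandems <- function(sequences, unit_lengths, min_copies = 5L) {
  stopifnot(all(unit_lengths >= 1), all(unit_lengths <= 50))
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  out <- list()
  for (nm in names(sequences)) {
    df <- cpp_find_tandems(toupper(sequences[[nm]]),
                           as.integer(unit_lengths), as.integer(min_copies))
    if (nrow(df) > 0) {
      df$seq_id <- nm
      out[[length(out) + 1L]] <- df
    }
  }
  sl <- setNames(nchar(sequences), names(sequences))
  if (length(out) == 0) {
    return(RepeatCatalog(character(), integer(), integer(), character(),
                         seqlengths = sl))
  }
  df <- do.call(rbind, out)
  RepeatCatalog(df$seq_id, df$start, df$end, df$unit,
                copy_number = df$copy_number,
                score = 2 * (df$end - df$start + 1), seqlengths = sl)
}
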