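test_that("zero divergence with no satellites gives identical parents", {
  cfg <- microPreset(1)
  cfg$parental_divergence <- 0
  cfg$array_positions <- list(parent1 = data.frame(chrom = integer(),
                                                   frac = numeric()),
                              parent2 = data.frame(chrom = integer(),
                                                   frac = numeric()))
  cfg$mini_length <- 0L
  par <- simulateParents(cfg)
  expect_identical(as.character(par$parents$parent1),
                   as.character(par$parents$parent2))
})

test_that("observed parent divergence matches the branch-mutation expectation", {
  cfg <- microPreset(2)
  cfg$chromosome_length <- 200000L
  cfg$n_chromosomes <- 1L
  cfg$array_positions <- list(parent1 = data.frame(chrom = integer(),
                                                   frac = numeric()),
                              parent2 = data.frame(chrom = integer(),
                                                   frac = numeric()))
  cfg$mini_length <- 0L
  par <- simulateParents(cfg)
  p1 <- charToRaw(as.character(par$parents$parent1[[1]]))
  p2 <- charToRaw(as.character(par$parents$parent2[[1]]))
  obs <- mean(p1 != p2)
  m <- cfg$parental_divergence
  # two independent branches; both-mutated sites coincide 1/3 of the time
  expected <- 2 * m * (1 - m) + m^2 * (2 / 3)
  expect_lt(abs(obs - expected) / expected, 0.1)
  # the mutation log covers every difference
  expect_lte(sum(p1 != p2),
             length(par$mutations$parent1[[1]]) +
             length(par$mutations$parent2[[1]]))
})

test_that("simulation is a pure function of the seed", {
  a <- simulateParents(microPreset(7))
  b <- simulateParents(microPreset(7))
  expect_identical(as.character(a$parents$parent1),
                   as.character(b$parents$parent1))
  expect_identical(as.data.frame(a$satellites), as.data.frame(b$satellites))
  c <- simulateParents(microPreset(8))
  expect_false(identical(as.character(a$parents$parent1),
                         as.character(c$parents$parent1)))

  g <- DNAStringSet(c(x = randomSeq(5000)))
  r1 <- simulateReads(g, 2, 100, seed = 3)
  r2 <- simulateReads(g, 2, 100, seed = 3)
  expect_identical(r1$reads, r2$reads)
})

test_that("hybrid assembly concatenates the planned parental segments exactly", {
  cfg <- microPreset(3)
  par <- simulateParents(cfg)
  # parent-pure plan: sequences equal the parents
  plan <- defaultAncestryPlan(within(cfg, introgression <- NULL))
  hyb <- simulateHybridAssembly(par, plan)
  expect_identical(as.character(hyb$assembly[["chr1_p1"]]),
                   as.character(par$parents$parent1[[1]]))
  expect_identical(as.character(hyb$assembly[["chr2_p2"]]),
                   as.character(par$parents$parent2[[2]]))
  expect_true(all(mcols(hyb$truth)$parent[grepl("_p1$", seqnames(hyb$truth))] == "a1"))

  # one planted introgression: exactly one foreign block on that copy
  hyb <- simulateHybridAssembly(par, defaultAncestryPlan(cfg))
  tr <- hyb$truth[seqnames(hyb$truth) == "chr2_p1"]
  expect_equal(sum(mcols(tr)$parent == "a2"), 1L)
  blk <- tr[mcols(tr)$parent == "a2"]
  L <- cfg$chromosome_length
  expect_equal(start(blk), as.integer(floor(0.4 * L)) + 1L)
  expect_equal(end(blk), as.integer(floor(0.6 * L)))
  # the introgressed block carries the donor sequence
  expect_identical(as.character(Biostrings::subseq(hyb$assembly[["chr2_p1"]],
                                                   start(blk), end(blk))),
                   as.character(Biostrings::subseq(par$parents$parent2[[2]],
                                                   start(blk), end(blk))))
  # junctions tile the copy without gaps
  expect_equal(start(tr), c(1L, start(blk), end(blk) + 1L))
  expect_equal(end(tr), c(start(blk) - 1L, end(blk), L))

  badPlan <- list(chr1_p1 = data.frame(from = 0, to = 0.5, parent = "parent1"))
  expect_error(simulateHybridAssembly(par, badPlan), "tile")
})

test_that("simulateReads draws the expected depth and logs exact windows", {
  g <- DNAStringSet(c(x = randomSeq(1000000)))
  sim <- simulateReads(g, 2, 100, seed = 5, window_size = 100000L)
  expect_equal(length(sim$reads), 20000L)
  expect_true(all(nchar(sim$reads) == 100L))
  expect_equal(sum(sim$windows$count), 20000L)
  # reads really come from their logged positions (error-free)
  idx <- sample(length(sim$reads), 50)
  s <- as.character(g[[1]])
  expect_identical(sim$reads[idx],
                   substring(s, sim$sources$start[idx],
                             sim$sources$start[idx] + 99L))
  # substitution errors appear at roughly the requested rate
  simE <- simulateReads(g, 1, 100, error_rate = 0.01, seed = 6)
  ref <- substring(s, simE$sources$start, simE$sources$start + 99L)
  obs <- mean(charToRaw(paste(simE$reads, collapse = "")) !=
              charToRaw(paste(ref, collapse = "")))
  expect_lt(abs(obs - 0.01) / 0.01, 0.2)
})

test_that("findPerfectTandems reports maximal exact runs", {
  ct <- findPerfectTandems(c(s = "TGCTGCTGCTGC"), 3L, min_copies = 3L)
  gr <- annotations(ct)
  expect_equal(length(gr), 1L)
  expect_equal(c(start(gr), end(gr)), c(1L, 12L))
  expect_identical(mcols(gr)$consensus_unit, "TGC")
  expect_equal(mcols(gr)$copy_number, 4)
  expect_identical(mcols(gr)$canonical_unit, "AGC")

  # seeded random sequence: no period-10 run of 5 copies
  set.seed(10)
  ct <- findPerfectTandems(c(s = randomSeq(50000)), 10L, min_copies = 5L)
  expect_equal(length(ct), 0L)

  # planted arrays are recovered at exact coordinates
  cfg <- microPreset(9)
  par <- simulateParents(cfg)
  ct <- findPerfectTandems(par$parents$parent1, 9L, min_copies = 5L)
  gr <- annotations(ct)
  planted <- par$satellites[mcols(par$satellites)$parent == "parent1"]
  for (i in seq_along(planted)) {
    sq <- as.character(seqnames(planted))[i]
    hit <- gr[as.character(seqnames(gr)) == sq &
              start(gr) <= start(planted)[i] & end(gr) >= end(planted)[i]]
    expect_gte(length(hit), 1L)
  }
})

test_that("population copy numbers follow the configured ratio over seeds", {
  cn <- unlist(lapply(1:5, function(s) {
    simulatePopulation(microPreset(s))$true_copies
  }))
  frac <- table(factor(cn, levels = 0:2)) / length(cn)
  expect_lt(abs(frac[["0"]] - 0.25), 0.08)
  expect_lt(abs(frac[["1"]] - 0.50), 0.08)
})
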