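test_that("clusterUnits groups exact matches and near-identical units", {
  ct <- RepeatCatalog(c("s", "s", "s"), c(1L, 101L, 201L),
                      c(30L, 130L, 230L), c("AGC", "AGC", "AAT"))
  cs <- clusterUnits(ct, identity_threshold = 1)
  expect_equal(nrow(clusterTable(cs)), 2L)
  expect_equal(clusterMembership(cs)[1], clusterMembership(cs)[2])

  # one substitution in 10 -> identity 0.9, linked at threshold 0.9
  ct <- RepeatCatalog(c("s", "s"), c(1L, 101L), c(100L, 200L),
                      c("AAAAAAAAAT", "AAAAAAAAAC"))
  cs <- clusterUnits(ct, identity_threshold = 0.9)
  expect_equal(nrow(clusterTable(cs)), 1L)
  expect_setequal(memberUnits(cs)[[1]],
                  canonicalUnit(c("AAAAAAAAAT", "AAAAAAAAAC")))
  # but not at a stricter threshold
  cs <- clusterUnits(ct, identity_threshold = 0.95)
  expect_equal(nrow(clusterTable(cs)), 2L)

  # singleton
  ct <- RepeatCatalog("s", 1L, 30L, "ACG")
  cs <- clusterUnits(ct)
  expect_equal(nrow(clusterTable(cs)), 1L)
  expect_equal(clusterTable(cs)$n_annotations, 1L)

  # empty catalog
  empty <- makeCatalog(character(0), integer(0), integer(0))
  expect_equal(nrow(clusterTable(clusterUnits(empty))), 0L)
})

test_that("clusters are ordered by total member bp, descending", {
  ct <- RepeatCatalog(c("s", "s", "s"), c(1L, 101L, 5001L),
                      c(50L, 150L, 9000L), c("ACG", "ACG", "AATCG"))
  cs <- clusterUnits(ct)
  tb <- clusterTable(cs)
  expect_equal(tb$total_bp, sort(tb$total_bp, decreasing = TRUE))
  expect_equal(tb$total_bp[1], 4000)
  # cluster 1 is the large AATCG family
  expect_identical(memberUnits(cs)[[1]], canonicalUnit("AATCG"))
})

test_that("clusterProfiles bins member bp and honors top_n", {
  sl <- c(s = 1000000L)
  # 30 kb array entirely inside bin 1
  ct <- RepeatCatalog("s", 1001L, 31000L, "ACG")
  cs <- clusterProfiles(clusterUnits(ct), sl, bin_size = 500000L)
  pr <- profileTable(cs)
  expect_equal(pr$bp[pr$bin == 1], 30000L)

  # array straddling the bin edge splits 40 kb / 20 kb
  ct <- RepeatCatalog("s", 460001L, 520000L, "ACG")
  cs <- clusterProfiles(clusterUnits(ct), sl, bin_size = 500000L)
  pr <- profileTable(cs)
  expect_equal(pr$bp[order(pr$bin)], c(40000L, 20000L))

  # top_n = 1 profiles only the largest cluster
  ct <- RepeatCatalog(c("s", "s"), c(1L, 200001L), c(50000L, 210000L),
                      c("ACG", "AATCG"))
  cs <- clusterProfiles(clusterUnits(ct), sl, bin_size = 500000L, top_n = 1L)
  expect_equal(unique(profileTable(cs)$cluster_id), 1L)

  expect_error(clusterProfiles(clusterUnits(ct), c(other = 100L)), "unknown")
})

test_that("phaseSpecificity scores and flags parent-specific families", {
  phases <- c(c1 = "phase1", c2 = "phase2")
  # all member bp on phase1 -> specificity 1, flagged a1
  ct <- RepeatCatalog(c("c1", "c1"), c(1L, 100001L), c(30000L, 130000L), "ACG")
  cs <- phaseSpecificity(clusterUnits(ct), phases)
  expect_equal(clusterTable(cs)$specificity, 1.0)
  expect_identical(clusterTable(cs)$flagged_parent, "a1")

  # 50/50 split is never flagged
  ct <- RepeatCatalog(c("c1", "c2"), c(1L, 1L), c(60000L, 60000L), "ACG")
  cs <- phaseSpecificity(clusterUnits(ct), phases)
  expect_equal(clusterTable(cs)$specificity, 0.5)
  expect_true(is.na(clusterTable(cs)$flagged_parent))

  # 95/5 with 100 kb total: flagged at defaults, not at s_min = 0.97
  ct <- RepeatCatalog(c("c1", "c2"), c(1L, 1L), c(95000L, 5000L), "ACG")
  cs <- phaseSpecificity(clusterUnits(ct), phases)
  expect_equal(clusterTable(cs)$specificity, 0.95)
  expect_identical(clusterTable(cs)$flagged_parent, "a1")
  cs <- phaseSpecificity(clusterUnits(ct), phases, s_min = 0.97)
  expect_true(is.na(clusterTable(cs)$flagged_parent))

  # below the bp floor nothing is flagged regardless of specificity
  ct <- RepeatCatalog("c1", 1L, 30000L, "ACG")
  cs <- phaseSpecificity(clusterUnits(ct), phases, b_min = 50000)
  expect_true(is.na(clusterTable(cs)$flagged_parent))

  expect_error(phaseSpecificity(clusterUnits(ct), c(other = "phase1")),
               "phase label")
})

test_that("provisionalPartition extends, merges, clips and drops double claims", {
  phases <- c(c1 = "phase1", c2 = "phase2")
  sl <- c(c1 = 1000000L, c2 = 1000000L)
  # two a1 arrays 10 kb apart merge at merge_distance 20 kb; the a2 array
  # sits on the other sequence
  ct <- RepeatCatalog(c("c1", "c1", "c2"), c(100001L, 140001L, 500001L),
                      c(130000L, 170000L, 560000L),
                      c("ACG", "ACG", "AATCG"))
  cs <- phaseSpecificity(clusterUnits(ct), phases, b_min = 50000)
  part <- provisionalPartition(cs, sl, merge_distance = 20000L)
  a1 <- part[mcols(part)$parent == "a1"]
  expect_equal(length(a1), 1L)
  expect_equal(c(start(a1), end(a1)), c(80001L, 190000L))

  # array at the sequence start clips at 1
  ct <- RepeatCatalog(c("c1", "c2"), c(1L, 500001L), c(60000L, 560000L),
                      c("ACG", "AATCG"))
  cs <- phaseSpecificity(clusterUnits(ct), phases)
  part <- provisionalPartition(cs, sl, merge_distance = 20000L)
  expect_equal(start(part[mcols(part)$parent == "a1"]), 1L)

  # intervals claimed by both parents are dropped from both: the a2
  # family has a member inside the a1 family's claim on c1
  ct <- RepeatCatalog(c("c1", "c2", "c1", "c2"),
                      c(100001L, 500001L, 120001L, 100001L),
                      c(190000L, 510000L, 130000L, 190000L),
                      c("ACG", "ACG", "AATCG", "AATCG"))
  cs <- phaseSpecificity(clusterUnits(ct), phases)
  tb <- clusterTable(cs)
  expect_setequal(tb$flagged_parent, c("a1", "a2"))
  part <- provisionalPartition(cs, c(c1 = 1000000L, c2 = 1000000L),
                               merge_distance = 20000L)
  expect_equal(length(GenomicRanges::findOverlaps(
    part[mcols(part)$parent == "a1"], part[mcols(part)$parent == "a2"])), 0L)
  onC1 <- part[seqnames(part) == "c1"]
  # the contested stretch 100001-150000 on c1 belongs to neither parent
  expect_false(any(start(onC1) <= 150000 & end(onC1) >= 100001 &
                   mcols(onC1)$parent == "a2"))
  gaps <- GenomicRanges::setdiff(GRanges("c1", IRanges(100001, 150000)), onC1)
  expect_equal(sum(width(gaps)), 50000L)

  # one parent without flagged clusters is an explicit error
  ct <- RepeatCatalog("c1", 100001L, 160000L, "ACG")
  cs <- phaseSpecificity(clusterUnits(ct), phases)
  expect_error(provisionalPartition(cs, sl, 20000L),
               "insufficient lineage signal")
})

test_that("provisionalPartition is invariant to annotation order", {
  phases <- c(c1 = "phase1", c2 = "phase2")
  sl <- c(c1 = 500000L, c2 = 500000L)
  st <- c(10001L, 200001L, 50001L, 300001L)
  en <- st + c(29999L, 29999L, 39999L, 59999L)
  sq <- c("c1", "c1", "c2", "c2")
  un <- c("ACG", "ACG", "AATCG", "AATCG")
  build <- function(ord) {
    ct <- RepeatCatalog(sq[ord], st[ord], en[ord], un[ord])
    cs <- phaseSpecificity(clusterUnits(ct), phases, b_min = 30000)
    part <- provisionalPartition(cs, sl, merge_distance = 5000L)
    df <- data.frame(seq = as.character(seqnames(part)),
                     start = start(part), end = end(part),
                     parent = mcols(part)$parent)
    df[order(df$seq, df$start), ]
  }
  ref <- build(1:4)
  for (p in list(4:1, c(2, 4, 1, 3))) {
    expect_equal(build(p), ref, ignore_attr = TRUE)
  }
})
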