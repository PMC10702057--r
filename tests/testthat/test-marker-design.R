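# VariantTable with bare candidate SNVs (single dummy sample)
candVt <- function(pos, chrom = "chr1", qual = 100) {
  n <- length(pos)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(qual) == 1L) qual <- rep(qual, n)
  VariantTable(chrom = chrom, pos = pos, ref = rep("A", n),
               alt = rep("T", n), qual = qual,
               gt = matrix("0/1", n, 1, dimnames = list(NULL, "s1")),
               adRef = matrix(10L, n, 1, dimnames = list(NULL, "s1")),
               adAlt = matrix(10L, n, 1, dimnames = list(NULL, "s1")))
}

# reference with prescribed flank content around a single position
flankRef <- function(leftFlank, rightFlank, pad = 10) {
  sq <- paste0(strrep("A", pad), leftFlank, "A", rightFlank,
               strrep("A", pad))
  Biostrings::DNAStringSet(c(chr1 = sq))
}

emptyLenient <- GenomicRanges::GRanges()

test_that("existing markers and nearby lenient variants disqualify candidates", {
  ref <- Biostrings::DNAStringSet(c(chr1 = strrep("AT", 600)))
  vt <- candVt(c(200, 400, 600, 800))
  lenient <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(200, 400, 430, 651, 800), width = 1))
  known <- data.frame(chrom = "chr1", pos = 800)
  cand <- markerCandidates(vt, lenient, ref, existingMarkers = known)
  # candidate at 400: lenient call 30 bp away
  expect_identical(cand$reason[cand$pos == 400], "flank_variant")
  # candidate at 600: nearest lenient call 51 bp away, outside the window
  expect_identical(cand$status[cand$pos == 600], "accepted")
  # candidate at 200: only itself in the lenient set
  expect_identical(cand$status[cand$pos == 200], "accepted")
  # known-marker position excluded before any other rule
  expect_identical(cand$reason[cand$pos == 800], "existing_marker")
  # exactly one first-failing reason per rejected candidate
  expect_true(all(is.na(cand$reason) == (cand$status == "accepted")))
})

test_that("the flank window boundary is inclusive at 50 bp", {
  ref <- Biostrings::DNAStringSet(c(chr1 = strrep("AT", 300)))
  vt <- candVt(300)
  at50 <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(250, 300), width = 1))
  expect_identical(
    markerCandidates(vt, at50, ref)$reason, "flank_variant")
  at51 <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(249, 300), width = 1))
  expect_identical(markerCandidates(vt, at51, ref)$status, "accepted")
})

test_that("GC screening is strict at 65% of the joint 100 bp flanks", {
  gc66 <- flankRef(strrep("G", 50), paste0(strrep("C", 16),
                                           strrep("T", 34)))
  vt <- candVt(61)  # 10 pad + 50 left flank + 1
  c66 <- markerCandidates(vt, emptyLenient, gc66)
  expect_identical(c66$reason, "gc_high")
  expect_equal(c66$gc_fraction, 0.66)

  gc65 <- flankRef(strrep("G", 50), paste0(strrep("C", 15),
                                           strrep("T", 35)))
  c65 <- markerCandidates(vt, emptyLenient, gc65)
  expect_identical(c65$reason, "gc_high")  # exactly 65%: still rejected
  expect_equal(c65$gc_fraction, 0.65)

  gc64 <- flankRef(strrep("G", 50), paste0(strrep("C", 14),
                                           strrep("T", 36)))
  c64 <- markerCandidates(vt, emptyLenient, gc64)
  expect_identical(c64$status, "accepted")

  allAT <- flankRef(strrep("A", 50), strrep("T", 50))
  cAT <- markerCandidates(vt, emptyLenient, allAT)
  expect_equal(cAT$gc_fraction, 0)
  expect_identical(cAT$status, "accepted")
  # the GC fraction equals a brute-force character count
  joint <- strsplit(paste0(strrep("G", 50), strrep("C", 14),
                           strrep("T", 36)), "")[[1]]
  expect_equal(c64$gc_fraction, mean(joint %in% c("G", "C")))
})

test_that("flanks near sequence edges or containing N are rejected", {
  ref <- Biostrings::DNAStringSet(c(chr1 = strrep("AT", 100)))
  near <- markerCandidates(candVt(30), emptyLenient, ref)
  expect_identical(near$reason, "flank_n")
  withN <- flankRef(paste0(strrep("A", 20), "N", strrep("A", 29)),
                    strrep("T", 50))
  cN <- markerCandidates(candVt(61), emptyLenient, withN)
  expect_identical(cN$reason, "flank_n")
})

test_that("per-contig quotas keep the best-quality candidates", {
  # 1200 clean candidates on one placed chromosome: top 1000 by quality
  n <- 1200
  pos <- 101L * seq_len(n) + 60L
  ref <- Biostrings::DNAStringSet(
    c(chr1 = strrep("AT", (max(pos) + 100) / 2)))
  set.seed(55)
  qual <- sample(seq(100, 2000, by = 1), n)
  vt <- candVt(pos, qual = qual)
  cand <- markerCandidates(vt, emptyLenient, ref)
  acc <- cand[cand$status == "accepted", ]
  expect_equal(nrow(acc), 1000L)
  expect_setequal(acc$qual, sort(qual, decreasing = TRUE)[1:1000])
  expect_equal(sum(cand$reason == "contig_quota", na.rm = TRUE), 200L)

  # quality ties at the cutoff: the lower position wins
  vt2 <- candVt(pos[1:6], qual = c(900, 900, 900, 900, 500, 500))
  ref2 <- Biostrings::DNAStringSet(
    c(scaffold21 = strrep("AT", (max(pos[1:6]) + 100) / 2)))
  names(ref2) <- "scaffold21"
  vt2 <- candVt(pos[1:6], chrom = "scaffold21",
                qual = c(900, 900, 900, 900, 500, 500))
  cand2 <- markerCandidates(vt2, emptyLenient, ref2,
                            maxPerUnplaced = 4)
  acc2 <- cand2[cand2$status == "accepted", ]
  # unplaced contig quota of four applies
  expect_equal(nrow(acc2), 4L)
  expect_identical(acc2$pos, sort(pos[1:4]))

  # five-way quality tie across the cutoff: lower positions win
  vt3 <- candVt(pos[1:6], chrom = "scaffold21",
                qual = c(900, 900, 900, 900, 900, 500))
  cand3 <- markerCandidates(vt3, emptyLenient, ref2,
                            maxPerUnplaced = 4)
  expect_identical(cand3$status,
                   c("accepted", "accepted", "accepted", "accepted",
                     "rejected", "rejected"))
})

test_that("the distributed panel maximizes minimum marker spacing", {
  ref <- Biostrings::DNAStringSet(c(chr1 = strrep("AT", 60000)))
  vt <- candVt(c(1000, 50000, 100000))
  cand <- markerCandidates(vt, emptyLenient, ref)
  # outermost candidates anchor the panel
  pick2 <- distributeSubset(cand, 2)
  expect_identical(pick2$pos, c(1000L, 100000L))

  # equidistant grid of 21: endpoints plus midpoint for k = 3
  grid <- candVt(seq(1000, 201000, by = 10000))
  refG <- Biostrings::DNAStringSet(c(chr1 = strrep("AT", 101000)))
  candG <- markerCandidates(grid, emptyLenient, refG)
  expect_equal(nrow(candG[candG$status == "accepted", ]), 21L)
  pick3 <- distributeSubset(candG, 3)
  expect_identical(pick3$pos, c(1000L, 101000L, 201000L))
  # brute force over all 3-subsets confirms optimal min spacing
  minGap <- function(p) min(diff(sort(p)))
  allBest <- max(apply(utils::combn(candG$pos, 3), 2, minGap))
  expect_equal(minGap(pick3$pos), allBest)

  # k = 1: candidate closest to the chromosome midpoint
  pick1 <- distributeSubset(candG, 1, chromLengths = c(chr1 = 202000))
  expect_identical(pick1$pos, 101000L)

  # asking for more than available returns all with a warning
  expect_warning(pickAll <- distributeSubset(cand, 10), "only")
  expect_equal(nrow(pickAll), 3L)
})

test_that("panel min spacing is never beaten by random subsets", {
  set.seed(77)
  minGap <- function(p) min(diff(sort(p)))
  for (case in 1:5) {
    pos <- sort(sample(seq(200, 1e6, by = 150), 40))
    cand <- data.frame(chrom = "chr1", pos = pos, status = "accepted")
    k <- sample(3:8, 1)
    panel <- distributeSubset(cand, k)
    g <- minGap(panel$pos)
    rand <- replicate(1000, minGap(sample(pos, k)))
    expect_gte(g, max(rand))
  }
})
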