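# independent brute-force oracles ------------------------------------------

# group unmasked variants of each chromosome into consecutive blocks of
# `size` and average, by explicit enumeration
bruteWindows <- function(chrom, pos, daf, size) {
  keep <- !is.na(daf)
  chrom <- chrom[keep]; pos <- pos[keep]; daf <- daf[keep]
  out <- list()
  for (cn in unique(chrom)) {
    d <- daf[chrom == cn]; p <- pos[chrom == cn]
    i <- 1L; idx <- 0L
    while (i <= length(d)) {
      j <- min(i + size - 1L, length(d))
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, index = idx, start_pos = p[i], end_pos = p[j],
        n = j - i + 1L, mean_daf = mean(d[i:j]),
        complete = (j - i + 1L) == size)
      i <- j + 1L; idx <- idx + 1L
    }
  }
  do.call(rbind, out)
}

# maximal qualifying runs by explicit scanning
bruteRuns <- function(hot, runMin) {
  runs <- list()
  i <- 1L
  while (i <= length(hot)) {
    if (hot[i]) {
      j <- i
      while (j < length(hot) && hot[j + 1L]) j <- j + 1L
      if (j - i + 1L >= runMin)
        runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

# ---------------------------------------------------------------------------

test_that("pool allele frequency divides tolerant depth by total, masked when shallow", {
  expect_equal(poolAlleleFrequency(0, 20, "alt"), 1.0)
  expect_equal(poolAlleleFrequency(10, 10, "alt"), 0.5)
  expect_equal(poolAlleleFrequency(10, 10, "ref"), 0.5)
  expect_equal(poolAlleleFrequency(15, 5, "ref"), 0.75)
  expect_true(is.na(poolAlleleFrequency(3, 2, "alt", minDepth = 10)))
  expect_equal(poolAlleleFrequency(3, 2, "alt", minDepth = 5), 0.4)
})

test_that("per-variant dAF is the signed pool difference with masking", {
  vt <- makeVt(list(
    # fixed opposite pools: ideal dAF of 1
    list(pos = 100, gt = c(parent_S = "0/0", parent_T = "1/1",
                           F1 = "0/1"),
         ad = list(pool_tol = c(0, 20), pool_sus = c(20, 0))),
    # equal frequencies: null site
    list(pos = 200, gt = c(parent_S = "0/0", parent_T = "1/1",
                           F1 = "0/1"),
         ad = list(pool_tol = c(10, 10), pool_sus = c(12, 12))),
    # afTol 0.2, afSus 0.9: signed dAF -0.7
    list(pos = 300, gt = c(parent_S = "0/0", parent_T = "1/1",
                           F1 = "0/1"),
         ad = list(pool_tol = c(16, 4), pool_sus = c(2, 18))),
    # susceptible pool too shallow: masked
    list(pos = 400, gt = c(parent_S = "0/0", parent_T = "1/1",
                           F1 = "0/1"),
         ad = list(pool_tol = c(10, 10), pool_sus = c(3, 2)))))
  fl <- highConfidenceFilter(vt)
  gr <- perVariantDaf(fl$variants, minDepth = 10)
  daf <- S4Vectors::mcols(gr)$daf
  expect_equal(daf[1], 1.0)
  expect_equal(daf[2], 0.0)
  expect_equal(daf[3], -0.7)
  expect_true(is.na(daf[4]))
  expect_true(all(abs(daf[!is.na(daf)]) <= 1))
  expect_error(perVariantDaf(vt), "orientation")
})

test_that("tumbling windows group unmasked variants in tens", {
  w1 <- windowScan(makeDafGr(rep(1, 10)))
  expect_equal(length(w1), 1L)
  expect_equal(S4Vectors::mcols(w1)$meanDaf, 1.0)
  expect_true(S4Vectors::mcols(w1)$complete)

  w2 <- windowScan(makeDafGr(seq(0, 1, length.out = 25)))
  expect_equal(S4Vectors::mcols(w2)$nVariants, c(10L, 10L, 5L))
  expect_identical(S4Vectors::mcols(w2)$complete, c(TRUE, TRUE, FALSE))
  expect_equal(S4Vectors::mcols(w2)$index, 0:2)

  w3 <- windowScan(makeDafGr(rep(c(1, 0), c(5, 5))))
  expect_equal(S4Vectors::mcols(w3)$meanDaf, 0.5)
})

test_that("window statistics match a brute-force oracle on random instances", {
  set.seed(101)
  for (case in 1:60) {
    nChrom <- sample(1:3, 1)
    chrom <- sort(rep(sprintf("chr%d", 1:nChrom),
                      sample(5:40, nChrom, replace = TRUE)))
    pos <- unlist(lapply(table(chrom), function(k) sort(sample(1e5, k))))
    daf <- round(runif(length(chrom), -1, 1), 3)
    daf[runif(length(daf)) < 0.2] <- NA  # masked records
    size <- sample(2:10, 1)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
    S4Vectors::mcols(gr)$daf <- daf
    w <- windowScan(gr, size)
    oracle <- bruteWindows(chrom, pos, daf, size)
    expect_equal(length(w), nrow(oracle))
    expect_equal(as.character(GenomicRanges::seqnames(w)), oracle$chrom)
    expect_equal(GenomicRanges::start(w), oracle$start_pos)
    expect_equal(GenomicRanges::end(w), oracle$end_pos)
    expect_equal(S4Vectors::mcols(w)$meanDaf, oracle$mean_daf,
                 tolerance = 1e-12)
    expect_equal(S4Vectors::mcols(w)$nVariants, oracle$n)
    # window mean never exceeds the largest member magnitude
    expect_true(all(abs(S4Vectors::mcols(w)$meanDaf) <=
                      max(abs(daf), na.rm = TRUE) + 1e-12))
  }
})

test_that("interval delimitation finds exactly the maximal qualifying runs", {
  # five hot windows flanked by cold ones: one 50-SNP interval
  daf <- rep(c(0.1, 0.6, 0.1), c(20, 50, 20))
  w <- windowScan(makeDafGr(daf))
  iv <- detectIntervals(w, threshold = 0.5, runMin = 5)
  expect_equal(length(iv), 1L)
  expect_equal(S4Vectors::mcols(iv)$nSnps, 50L)
  expect_equal(S4Vectors::mcols(iv)$nWindows, 5L)
  expect_equal(GenomicRanges::start(iv), 21 * 1000)
  expect_equal(GenomicRanges::end(iv), 70 * 1000)

  # four hot windows: below the run minimum, no interval
  daf4 <- rep(c(0.1, 0.6, 0.1), c(20, 40, 20))
  expect_equal(length(detectIntervals(windowScan(makeDafGr(daf4)))), 0L)

  # two runs separated by a single cold window: two intervals
  daf2 <- rep(c(0.6, 0.1, 0.6), c(50, 10, 50))
  iv2 <- detectIntervals(windowScan(makeDafGr(daf2)))
  expect_equal(length(iv2), 2L)

  # the boundary is strict: windows at exactly the threshold do not count
  dafEq <- rep(0.5, 60)
  expect_equal(length(detectIntervals(windowScan(makeDafGr(dafEq)))), 0L)

  # a trailing incomplete window never contributes to an interval
  daf5 <- rep(c(0.1, 0.9), c(10, 45))  # 4 complete hot + 5 leftover
  expect_equal(length(detectIntervals(windowScan(makeDafGr(daf5)))), 0L)
})

test_that("run detection matches a brute-force enumeration on random series", {
  set.seed(202)
  for (case in 1:60) {
    nw <- sample(5:40, 1)
    means <- round(runif(nw, 0, 1), 3)
    runMin <- sample(2:5, 1)
    thr <- runif(1, 0.2, 0.8)
    daf <- rep(means, each = 10)
    w <- windowScan(makeDafGr(daf))
    iv <- detectIntervals(w, threshold = thr, runMin = runMin)
    oracle <- bruteRuns(means > thr, runMin)
    expect_equal(length(iv), length(oracle))
    if (length(oracle)) {
      expect_equal(S4Vectors::mcols(iv)$firstWindow,
                   vapply(oracle, `[`, 0, 1) - 1L)
      expect_equal(S4Vectors::mcols(iv)$lastWindow,
                   vapply(oracle, `[`, 0, 2) - 1L)
    }
  }
})

test_that("raising threshold or run length never enlarges any interval", {
  set.seed(303)
  for (case in 1:20) {
    means <- round(runif(30, 0, 1), 3)
    w <- windowScan(makeDafGr(rep(means, each = 10)))
    ivLo <- detectIntervals(w, threshold = 0.4, runMin = 3)
    ivHi <- detectIntervals(w, threshold = 0.6, runMin = 3)
    ivLong <- detectIntervals(w, threshold = 0.4, runMin = 5)
    # a stricter run minimum only drops intervals, never creates them
    expect_lte(length(ivLong), length(ivLo))
    expect_true(all(GenomicRanges::countOverlaps(ivLong, ivLo,
                                                 type = "equal") == 1))
    # a stricter threshold never enlarges coverage, and every surviving
    # interval is nested in an interval found at the looser threshold
    # (note the count itself can grow when a long run splits in two)
    expect_lte(sum(GenomicRanges::width(ivHi)),
               sum(GenomicRanges::width(ivLo)))
    if (length(ivHi))
      expect_true(all(GenomicRanges::countOverlaps(ivHi, ivLo,
                                                   type = "within") >= 1))
  }
})

test_that("masked variants neither occupy slots nor shift boundaries", {
  daf <- rep(c(0.1, 0.9, 0.1), c(20, 50, 20))
  pos <- 1000L * seq_along(daf)
  plain <- windowScan(makeDafGr(daf, pos = pos))
  # interleave masked records between every pair
  dafM <- as.vector(rbind(daf, NA))[-(2 * length(daf))]
  posM <- sort(c(pos, pos[-length(pos)] + 500L))
  masked <- windowScan(makeDafGr(dafM, pos = posM))
  expect_equal(S4Vectors::mcols(plain)$meanDaf,
               S4Vectors::mcols(masked)$meanDaf)
  expect_equal(GenomicRanges::start(plain), GenomicRanges::start(masked))
  expect_identical(detectIntervals(plain), detectIntervals(masked))
})

test_that("the scan report summarizes windows, intervals and the track", {
  daf <- rep(c(0.1, 0.2, 0.3), each = 10)
  w <- windowScan(makeDafGr(daf))
  iv <- detectIntervals(w)
  rep_ <- scanReport(w, iv)
  expect_equal(rep_$globalMean, 0.2, tolerance = 1e-12)
  expect_equal(nrow(rep_$track), 3L)
  expect_equal(rep_$perChrom$n_intervals, 0L)

  # monogenic noiseless simulation: exactly one interval, on the causal
  # chromosome, containing the causal variant
  gm <- makeGeneticMap(nChrom = 3, variantsPerChrom = 60,
                       chromLenBp = 1e6, chromLenCM = 30, seed = 9)
  v <- mapVariants(gm)
  cp <- v$pos[v$chrom == "chr2"][30]
  cfg <- SimConfig(nLines = 200, plantsPerLine = 10,
                   causalChrom = "chr2", causalPos = cp,
                   effect = 45, baselineMean = 90, dispersion = Inf,
                   blockSd = 0, coverage = 40, errorRate = 0,
                   decoyFrac = 0, seed = 12)
  res <- simulateAndScan(gm, cfg, kTol = 15, kSus = 15, cvMax = Inf)
  expect_equal(length(res$intervals), 1L)
  expect_equal(as.character(GenomicRanges::seqnames(res$intervals)),
               "chr2")
  expect_true(GenomicRanges::start(res$intervals) <= cp &&
                GenomicRanges::end(res$intervals) >= cp)
})
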