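# In-code fixtures shared across test files.

# single-chromosome map with given bp positions and cM coordinates
tinyMap <- function(pos, cM = seq_along(pos) - 1, chrom = "chr1",
                    lengthBp = max(pos) + 1000) {
  GeneticMap(data.frame(chrom = chrom, pos = pos, cM = cM),
             stats::setNames(lengthBp, chrom))
}

# GenotypeMatrix with prescribed F2 dosages (lines x variants matrix or a
# vector for a single variant)
makeGeno <- function(dosage, map = NULL) {
  if (is.null(dim(dosage))) dosage <- matrix(as.integer(dosage), ncol = 1)
  storage.mode(dosage) <- "integer"
  n <- nrow(dosage)
  if (is.null(map))
    map <- tinyMap(1000L * seq_len(ncol(dosage)),
                   cM = seq_len(ncol(dosage)))
  lineIds <- sprintf("L%03d", seq_len(n))
  vids <- variantIds(map)
  dimnames(dosage) <- list(lineIds, vids)
  nv <- ncol(dosage)
  dos <- rbind(parent_S = rep(0L, nv), parent_T = rep(2L, nv),
               F1 = rep(1L, nv), dosage)
  g1 <- pmin(dosage, 1L); g2 <- dosage - g1
  new("GenotypeMatrix", dosage = dos, gametes = list(g1, g2), map = map)
}

# VariantTable from a compact per-record list; each record is
# list(chrom, pos, ref, alt, qual, gt = named chr, ad = named list of
# c(ref, alt))
makeVt <- function(records,
                   samples = c("parent_S", "parent_T", "F1",
                               "pool_sus", "pool_tol")) {
  n <- length(records)
  g <- function(r, f, d) if (!is.null(r[[f]])) r[[f]] else d
  gt <- matrix("0/1", n, length(samples),
               dimnames = list(NULL, samples))
  adR <- adA <- matrix(10L, n, length(samples),
                       dimnames = list(NULL, samples))
  for (i in seq_len(n)) {
    r <- records[[i]]
    for (s in names(g(r, "gt", list()))) gt[i, s] <- r$gt[[s]]
    for (s in names(g(r, "ad", list()))) {
      adR[i, s] <- r$ad[[s]][1]; adA[i, s] <- r$ad[[s]][2]
    }
  }
  VariantTable(
    chrom = vapply(records, g, "", f = "chrom", d = "chr1"),
    pos = vapply(records, function(r) r$pos, 0),
    ref = vapply(records, g, "", f = "ref", d = "A"),
    alt = vapply(records, g, "", f = "alt", d = "T"),
    qual = vapply(records, g, 0, f = "qual", d = 100),
    gt = gt, adRef = adR, adAlt = adA)
}

# GRanges of per-variant dAF values as produced by perVariantDaf
makeDafGr <- function(daf, chrom = "chr1", pos = 1000L * seq_along(daf)) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    afTol = ifelse(is.na(daf), NA_real_, pmin(1, pmax(0, daf))),
    afSus = ifelse(is.na(daf), NA_real_, 0),
    daf = daf,
    depthTol = 20L, depthSus = 20L)
  gr
}

# run the in-memory analysis chain on one simulated study; returns the
# detected intervals and the causal position
simulateAndScan <- function(map, config, kTol = 20L, kSus = 16L,
                            cvMax = 0.3) {
  geno <- simulateF2(map, config)
  ph <- simulatePhenotypes(geno, config)
  summ <- lineSummary(adjustedMeans(ph))
  pools <- selectExtremes(summ, kTol, kSus, cvMax)
  vt <- simulatePoolReads(geno, pools$tolerant, pools$susceptible, config)
  fl <- highConfidenceFilter(vt)
  dafs <- perVariantDaf(fl$variants)
  w <- windowScan(dafs)
  list(intervals = detectIntervals(w), windows = w, filter = fl,
       raw = vt, pools = pools)
}
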