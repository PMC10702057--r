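# Pooled allele frequencies, per-variant delta allele frequencies,
# tumbling 10-SNP windows and run-based candidate interval delimitation.

#' Pool allele frequency from allele depths
#'
#' Tolerant-allele read fraction of a pool at one or more variants; masked
#' (NA) where the total depth is below \code{minDepth}.
#'
#' @param refDepth,altDepth non-negative read counts.
#' @param tolAllele "ref" or "alt" per variant: which allele descends from
#'   the tolerant parent.
#' @param minDepth minimum total depth for an unmasked estimate
#'   (default 10).
#' @return Numeric vector in [0, 1], NA where masked.
#' @export
#' @examples
#' poolAlleleFrequency(c(0, 10, 3), c(20, 10, 2), c("alt", "alt", "alt"))
poolAlleleFrequency <- function(refDepth, altDepth, tolAllele,
                                minDepth = 10L) {
  stopifnot(all(refDepth >= 0), all(altDepth >= 0),
            all(tolAllele %in% c("ref", "alt")))
  tot <- refDepth + altDepth
  tolD <- ifelse(tolAllele == "alt", altDepth, refDepth)
  ifelse(tot >= minDepth, tolD / tot, NA_real_)
}

#' Per-variant delta allele frequency between phenotype-class pools
#'
#' For every record of a high-confidence-filtered table, computes the
#' tolerant-allele frequency in the tolerant and susceptible pools and
#' their signed difference dAF = AF_tol - AF_sus. At a monogenic causal
#' locus with fixed opposite pools the dAF is 1. Records where either pool
#' is below \code{minDepth} are masked (dAF = NA).
#'
#' @param x a \linkS4class{VariantTable} with \code{tolAllele} set (see
#'   \code{\link{highConfidenceFilter}}).
#' @param poolTol,poolSus pool sample names.
#' @param minDepth per-pool minimum depth (default 10).
#' @return A \code{GRanges} with metadata columns afTol, afSus, daf,
#'   depthTol, depthSus.
#' @export
perVariantDaf <- function(x, poolTol = "pool_tol", poolSus = "pool_sus",
                          minDepth = 10L) {
  stopifnot(is(x, "VariantTable"))
  tolA <- tolAllele(x)
  if (is.null(tolA) || anyNA(tolA))
    stop("tolerant-allele orientation missing; run highConfidenceFilter",
         call. = FALSE)
  adR <- alleleDepths(x, "ref"); adA <- alleleDepths(x, "alt")
  afT <- poolAlleleFrequency(adR[, poolTol], adA[, poolTol], tolA, minDepth)
  afS <- poolAlleleFrequency(adR[, poolSus], adA[, poolSus], tolA, minDepth)
  gr <- GenomicRanges::granges(SummarizedExperiment::rowRanges(x))
  mcols(gr) <- DataFrame(
    afTol = unname(afT), afSus = unname(afS),
    daf = unname(afT - afS),
    depthTol = unname(adR[, poolTol] + adA[, poolTol]),
    depthSus = unname(adR[, poolSus] + adA[, poolSus]))
  gr
}

#' Tumbling window scan of per-variant dAF
#'
#' Groups the unmasked variants of each chromosome into consecutive,
#' non-overlapping windows of \code{windowSize} variants (default 10) and
#' averages their dAF. Masked variants neither occupy window slots nor
#' shift boundaries. A trailing window with fewer than \code{windowSize}
#' variants is emitted with its true count but flagged incomplete;
#' interval detection ignores it.
#'
#' @param dafs GRanges from \code{\link{perVariantDaf}} (sorted by
#'   chrom, pos).
#' @param windowSize variants per window.
#' @return GRanges of windows with metadata columns \code{index} (0-based
#'   per chromosome), \code{nVariants}, \code{meanDaf}, \code{complete}.
#' @export
windowScan <- function(dafs, windowSize = 10L) {
  stopifnot(is(dafs, "GRanges"), windowSize >= 1L)
  dafs <- dafs[!is.na(mcols(dafs)$daf)]
  res <- list()
  for (cn in GenomeInfoDb::seqlevels(dafs)) {
    sub <- dafs[seqnames(dafs) == cn]
    if (length(sub) == 0L) next
    grpIdx <- (seq_along(sub) - 1L) %/% windowSize
    spl <- split(seq_along(sub), grpIdx)
    w <- GRanges(factor(cn, levels = GenomeInfoDb::seqlevels(dafs)),
                 IRanges(
      start = unname(vapply(spl, function(i) start(sub)[i[1L]], 0L)),
      end = unname(vapply(spl, function(i) start(sub)[i[length(i)]], 0L))))
    mcols(w) <- DataFrame(
      index = as.integer(names(spl)),
      nVariants = unname(lengths(spl)),
      meanDaf = unname(vapply(spl, function(i) mean(mcols(sub)$daf[i]), 0)),
      complete = unname(lengths(spl) == windowSize))
    res[[cn]] <- w
  }
  if (length(res) == 0L) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(index = integer(0), nVariants = integer(0),
                           meanDaf = numeric(0), complete = logical(0))
    return(gr)
  }
  out <- unname(do.call(c, unname(res)))
  GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(dafs)
  out
}

#' Delimit candidate trait-locus intervals from window runs
#'
#' Every maximal run of at least \code{runMin} consecutive complete
#' windows whose mean dAF is strictly greater than \code{threshold}
#' becomes one candidate interval, spanning from the first member variant
#' of the first window to the last member variant of the last. With the
#' defaults (threshold 0.5, runMin 5, 10-SNP windows) an interval is a
#' 50-SNP delimitation.
#'
#' @param windows GRanges from \code{\link{windowScan}}.
#' @param threshold mean-dAF threshold, exceeded strictly (default 0.5).
#' @param runMin minimum run length in windows (default 5).
#' @return GRanges of intervals with metadata columns \code{firstWindow},
#'   \code{lastWindow}, \code{nWindows}, \code{nSnps}, \code{maxMeanDaf}.
#' @export
detectIntervals <- function(windows, threshold = 0.5, runMin = 5L) {
  stopifnot(is(windows, "GRanges"))
  res <- list()
  for (cn in as.character(unique(seqnames(windows)))) {
    w <- windows[seqnames(windows) == cn]
    w <- w[mcols(w)$complete]
    if (length(w) == 0L) next
    w <- w[order(mcols(w)$index)]
    hot <- mcols(w)$meanDaf > threshold
    # runs must be consecutive in window index too (guards against
    # pre-subset input; windowScan output is always index-contiguous)
    idx <- mcols(w)$index
    blocks <- split(seq_along(w), cumsum(c(TRUE, diff(idx) != 1L)))
    for (b in blocks) {
      r <- rle(hot[b])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values & r$lengths >= runMin)) {
        ii <- b[starts[k]:ends[k]]
        gr <- GRanges(factor(cn,
                             levels = GenomeInfoDb::seqlevels(windows)),
                      IRanges(min(start(w)[ii]), max(end(w)[ii])))
        mcols(gr) <- DataFrame(
          firstWindow = idx[ii[1L]], lastWindow = idx[ii[length(ii)]],
          nWindows = length(ii),
          nSnps = sum(mcols(w)$nVariants[ii]),
          maxMeanDaf = max(mcols(w)$meanDaf[ii]))
        res[[length(res) + 1L]] <- gr
      }
    }
  }
  if (length(res) == 0L) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(firstWindow = integer(0),
                           lastWindow = integer(0),
                           nWindows = integer(0), nSnps = integer(0),
                           maxMeanDaf = numeric(0))
    return(gr)
  }
  out <- unname(do.call(c, res))
  GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(windows)
  sort(out)
}

#' Genome-wide scan summary
#'
#' Per-chromosome window statistics, the global mean and SD of complete
#' window mean dAFs, the interval list, and a plot-ready track of
#' (chrom, window midpoint, meanDaf).
#'
#' @param windows GRanges from \code{\link{windowScan}}.
#' @param intervals GRanges from \code{\link{detectIntervals}}.
#' @return List with \code{perChrom}, \code{globalMean}, \code{globalSd},
#'   \code{intervals}, \code{track}.
#' @export
scanReport <- function(windows, intervals) {
  comp <- windows[mcols(windows)$complete]
  chroms <- as.character(unique(seqnames(windows)))
  perChrom <- do.call(rbind, lapply(chroms, function(cn) {
    w <- comp[seqnames(comp) == cn]
    data.frame(chrom = cn, n_windows = length(w),
               mean_daf = if (length(w)) mean(mcols(w)$meanDaf) else NA,
               max_daf = if (length(w)) max(mcols(w)$meanDaf) else NA,
               n_intervals = sum(as.character(seqnames(intervals)) == cn))
  }))
  track <- data.frame(
    chrom = as.character(seqnames(windows)),
    midpoint = (start(windows) + end(windows)) / 2,
    mean_daf = mcols(windows)$meanDaf,
    complete = mcols(windows)$complete)
  list(perChrom = perChrom,
       globalMean = if (length(comp)) mean(mcols(comp)$meanDaf) else NA,
       globalSd = if (length(comp) > 1) stats::sd(mcols(comp)$meanDaf)
                  else NA,
       intervals = intervals, track = track)
}

#' Write window stats, intervals and scan track as TSV/BED
#'
#' Interval coordinates are 1-based inclusive in the TSV and converted to
#' 0-based half-open in the BED export.
#'
#' @param windows,intervals GRanges from the scan.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return Invisibly, the written paths.
#' @export
writeScanOutputs <- function(windows, intervals, dir, prefix = "scan") {
  wdf <- data.frame(chrom = as.character(seqnames(windows)),
                    index = mcols(windows)$index,
                    start_pos = start(windows), end_pos = end(windows),
                    n_variants = mcols(windows)$nVariants,
                    mean_daf = mcols(windows)$meanDaf,
                    complete = mcols(windows)$complete)
  idf <- data.frame(chrom = as.character(seqnames(intervals)),
                    start_pos = start(intervals),
                    end_pos = end(intervals),
                    first_window = mcols(intervals)$firstWindow,
                    last_window = mcols(intervals)$lastWindow,
                    n_snps = mcols(intervals)$nSnps,
                    max_mean_daf = mcols(intervals)$maxMeanDaf)
  paths <- file.path(dir, paste0(prefix, c("_windows.tsv",
                                           "_intervals.tsv",
                                           "_intervals.bed")))
  utils::write.table(wdf, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(idf, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- intervals
  if (length(bed)) {
    names(bed) <- sprintf("interval_%d", seq_along(bed))
    mcols(bed) <- NULL
  }
  rtracklayer::export(bed, paths[3], format = "BED")
  invisible(paths)
}
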