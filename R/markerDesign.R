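# KASP-style marker candidate selection: clean-variant pool, 50 bp
# flank-variant check against a lenient call set, GC content of the 100 bp
# flanking sequence, per-contig quotas, and a well-distributed subset.

#' Screen clean variants into KASP marker candidates
#'
#' Applies the candidate-selection rules to a high-confidence ("clean")
#' variant set, in fixed order, attributing each rejection to its first
#' failing rule:
#' \enumerate{
#'   \item \code{existing_marker}: position overlaps a supplied known
#'     marker.
#'   \item \code{flank_variant}: any lenient-call variant other than the
#'     candidate itself lies within \code{flankBp} (default 50) bp up- or
#'     downstream.
#'   \item \code{flank_n}: flanks not extractable (within \code{flankBp}
#'     of a sequence edge) or containing an N.
#'   \item \code{gc_high}: GC fraction of the concatenated 2 x
#'     \code{flankBp} bp flanks is not strictly below \code{maxGc}
#'     (default 0.65).
#'   \item \code{contig_quota}: beyond the per-sequence quota
#'     (\code{maxPerChrom} for placed chromosomes, default 1000;
#'     \code{maxPerUnplaced} for unplaced contigs, default 4), candidates
#'     ranked by descending call quality, ties by ascending position.
#' }
#'
#' @param clean a \linkS4class{VariantTable} of high-confidence variants.
#' @param lenient GRanges (or data.frame with chrom, pos) of the lenient,
#'   unfiltered variant calls used for the flank check.
#' @param reference \link[Biostrings]{DNAStringSet} reference sequences.
#' @param existingMarkers optional data.frame with columns chrom, pos of
#'   known markers to exclude.
#' @param flankBp flank length per side (default 50).
#' @param maxGc strict upper GC bound on the joint flanks (default 0.65).
#' @param placed character vector of placed-chromosome names; all other
#'   sequences are treated as unplaced contigs. Defaults to names
#'   starting "chr".
#' @param maxPerChrom,maxPerUnplaced per-sequence quotas.
#' @return data.frame, one row per clean variant: chrom, pos, ref, alt,
#'   qual, left_flank, right_flank, gc_fraction, status
#'   ("accepted"/"rejected"), reason (NA when accepted), kasp (flank
#'   submission string for accepted candidates).
#' @export
markerCandidates <- function(clean, lenient, reference,
                             existingMarkers = NULL, flankBp = 50L,
                             maxGc = 0.65, placed = NULL,
                             maxPerChrom = 1000L, maxPerUnplaced = 4L) {
  stopifnot(is(clean, "VariantTable"))
  gr <- SummarizedExperiment::rowRanges(clean)
  chrom <- as.character(seqnames(gr))
  pos <- start(gr)
  n <- length(gr)
  if (is.null(placed)) placed <- grep("^chr", names(reference), value = TRUE)
  if (is(lenient, "GRanges")) {
    lchrom <- as.character(seqnames(lenient)); lpos <- start(lenient)
  } else {
    lchrom <- as.character(lenient$chrom); lpos <- lenient$pos
  }
  reason <- rep(NA_character_, n)
  leftF <- rightF <- rep(NA_character_, n)
  gcFrac <- rep(NA_real_, n)

  if (!is.null(existingMarkers) && nrow(existingMarkers) > 0) {
    hit <- paste0(chrom, ":", pos) %in%
      paste0(existingMarkers$chrom, ":", existingMarkers$pos)
    reason[hit] <- "existing_marker"
  }

  for (i in which(is.na(reason))) {
    near <- lchrom == chrom[i] & abs(lpos - pos[i]) <= flankBp &
      !(lpos == pos[i])
    if (any(near)) reason[i] <- "flank_variant"
  }

  for (i in which(is.na(reason))) {
    if (!chrom[i] %in% names(reference)) { reason[i] <- "flank_n"; next }
    sq <- reference[[chrom[i]]]
    if (pos[i] - flankBp < 1L ||
        pos[i] + flankBp > length(sq)) {
      reason[i] <- "flank_n"; next
    }
    lf <- as.character(Biostrings::subseq(sq, pos[i] - flankBp,
                                          pos[i] - 1L))
    rf <- as.character(Biostrings::subseq(sq, pos[i] + 1L,
                                          pos[i] + flankBp))
    leftF[i] <- lf; rightF[i] <- rf
    joint <- Biostrings::DNAString(paste0(lf, rf))
    if (Biostrings::letterFrequency(joint, "N") > 0) {
      reason[i] <- "flank_n"; next
    }
    gcFrac[i] <- as.numeric(
      Biostrings::letterFrequency(joint, "GC", as.prob = TRUE))
    if (gcFrac[i] >= maxGc) reason[i] <- "gc_high"
  }

  qual <- variantQual(clean)
  for (cn in unique(chrom)) {
    quota <- if (cn %in% placed) maxPerChrom else maxPerUnplaced
    cand <- which(chrom == cn & is.na(reason))
    if (length(cand) > quota) {
      keep <- cand[order(-qual[cand], pos[cand])][seq_len(quota)]
      reason[setdiff(cand, keep)] <- "contig_quota"
    }
  }

  status <- ifelse(is.na(reason), "accepted", "rejected")
  kasp <- ifelse(status == "accepted",
                 paste0(leftF, "[", refAllele(clean), "/",
                        altAllele(clean), "]", rightF),
                 NA_character_)
  data.frame(chrom = chrom, pos = pos, ref = refAllele(clean),
             alt = altAllele(clean), qual = qual,
             left_flank = leftF, right_flank = rightF,
             gc_fraction = gcFrac, status = status, reason = reason,
             kasp = kasp, stringsAsFactors = FALSE)
}

# exact 1-D max-min dispersion: choose k of pos (sorted) including both
# endpoints so the minimum pairwise gap is maximal; binary search on the
# gap with a greedy feasibility sweep, interior points pruned
# deterministically from the right
.maxminSubset <- function(pos, k) {
  pos <- sort(pos)
  n <- length(pos)
  if (k >= n) return(pos)
  greedySel <- function(g) {
    sel <- pos[1L]
    last <- pos[1L]
    for (p in pos[-1L]) {
      if (p - last >= g && (pos[n] - p >= g || p == pos[n])) {
        sel <- c(sel, p); last <- p
      }
    }
    if (sel[length(sel)] != pos[n] && pos[n] - last >= g)
      sel <- c(sel, pos[n])
    sel
  }
  lo <- 1; hi <- pos[n] - pos[1L]
  while (lo < hi) {
    mid <- ceiling((lo + hi) / 2)
    if (length(greedySel(mid)) >= k) lo <- mid else hi <- mid - 1
  }
  sel <- greedySel(lo)
  # drop interior points (gaps only grow) until k remain
  while (length(sel) > k) sel <- sel[-(length(sel) - 1L)]
  sel
}

#' Pick a well-distributed marker subset per chromosome
#'
#' Selects up to \code{kPerChrom} accepted candidates per chromosome so
#' that the minimum pairwise bp spacing is maximal (exact 1-D max-min
#' dispersion; the two outermost candidates are always part of an optimal
#' panel and are retained). For \code{k = 1} the candidate closest to the
#' chromosome midpoint is chosen (ties to the lower position). If fewer
#' candidates than requested exist, all are returned with a warning.
#'
#' @param candidates data.frame from \code{\link{markerCandidates}}
#'   (accepted rows are used).
#' @param kPerChrom markers per chromosome.
#' @param chromLengths optional named lengths used for the k = 1 midpoint
#'   rule; defaults to the candidate span.
#' @return The selected candidate rows, ordered by (chrom, pos).
#' @export
distributeSubset <- function(candidates, kPerChrom,
                             chromLengths = NULL) {
  acc <- candidates[candidates$status == "accepted", , drop = FALSE]
  sel <- lapply(unique(acc$chrom), function(cn) {
    sub <- acc[acc$chrom == cn, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    if (nrow(sub) <= kPerChrom) {
      if (nrow(sub) < kPerChrom)
        warning("only ", nrow(sub), " candidates on ", cn,
                " for k = ", kPerChrom, call. = FALSE)
      return(sub)
    }
    if (kPerChrom == 1L) {
      mid <- if (!is.null(chromLengths) && cn %in% names(chromLengths)) {
        chromLengths[[cn]] / 2
      } else {
        (min(sub$pos) + max(sub$pos)) / 2
      }
      return(sub[which.min(abs(sub$pos - mid)), , drop = FALSE])
    }
    keep <- .maxminSubset(sub$pos, kPerChrom)
    sub[sub$pos %in% keep, , drop = FALSE]
  })
  out <- do.call(rbind, sel)
  rownames(out) <- NULL
  out
}

#' Write marker candidate and rejection tables as TSV
#'
#' @param candidates data.frame from \code{\link{markerCandidates}}.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @export
writeMarkerOutputs <- function(candidates, dir, prefix = "markers") {
  acc <- candidates[candidates$status == "accepted",
                    c("chrom", "pos", "ref", "alt", "qual",
                      "gc_fraction", "kasp")]
  rej <- candidates[candidates$status == "rejected",
                    c("chrom", "pos", "ref", "alt", "qual", "reason")]
  paths <- file.path(dir, paste0(prefix, c("_candidates.tsv",
                                           "_rejected.tsv")))
  utils::write.table(acc, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(rej, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
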