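#' Construct a VariantTable
#'
#' Assembles per-variant alleles and per-sample GT/AD matrices into the
#' package's central container, sorting records by (chrom, pos). The row
#' order applied during sorting is recorded in
#' \code{metadata(x)$sortOrder} so parallel annotations can be reordered to
#' match.
#'
#' @param chrom,pos,ref,alt,qual per-variant vectors (pos is 1-based).
#' @param gt character matrix (variants x samples) of "0/0", "0/1", "1/1",
#'   "./." calls.
#' @param adRef,adAlt integer matrices of reference/alternate allele depths.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return A \linkS4class{VariantTable}.
#' @export
VariantTable <- function(chrom, pos, ref, alt, qual, gt, adRef, adAlt,
                         seqlengths = NULL) {
  chrom <- as.character(chrom)
  lev <- if (!is.null(seqlengths)) names(seqlengths) else unique(chrom)
  ord <- order(match(chrom, lev), pos)
  gr <- GRanges(factor(chrom[ord], levels = lev),
                IRanges(start = as.integer(pos)[ord], width = 1L))
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  mcols(gr) <- DataFrame(ref = as.character(ref)[ord],
                         alt = as.character(alt)[ord],
                         qual = as.numeric(qual)[ord])
  names(gr) <- paste0(chrom[ord], ":", as.integer(pos)[ord])
  stripRows <- function(m) { rownames(m) <- NULL; m }
  asy <- SimpleList(gt = stripRows(gt[ord, , drop = FALSE]),
                    adRef = stripRows(adRef[ord, , drop = FALSE]),
                    adAlt = stripRows(adAlt[ord, , drop = FALSE]))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = asy, rowRanges = gr,
    colData = DataFrame(row.names = colnames(gt)))
  out <- new("VariantTable", se)
  metadata(out)$sortOrder <- ord
  out
}

#' @describeIn VariantTable-class genotype-call matrix ("0/0" etc.)
#' @param x a VariantTable
#' @export
genotypeCalls <- function(x) SummarizedExperiment::assay(x, "gt")

#' @describeIn VariantTable-class allele-depth matrix for one allele
#' @param allele "ref" or "alt"
#' @export
alleleDepths <- function(x, allele = c("ref", "alt")) {
  allele <- match.arg(allele)
  SummarizedExperiment::assay(x, paste0("ad",
    if (allele == "ref") "Ref" else "Alt"))
}

#' @describeIn VariantTable-class per-variant REF alleles
#' @export
refAllele <- function(x) mcols(SummarizedExperiment::rowRanges(x))$ref

#' @describeIn VariantTable-class per-variant ALT alleles
#' @export
altAllele <- function(x) mcols(SummarizedExperiment::rowRanges(x))$alt

#' @describeIn VariantTable-class per-variant call quality (site QUAL)
#' @export
variantQual <- function(x) mcols(SummarizedExperiment::rowRanges(x))$qual

#' @describeIn VariantTable-class tolerant-allele orientation ("ref"/"alt"),
#'   set by \code{\link{highConfidenceFilter}}
#' @export
tolAllele <- function(x) mcols(SummarizedExperiment::rowRanges(x))$tolAllele

#' Write a VariantTable as a VCF v4.2 file
#'
#' Emits a plain-text VCF with FORMAT GT:AD and site QUAL; contig header
#' lines are included when chromosome lengths are known. Output is
#' byte-deterministic for a given object.
#'
#' @param x a \linkS4class{VariantTable}.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeVariantVcf <- function(x, path) {
  gr <- SummarizedExperiment::rowRanges(x)
  sl <- GenomeInfoDb::seqlengths(gr)
  hdr <- c("##fileformat=VCFv4.2", "##source=beetMBS")
  if (length(sl) && !all(is.na(sl)))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(sl),
                          as.integer(sl)))
  hdr <- c(hdr,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths for the ref and alt alleles\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(x)), collapse = "\t"))
  gt <- genotypeCalls(x)
  adR <- alleleDepths(x, "ref")
  adA <- alleleDepths(x, "alt")
  fmt <- matrix(paste0(gt, ":", adR, ",", adA), nrow = nrow(x))
  body <- if (nrow(x)) {
    paste(as.character(seqnames(gr)), start(gr), ".",
          refAllele(x), altAllele(x), sprintf("%.1f", variantQual(x)),
          "PASS", ".", "GT:AD",
          apply(fmt, 1L, paste, collapse = "\t"), sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

setMethod("show", "VariantTable", function(object) {
  cat(sprintf("VariantTable: %d biallelic SNVs x %d samples\n",
              nrow(object), ncol(object)))
  if (ncol(object))
    cat("  samples:", paste(colnames(object), collapse = ", "), "\n")
  if (!is.null(tolAllele(object)))
    cat("  tolerant-allele orientation set\n")
})
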