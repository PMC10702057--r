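# Ingestion of multi-sample VCFs and the three-criteria high-confidence
# filter (parents homozygous, parents contrasting, F1 heterozygous).

.defaultSamples <- c("parent_S", "parent_T", "F1", "pool_sus", "pool_tol")

#' Read a multi-sample VCF into a VariantTable
#'
#' Parses a VCF v4.2 via \code{VariantAnnotation::readVcf}, keeps biallelic
#' single-nucleotide variants only (indels and multiallelic records are
#' counted and dropped; counts are in \code{metadata(x)$ingest}),
#' normalizes the sample order to \code{samples} and preserves QUAL and
#' AD. GT separators "|" are normalized to "/" and phased genotypes
#' reordered so "1/0" reads "0/1".
#'
#' @param path VCF file path.
#' @param samples required sample names, in the order the table should
#'   carry them. Missing samples are an error.
#' @return A \linkS4class{VariantTable}.
#' @export
readVariantVcf <- function(path,
                           samples = .defaultSamples) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  have <- colnames(vcf)
  missing <- setdiff(samples, have)
  if (length(missing))
    stop("required sample(s) missing from VCF: ",
         paste(missing, collapse = ", "), call. = FALSE)
  vcf <- vcf[, samples]
  nIn <- nrow(vcf)
  alt <- VariantAnnotation::alt(vcf)
  multi <- S4Vectors::elementNROWS(alt) != 1L
  altChar <- rep(NA_character_, nIn)
  altChar[!multi] <- as.character(unlist(alt[!multi]))
  refChar <- as.character(VariantAnnotation::ref(vcf))
  isSnv <- !multi & nchar(refChar) == 1L & nchar(altChar) == 1L &
    altChar %in% c("A", "C", "G", "T")
  nMulti <- sum(multi)
  nIndel <- sum(!multi & !isSnv)
  vcf <- vcf[isSnv, ]
  gt <- VariantAnnotation::geno(vcf)$GT
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[gt == "1/0"] <- "0/1"
  gt[gt %in% c(".", "./.", ".|.")] <- "./."
  ad <- VariantAnnotation::geno(vcf)$AD
  pick <- function(k) {
    m <- vapply(ad, function(x)
      if (length(x) >= k && !is.na(x[k])) x[k] else 0L, 0L)
    matrix(as.integer(m), nrow = nrow(vcf), dimnames = dimnames(gt))
  }
  gr <- SummarizedExperiment::rowRanges(vcf)
  qual <- VariantAnnotation::qual(vcf)
  qual[is.na(qual)] <- 0
  sl <- GenomeInfoDb::seqlengths(gr)
  out <- VariantTable(chrom = as.character(seqnames(gr)),
                      pos = start(gr),
                      ref = refChar[isSnv], alt = altChar[isSnv],
                      qual = qual, gt = gt,
                      adRef = pick(1L), adAlt = pick(2L),
                      seqlengths = if (all(is.na(sl))) NULL else sl)
  metadata(out)$ingest <- c(records = nIn, kept = sum(isSnv),
                            multiallelic = nMulti, indel = nIndel)
  out
}

#' Three-criteria high-confidence variant filter
#'
#' Retains a record iff, in order: no genotype among the two parents and
#' the F1 is missing; both parents are homozygous; the parental genotypes
#' contrast; the F1 is heterozygous; each parent's summed allele depth
#' reaches \code{minParentDepth}; and site QUAL reaches \code{minQual}.
#' Every rejected record is counted once under its first failing
#' criterion. Survivors gain a \code{tolAllele} row annotation ("ref" or
#' "alt"): the allele the tolerant parent is homozygous for.
#'
#' Applying the filter to its own output changes nothing.
#'
#' @param x a \linkS4class{VariantTable}.
#' @param parentSus,parentTol,f1 sample names of the susceptible parent,
#'   tolerant parent and F1.
#' @param minParentDepth minimum per-parent AD sum (default 5).
#' @param minQual minimum site QUAL (default 30).
#' @return List with \code{variants} (filtered \linkS4class{VariantTable}
#'   with \code{tolAllele} set) and \code{report}
#'   (\linkS4class{FilterReport}).
#' @export
highConfidenceFilter <- function(x, parentSus = "parent_S",
                                 parentTol = "parent_T", f1 = "F1",
                                 minParentDepth = 5L, minQual = 30) {
  stopifnot(is(x, "VariantTable"))
  need <- c(parentSus, parentTol, f1)
  if (!all(need %in% colnames(x)))
    stop("sample(s) not in table: ",
         paste(setdiff(need, colnames(x)), collapse = ", "), call. = FALSE)
  gt <- genotypeCalls(x)
  gS <- gt[, parentSus]; gT <- gt[, parentTol]; gF <- gt[, f1]
  hom <- function(g) g %in% c("0/0", "1/1")
  depth <- alleleDepths(x, "ref") + alleleDepths(x, "alt")
  fail <- character(nrow(x))
  miss <- gS == "./." | gT == "./." | gF == "./."
  fail[miss] <- "missing_genotype"
  f <- fail == "" & !(hom(gS) & hom(gT))
  fail[f] <- "parent_not_homozygous"
  f <- fail == "" & gS == gT
  fail[f] <- "parents_not_contrasting"
  f <- fail == "" & gF != "0/1"
  fail[f] <- "f1_not_heterozygous"
  f <- fail == "" & (depth[, parentSus] < minParentDepth |
                       depth[, parentTol] < minParentDepth)
  fail[f] <- "low_parent_depth"
  f <- fail == "" & variantQual(x) < minQual
  fail[f] <- "low_qual"
  keep <- fail == ""
  crits <- c("missing_genotype", "parent_not_homozygous",
             "parents_not_contrasting", "f1_not_heterozygous",
             "low_parent_depth", "low_qual")
  rej <- vapply(crits, function(cr) sum(fail == cr), 0L)
  out <- x[keep, ]
  rr <- SummarizedExperiment::rowRanges(out)
  mcols(rr)$tolAllele <- unname(ifelse(gT[keep] == "1/1", "alt", "ref"))
  SummarizedExperiment::rowRanges(out) <- rr
  list(variants = out,
       report = new("FilterReport", nIn = nrow(x), nOut = nrow(out),
                    rejections = rej))
}

#' Write a filter report as TSV
#'
#' @param report a \linkS4class{FilterReport}.
#' @param path output path.
#' @export
writeFilterReport <- function(report, path) {
  df <- data.frame(
    category = c("records_in", "records_out", names(report@rejections)),
    count = c(report@nIn, report@nOut, unname(report@rejections)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
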