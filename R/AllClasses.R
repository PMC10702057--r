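#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- SimpleList
#' @importFrom GenomicRanges GRanges seqnames start end granges sort
#' @importFrom IRanges IRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges rowRanges<-
NULL

#' Genetic map of biallelic variant positions
#'
#' Holds the marker scaffold of a biparental cross: chromosome names and
#' physical lengths, plus per-variant physical (bp, 1-based) and genetic (cM)
#' coordinates. Physical positions are strictly increasing and genetic
#' positions non-decreasing within a chromosome.
#'
#' @slot chromosomes data.frame with columns \code{name}, \code{lengthBp}.
#' @slot variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{cM}, ordered by (chrom, pos).
#' @export
setClass("GeneticMap",
  slots = c(chromosomes = "data.frame", variants = "data.frame"))

setValidity("GeneticMap", function(object) {
  ch <- object@chromosomes
  v <- object@variants
  if (!all(c("name", "lengthBp") %in% names(ch)))
    return("chromosomes needs columns 'name', 'lengthBp'")
  if (!all(c("chrom", "pos", "cM") %in% names(v)))
    return("variants needs columns 'chrom', 'pos', 'cM'")
  if (anyDuplicated(ch$name)) return("duplicated chromosome names")
  if (!all(v$chrom %in% ch$name))
    return("variant on a chromosome absent from the map")
  for (cn in unique(v$chrom)) {
    sub <- v[v$chrom == cn, ]
    if (is.unsorted(sub$pos, strictly = TRUE))
      return(sprintf("positions not strictly increasing on %s", cn))
    if (is.unsorted(sub$cM))
      return(sprintf("cM positions decreasing on %s", cn))
    if (any(sub$cM < 0)) return("negative cM position")
    if (any(sub$pos < 1) || any(sub$pos > ch$lengthBp[match(cn, ch$name)]))
      return(sprintf("position outside chromosome bounds on %s", cn))
  }
  TRUE
})

#' Simulation configuration for a synthetic F2 pool-seq study
#'
#' Parameters of the synthetic biparental F2 design: population size,
#' plants phenotyped per F2:3 line, the causal locus and its additive
#' effect, the cyst-count noise model, pooled sequencing depth and the
#' per-read miscall rate. Defaults reproduce the shape of the mapping
#' study the package emulates: 406 lines, 10 plants per line, an additive
#' effect of 11 cysts per tolerant-allele dose, and ~20x pooled coverage.
#'
#' @slot nLines integer, number of F2 lines.
#' @slot plantsPerLine integer, phenotyped F3 plants per line.
#' @slot causalChrom character, chromosome of the causal variant (NA for a
#'   null simulation without a trait locus).
#' @slot causalPos integer, bp position of the causal variant (NA for null).
#' @slot effect numeric >= 0, reduction of mean cyst count per
#'   tolerant-allele dose.
#' @slot baselineMean numeric > 0, mean cyst count of the susceptible
#'   homozygote.
#' @slot dispersion numeric > 0, negative-binomial size parameter of the
#'   cyst counts (\code{Inf} gives the Poisson limit).
#' @slot blockSd numeric >= 0, SD of additive block (box) effects on the
#'   square-root-transformed scale.
#' @slot coverage numeric > 0, mean pooled depth per variant per sample.
#' @slot errorRate numeric in [0, 1), per-read allele miscall probability.
#' @slot decoyFrac numeric >= 0, fraction (relative to the map size) of
#'   extra population-monomorphic decoy sites emitted into the VCF.
#' @slot seed integer root seed; per-stage streams are derived from it.
#' @export
setClass("SimConfig",
  slots = c(nLines = "integer", plantsPerLine = "integer",
            causalChrom = "character", causalPos = "integer",
            effect = "numeric", baselineMean = "numeric",
            dispersion = "numeric", blockSd = "numeric",
            coverage = "numeric", errorRate = "numeric",
            decoyFrac = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@nLines < 1L) return("nLines must be >= 1")
  if (object@plantsPerLine < 1L) return("plantsPerLine must be >= 1")
  if (object@effect < 0) return("effect must be >= 0")
  if (object@baselineMean <= 0) return("baselineMean must be > 0")
  if (object@dispersion <= 0) return("dispersion must be > 0")
  if (object@blockSd < 0) return("blockSd must be >= 0")
  if (object@coverage <= 0) return("coverage must be > 0")
  if (object@errorRate < 0 || object@errorRate >= 1)
    return("errorRate must be in [0, 1)")
  if (object@decoyFrac < 0) return("decoyFrac must be >= 0")
  if (is.na(object@causalChrom) != is.na(object@causalPos))
    return("causalChrom and causalPos must be both set or both NA")
  TRUE
})

#' F2 genotype dosage matrix
#'
#' Dosage of the tolerant-parent allele (0/1/2) for every individual at
#' every map variant. The first three rows are the fixed founders:
#' \code{parent_S} (all 0), \code{parent_T} (all 2) and \code{F1} (all 1);
#' the remaining rows are the F2 lines. The two gametes each F2 inherited
#' from the F1 are retained for haplotype-level checks.
#'
#' @slot dosage integer matrix, individuals x variants; dimnames are
#'   individual ids and "chrom:pos" variant ids.
#' @slot gametes list of two 0/1 integer matrices (lines x variants), the
#'   maternal and paternal F1 gametes of each F2 line.
#' @slot map the \linkS4class{GeneticMap} the columns refer to.
#' @export
setClass("GenotypeMatrix",
  slots = c(dosage = "matrix", gametes = "list", map = "GeneticMap"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  if (!all(rownames(d)[1:3] == c("parent_S", "parent_T", "F1")))
    return("first rows must be parent_S, parent_T, F1")
  if (!all(d[1L, ] == 0L)) return("parent_S row must be all 0")
  if (!all(d[2L, ] == 2L)) return("parent_T row must be all 2")
  if (!all(d[3L, ] == 1L)) return("F1 row must be all 1")
  if (!all(d %in% 0:2)) return("dosages must be in {0,1,2}")
  if (ncol(d) != nrow(object@map@variants))
    return("dosage columns do not match map variants")
  TRUE
})

#' Multi-sample biallelic SNV table
#'
#' The substrate of variant filtering and the delta allele-frequency scan:
#' biallelic single-nucleotide variants with per-sample genotype calls and
#' allele depths, held as a \code{RangedSummarizedExperiment} with assays
#' \code{gt} (genotype strings "0/0", "0/1", "1/1", "./."), \code{adRef}
#' and \code{adAlt} (integer depths). Row metadata columns carry \code{ref},
#' \code{alt} and \code{qual}; after high-confidence filtering a
#' \code{tolAllele} column ("ref" or "alt") records which allele descends
#' from the tolerant parent. Rows are sorted by (chrom, pos).
#'
#' @export
setClass("VariantTable", contains = "RangedSummarizedExperiment")

setValidity("VariantTable", function(object) {
  need <- c("gt", "adRef", "adAlt")
  if (!all(need %in% SummarizedExperiment::assayNames(object)))
    return("assays gt, adRef, adAlt required")
  mc <- mcols(SummarizedExperiment::rowRanges(object))
  if (!all(c("ref", "alt", "qual") %in% names(mc)))
    return("row metadata ref, alt, qual required")
  if (nrow(object) > 0) {
    if (!all(nchar(mc$ref) == 1L & nchar(mc$alt) == 1L))
      return("only single-base ref/alt alleles allowed")
    ad <- SummarizedExperiment::assay(object, "adRef")
    if (any(ad < 0) || any(SummarizedExperiment::assay(object, "adAlt") < 0))
      return("negative allele depths")
    gr <- SummarizedExperiment::rowRanges(object)
    o <- order(as.factor(seqnames(gr)), start(gr))
    if (!identical(o, seq_along(gr)))
      return("records must be sorted by (chrom, pos)")
  }
  TRUE
})

#' Accounting report of the high-confidence variant filter
#'
#' Counts of records entering and surviving the filter, plus per-criterion
#' rejection counts where each rejected record is attributed to its first
#' failing criterion.
#'
#' @slot nIn integer, records entering.
#' @slot nOut integer, records surviving.
#' @slot rejections named integer vector of rejection counts per criterion.
#' @export
setClass("FilterReport",
  slots = c(nIn = "integer", nOut = "integer", rejections = "integer"))

setValidity("FilterReport", function(object) {
  if (object@nIn != object@nOut + sum(object@rejections))
    return("nIn must equal nOut + sum(rejections)")
  TRUE
})

setMethod("show", "GeneticMap", function(object) {
  cat(sprintf("GeneticMap: %d chromosomes, %d variants\n",
              nrow(object@chromosomes), nrow(object@variants)))
  tab <- table(factor(object@variants$chrom,
                      levels = object@chromosomes$name))
  for (i in seq_len(nrow(object@chromosomes)))
    cat(sprintf("  %s  %s bp  %d variants\n",
                object@chromosomes$name[i],
                format(object@chromosomes$lengthBp[i], big.mark = ","),
                tab[i]))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  nLines=%d plantsPerLine=%d\n",
              object@nLines, object@plantsPerLine))
  if (is.na(object@causalChrom)) {
    cat("  causal locus: none (null simulation)\n")
  } else {
    cat(sprintf("  causal locus: %s:%d, effect %.1f cysts/dose\n",
                object@causalChrom, object@causalPos, object@effect))
  }
  cat(sprintf("  baselineMean=%.1f dispersion=%s blockSd=%.2f\n",
              object@baselineMean, format(object@dispersion), object@blockSd))
  cat(sprintf("  coverage=%.1fx errorRate=%g decoyFrac=%g seed=%d\n",
              object@coverage, object@errorRate, object@decoyFrac,
              object@seed))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d F2 lines + 3 founders, %d variants\n",
              nrow(object@dosage) - 3L, ncol(object@dosage)))
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport: %d in, %d out (%d rejected)\n",
              object@nIn, object@nOut, sum(object@rejections)))
  for (nm in names(object@rejections))
    cat(sprintf("  %-18s %d\n", nm, object@rejections[[nm]]))
})
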