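#' Construct a GeneticMap
#'
#' @param variants data.frame with columns \code{chrom}, \code{pos} (1-based
#'   bp, strictly increasing within a chromosome) and \code{cM}
#'   (non-decreasing within a chromosome).
#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @return A \linkS4class{GeneticMap}.
#' @export
#' @examples
#' GeneticMap(data.frame(chrom = "chr1", pos = c(100, 500), cM = c(0, 1)),
#'            c(chr1 = 1000))
GeneticMap <- function(variants, chromLengths) {
  stopifnot(is.data.frame(variants), !is.null(names(chromLengths)))
  variants <- variants[order(match(variants$chrom, names(chromLengths)),
                             variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$cM <- as.numeric(variants$cM)
  new("GeneticMap",
      chromosomes = data.frame(name = names(chromLengths),
                               lengthBp = as.numeric(chromLengths),
                               stringsAsFactors = FALSE),
      variants = variants[, c("chrom", "pos", "cM")])
}

#' Generate a study-shaped genetic map
#'
#' Builds a marker scaffold resembling a nine-pseudochromosome sugar beet
#' assembly: \code{nChrom} chromosomes of \code{chromLenBp} each, with
#' \code{variantsPerChrom} contrasting variant positions drawn uniformly and
#' genetic positions proportional to physical position (\code{chromLenCM}
#' total). Deterministic given \code{seed}.
#'
#' @param nChrom number of chromosomes (default 9).
#' @param variantsPerChrom variants per chromosome (default 223, giving
#'   ~2,000 genome-wide).
#' @param chromLenBp physical length per chromosome in bp (default 54 Mb,
#'   the pseudochromosome scale of recent sugar beet assemblies).
#' @param chromLenCM genetic length per chromosome in cM (default 65,
#'   matching a beet linkage map of ~190 markers at ~3 cM average spacing
#'   over nine groups).
#' @param seed integer seed.
#' @return A \linkS4class{GeneticMap}.
#' @export
makeGeneticMap <- function(nChrom = 9L, variantsPerChrom = 223L,
                           chromLenBp = 5.4e7, chromLenCM = 65,
                           seed = 1L) {
  set.seed(.stageSeed(seed, 0L))
  chroms <- sprintf("chr%d", seq_len(nChrom))
  vs <- lapply(chroms, function(cn) {
    pos <- sort(sample.int(chromLenBp, variantsPerChrom))
    data.frame(chrom = cn, pos = pos,
               cM = pos / chromLenBp * chromLenCM)
  })
  GeneticMap(do.call(rbind, vs),
             stats::setNames(rep(chromLenBp, nChrom), chroms))
}

#' @describeIn GeneticMap-class number of variants on the map
#' @param x,object a GeneticMap
#' @export
mapVariants <- function(x) x@variants

#' @rdname mapVariants
#' @export
mapChromosomes <- function(x) x@chromosomes

#' Variant identifiers ("chrom:pos") of a GeneticMap
#' @param x a GeneticMap
#' @export
variantIds <- function(x) paste0(x@variants$chrom, ":", x@variants$pos)
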