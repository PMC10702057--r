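# Seeded synthetic F2 pool-seq generator.
#
# One root seed; every stage (map, meiosis, phenotypes, pool reads,
# reference) draws from its own derived stream so that adding a stage never
# perturbs the draws of another.

.stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 2147400000) + stage * 101)
}

#' Construct a SimConfig
#'
#' Defaults mirror the mapping study the package emulates: 406 F2 lines,
#' 10 plants per F2:3 line, an additive tolerance effect of 11 cysts per
#' allele dose on a susceptible-homozygote baseline of 90 cysts, and 20x
#' pooled coverage. Noise parameters the study does not report (count
#' overdispersion, block-effect spread, sequencing miscall rate, decoy-site
#' fraction) carry package defaults discussed in the methods vignette.
#'
#' @param nLines number of F2 lines.
#' @param plantsPerLine phenotyped plants per line.
#' @param causalChrom,causalPos causal variant location (both NA for a null
#'   simulation). Must be a variant position of the map used downstream.
#' @param effect mean cyst-count reduction per tolerant-allele dose.
#' @param baselineMean mean cyst count of the susceptible homozygote.
#' @param dispersion negative-binomial size; \code{Inf} for the Poisson
#'   limit.
#' @param blockSd SD of block (box) effects on the transformed scale.
#' @param coverage mean pooled depth per variant per sample.
#' @param errorRate per-read allele miscall probability.
#' @param decoyFrac fraction of extra monomorphic decoy sites.
#' @param seed integer root seed.
#' @return A \linkS4class{SimConfig}.
#' @export
#' @examples
#' SimConfig(nLines = 50, seed = 7)
SimConfig <- function(nLines = 406L, plantsPerLine = 10L,
                      causalChrom = NA_character_, causalPos = NA_integer_,
                      effect = 11, baselineMean = 90, dispersion = 5,
                      blockSd = 0.5, coverage = 20, errorRate = 0.005,
                      decoyFrac = 0.1, seed = 1L) {
  new("SimConfig", nLines = as.integer(nLines),
      plantsPerLine = as.integer(plantsPerLine),
      causalChrom = as.character(causalChrom),
      causalPos = as.integer(causalPos),
      effect = as.numeric(effect), baselineMean = as.numeric(baselineMean),
      dispersion = as.numeric(dispersion), blockSd = as.numeric(blockSd),
      coverage = as.numeric(coverage), errorRate = as.numeric(errorRate),
      decoyFrac = as.numeric(decoyFrac), seed = as.integer(seed))
}

.checkCausal <- function(map, config) {
  if (is.na(config@causalChrom)) return(invisible(NULL))
  v <- map@variants
  if (!any(v$chrom == config@causalChrom & v$pos == config@causalPos))
    stop("causal position ", config@causalChrom, ":", config@causalPos,
         " is not a variant position of the map", call. = FALSE)
  invisible(NULL)
}

.gametes <- function(map, n) {
  v <- map@variants
  m <- matrix(0L, nrow = n, ncol = nrow(v))
  for (cn in unique(v$chrom)) {
    idx <- which(v$chrom == cn)
    # Haldane: recombination fraction between adjacent variants from their
    # cM distance, no interference
    r <- 0.5 * (1 - exp(-2 * diff(v$cM[idx]) / 100))
    cur <- as.integer(stats::runif(n) < 0.5)
    m[, idx[1L]] <- cur
    for (j in seq_along(r)) {
      sw <- stats::runif(n) < r[j]
      cur <- as.integer(ifelse(sw, 1L - cur, cur))
      m[, idx[j + 1L]] <- cur
    }
  }
  m
}

#' Simulate an F2 population from a heterozygous F1
#'
#' Each F2 line is the fusion of two independent gametes of the F1, with
#' recombination between adjacent map variants governed by the Haldane map
#' function (no interference). The dosage matrix counts copies of the
#' tolerant-parent allele and carries the two founder parents and the F1 as
#' fixed rows.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param config a \linkS4class{SimConfig}; uses \code{nLines} and
#'   \code{seed}, and validates the causal position against the map.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
#' @examples
#' gm <- makeGeneticMap(nChrom = 1, variantsPerChrom = 5, chromLenBp = 1e5)
#' simulateF2(gm, SimConfig(nLines = 10, seed = 3))
simulateF2 <- function(map, config) {
  stopifnot(is(map, "GeneticMap"), is(config, "SimConfig"))
  .checkCausal(map, config)
  set.seed(.stageSeed(config@seed, 1L))
  n <- config@nLines
  g1 <- .gametes(map, n)
  g2 <- .gametes(map, n)
  lineIds <- sprintf("L%0*d", max(3L, nchar(n)), seq_len(n))
  vids <- variantIds(map)
  dimnames(g1) <- dimnames(g2) <- list(lineIds, vids)
  nv <- length(vids)
  dos <- rbind(parent_S = rep(0L, nv), parent_T = rep(2L, nv),
               F1 = rep(1L, nv), g1 + g2)
  colnames(dos) <- vids
  new("GenotypeMatrix", dosage = dos, gametes = list(g1, g2), map = map)
}

#' @rdname GenotypeMatrix-class
#' @param x a GenotypeMatrix
#' @export
dosageMatrix <- function(x) x@dosage

#' @rdname GenotypeMatrix-class
#' @export
f2Lines <- function(x) rownames(x@dosage)[-(1:3)]

#' @rdname GenotypeMatrix-class
#' @export
gameteMatrices <- function(x) x@gametes

#' Exact pool allele frequency from dosages
#'
#' Tolerant-allele frequency of a pool computed from true allele dosages
#' (half the pool mean dosage), i.e. the allele frequency a pool-sequencing
#' experiment estimates in the limit of infinite depth and zero error.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param lineIds character vector of pool member line ids.
#' @return Named numeric vector (one frequency per map variant).
#' @export
exactPoolAf <- function(genotypes, lineIds) {
  stopifnot(all(lineIds %in% rownames(genotypes@dosage)))
  colMeans(genotypes@dosage[lineIds, , drop = FALSE]) / 2
}

#' Assign plants to randomized incomplete blocks
#'
#' Plants are permuted and packed into boxes of \code{blockSize}; the last
#' box may be smaller.
#'
#' @param nPlants number of plants.
#' @param blockSize plants per box (default 120, the greenhouse box size of
#'   the emulated design).
#' @return Character vector of block ids, one per plant.
#' @keywords internal
.assignBlocks <- function(nPlants, blockSize = 120L) {
  nb <- ceiling(nPlants / blockSize)
  lab <- sprintf("B%0*d", max(2L, nchar(nb)), seq_len(nb))
  sample(rep(lab, each = blockSize, length.out = nPlants))
}

#' Simulate cyst-count phenotypes for F2:3 lines
#'
#' Per plant, the cyst count is negative-binomial with line mean
#' \code{max(0, baselineMean - effect * dosage)} where dosage counts
#' tolerant-parent alleles at the causal variant; heterozygotes are exactly
#' intermediate (purely additive locus). Block (box) effects are additive
#' shifts on the square-root-transformed scale, back-transformed before
#' sampling; a mean pushed below zero by a block shift is clamped to zero
#' and reported via a message.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param config a \linkS4class{SimConfig}.
#' @param blocks optional character vector assigning each plant (ordered by
#'   line, then plant) to a block; defaults to randomized boxes of 120.
#' @return data.frame with columns plant_id, line_id, block_id, cysts.
#' @export
simulatePhenotypes <- function(genotypes, config, blocks = NULL) {
  stopifnot(is(genotypes, "GenotypeMatrix"), is(config, "SimConfig"))
  .checkCausal(genotypes@map, config)
  set.seed(.stageSeed(config@seed, 2L))
  lines <- f2Lines(genotypes)
  ppl <- config@plantsPerLine
  nPlants <- length(lines) * ppl
  lineOf <- rep(lines, each = ppl)
  plantId <- sprintf("%s_p%02d", lineOf, rep(seq_len(ppl), length(lines)))
  if (is.null(blocks)) blocks <- .assignBlocks(nPlants)
  stopifnot(length(blocks) == nPlants)
  if (is.na(config@causalChrom) || config@effect == 0) {
    dos <- rep(0L, length(lines))
  } else {
    vid <- paste0(config@causalChrom, ":", config@causalPos)
    dos <- genotypes@dosage[lines, vid]
  }
  muLine <- pmax(0, config@baselineMean - config@effect * dos)
  blockEff <- stats::rnorm(length(unique(blocks)), 0, config@blockSd)
  names(blockEff) <- sort(unique(blocks))
  snMu <- sqrt(muLine[match(lineOf, lines)] + 3 / 8) + blockEff[blocks]
  muPlant <- snMu^2 - 3 / 8
  nClamped <- sum(muPlant < 0 | snMu < 0)
  if (nClamped > 0)
    message(nClamped, " plant means clamped to 0 after block shift")
  muPlant <- ifelse(snMu < 0, 0, pmax(0, muPlant))
  cysts <- if (is.finite(config@dispersion)) {
    stats::rnbinom(nPlants, mu = muPlant, size = config@dispersion)
  } else {
    stats::rpois(nPlants, muPlant)
  }
  data.frame(plant_id = plantId, line_id = lineOf,
             block_id = unname(blocks), cysts = as.integer(cysts),
             stringsAsFactors = FALSE)
}

#' Simulate pooled allele depths and emit a multi-sample variant table
#'
#' Sequencing is simulated at the allele-depth level (no reads): per variant
#' and sample, depth ~ Poisson(coverage) and alt-allele reads ~
#' Binomial(depth, q') where q is half the sample's mean tolerant-allele
#' dosage mapped to the alt allele and q' = q(1-e) + (1-q)e perturbs it
#' toward the other allele with miscall rate e. The two parents and the F1
#' are emitted as fixed-genotype samples, the two phenotype-class pools as
#' allele-frequency samples. A configurable fraction of monomorphic decoy
#' sites (all samples homozygous reference) is interleaved; the truth of
#' every site (informative flag, tolerant-allele orientation, causal flag)
#' is attached as \code{metadata(x)$truth}.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param poolTol,poolSus disjoint, non-empty character vectors of F2 line
#'   ids forming the tolerant and susceptible pools.
#' @param config a \linkS4class{SimConfig}.
#' @return A \linkS4class{VariantTable} with samples parent_S, parent_T,
#'   F1, pool_sus, pool_tol.
#' @export
simulatePoolReads <- function(genotypes, poolTol, poolSus, config) {
  stopifnot(is(genotypes, "GenotypeMatrix"), is(config, "SimConfig"))
  if (length(poolTol) == 0L || length(poolSus) == 0L)
    stop("pools must be non-empty", call. = FALSE)
  if (length(intersect(poolTol, poolSus)) > 0L)
    stop("pools must be disjoint", call. = FALSE)
  lines <- f2Lines(genotypes)
  if (!all(c(poolTol, poolSus) %in% lines))
    stop("unknown line id in pool", call. = FALSE)
  set.seed(.stageSeed(config@seed, 3L))
  map <- genotypes@map
  v <- map@variants
  nv <- nrow(v)
  bases <- c("A", "C", "G", "T")
  refB <- sample(bases, nv, replace = TRUE)
  altB <- vapply(refB, function(b) sample(setdiff(bases, b), 1L), "")
  tolIsAlt <- stats::runif(nv) < 0.5

  # decoy sites: population-monomorphic, all samples homozygous reference
  nd <- round(config@decoyFrac * nv)
  if (nd > 0) {
    dChrom <- sample(map@chromosomes$name, nd, replace = TRUE)
    len <- map@chromosomes$lengthBp[match(dChrom, map@chromosomes$name)]
    dPos <- as.integer(ceiling(stats::runif(nd) * len))
    # avoid colliding with true variant positions
    clash <- paste0(dChrom, ":", dPos) %in% variantIds(map)
    dPos[clash] <- dPos[clash] + 1L
    dRef <- sample(bases, nd, replace = TRUE)
    dAlt <- vapply(dRef, function(b) sample(setdiff(bases, b), 1L), "")
  } else {
    dChrom <- character(0); dPos <- integer(0)
    dRef <- character(0); dAlt <- character(0)
  }

  chrom <- c(v$chrom, dChrom)
  pos <- c(v$pos, dPos)
  ref <- c(refB, dRef)
  alt <- c(altB, dAlt)
  informative <- c(rep(TRUE, nv), rep(FALSE, nd))
  tolAll <- c(ifelse(tolIsAlt, "alt", "ref"), rep(NA_character_, nd))
  causal <- rep(FALSE, nv + nd)
  if (!is.na(config@causalChrom))
    causal[seq_len(nv)] <- v$chrom == config@causalChrom &
      v$pos == config@causalPos

  # tolerant-allele frequency per emitted sample at the true sites
  qTol <- rbind(
    parent_S = rep(0, nv),
    parent_T = rep(1, nv),
    F1       = rep(0.5, nv),
    pool_sus = colMeans(genotypes@dosage[poolSus, , drop = FALSE]) / 2,
    pool_tol = colMeans(genotypes@dosage[poolTol, , drop = FALSE]) / 2)
  sampleNames <- rownames(qTol)
  e <- config@errorRate
  n <- nv + nd
  gt <- matrix("./.", n, 5L, dimnames = list(NULL, sampleNames))
  adR <- adA <- matrix(0L, n, 5L, dimnames = list(NULL, sampleNames))
  for (s in seq_along(sampleNames)) {
    qa <- c(ifelse(tolIsAlt, qTol[s, ], 1 - qTol[s, ]), rep(0, nd))
    qa <- qa * (1 - e) + (1 - qa) * e
    depth <- stats::rpois(n, config@coverage)
    altD <- stats::rbinom(n, depth, qa)
    adA[, s] <- altD
    adR[, s] <- depth - altD
    if (s <= 3L) {
      gtTrue <- c(parent_S = 0, parent_T = 2, F1 = 1)[s]
      altDose <- c(ifelse(tolIsAlt, gtTrue, 2 - gtTrue), rep(0, nd))
      gt[, s] <- c("0/0", "0/1", "1/1")[altDose + 1L]
    } else {
      frac <- ifelse(depth > 0, altD / depth, NA)
      gt[, s] <- ifelse(is.na(frac), "./.",
                 ifelse(frac < 0.1, "0/0",
                 ifelse(frac > 0.9, "1/1", "0/1")))
    }
    gt[depth == 0, s] <- "./."
  }
  qual <- round(stats::runif(n, 31, 2000), 1)

  truth <- data.frame(chrom = chrom, pos = pos, informative = informative,
                      tolAllele = tolAll, causal = causal,
                      stringsAsFactors = FALSE)
  vt <- VariantTable(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     qual = qual, gt = gt, adRef = adR, adAlt = adA,
                     seqlengths = stats::setNames(map@chromosomes$lengthBp,
                                                  map@chromosomes$name))
  ord <- metadata(vt)$sortOrder
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  metadata(vt)$truth <- truth
  vt
}

#' Simulate a reference sequence matching a genetic map
#'
#' Random DNA per chromosome, with the supplied reference allele planted at
#' every variant position so that flank extraction around variants is
#' consistent with the VCF. Intended for desk-scale maps (marker-design
#' tests and pipeline demos), not 500+ Mb genomes.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param variants optional \linkS4class{VariantTable} whose REF alleles are
#'   planted at their positions.
#' @param seed integer seed.
#' @return A \link[Biostrings]{DNAStringSet}, one sequence per chromosome.
#' @export
simulateReference <- function(map, variants = NULL, seed = 1L) {
  set.seed(.stageSeed(seed, 4L))
  bases <- c("A", "C", "G", "T")
  seqs <- lapply(seq_len(nrow(map@chromosomes)), function(i) {
    len <- map@chromosomes$lengthBp[i]
    paste(sample(bases, len, replace = TRUE), collapse = "")
  })
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  names(dna) <- map@chromosomes$name
  if (!is.null(variants)) {
    gr <- SummarizedExperiment::rowRanges(variants)
    for (cn in intersect(names(dna), as.character(unique(seqnames(gr))))) {
      sub <- gr[seqnames(gr) == cn]
      keep <- start(sub) <= length(dna[[cn]])
      sub <- sub[keep]
      if (length(sub))
        dna[[cn]] <- Biostrings::replaceLetterAt(
          dna[[cn]], start(sub), mcols(sub)$ref)
    }
  }
  dna
}
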