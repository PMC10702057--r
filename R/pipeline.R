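# One-command orchestration: simulate -> phenotype -> filter -> scan ->
# markers, with a plain-text key=value config and a JSON run manifest of
# md5-hashed outputs.

#' Default pipeline configuration
#'
#' All analysis defaults are the study-anchored values: 10-SNP windows,
#' dAF threshold 0.5, runs of 5 windows, pools of 20/16, per-pool minimum
#' depth 10, 50 bp flanks, GC bound 0.65, per-contig quotas 1000 (placed)
#' and 4 (unplaced). Simulation defaults come from
#' \code{\link{SimConfig}}; the demo genome is scaled to 9 x 1 Mb
#' chromosomes so the reference FASTA stays desk-sized.
#'
#' @param ... named overrides of any default.
#' @return Named list (class "beetmbs_config").
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    seed = 1, n_lines = 406, plants_per_line = 10,
    n_chrom = 9, variants_per_chrom = 223,
    chrom_len_bp = 1e6, chrom_len_cm = 65,
    causal_chrom = "chr5", causal_index = 23,
    effect = 11, baseline_mean = 90, dispersion = 5, block_sd = 0.5,
    coverage = 20, error_rate = 0.005, decoy_frac = 0.1,
    k_tol = 20, k_sus = 16, cv_max = 0.3,
    min_parent_depth = 5, min_qual = 30,
    window_size = 10, threshold = 0.5, run_min = 5, min_depth = 10,
    flank_bp = 50, max_gc = 0.65, max_per_chrom = 1000,
    max_per_unplaced = 4, k_markers = 21)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  class(cfg) <- "beetmbs_config"
  cfg
}

#' Read / write a pipeline configuration
#'
#' Plain-text \code{key = value} format; unknown keys are an error,
#' missing keys take defaults. Writing then reading then writing again is
#' byte-identical.
#'
#' @param path file path.
#' @param cfg a config list from \code{\link{defaultRunConfig}}.
#' @return \code{readRunConfig}: the config list.
#' @export
readRunConfig <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  kv <- regmatches(ln, regexec("^\\s*([A-Za-z_0-9]+)\\s*=\\s*(.*?)\\s*$", ln))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  parsed <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  do.call(defaultRunConfig, stats::setNames(parsed, keys))
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(cfg, path) {
  vals <- vapply(cfg, function(v)
    if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE)
    else as.character(v), "")
  writeLines(paste(names(cfg), "=", vals), path)
  invisible(path)
}

.cfgSimConfig <- function(cfg, map, null = FALSE) {
  if (null || is.na(cfg$causal_chrom) || cfg$causal_chrom == "none") {
    cc <- NA_character_; cp <- NA_integer_
  } else {
    v <- mapVariants(map)
    vp <- v$pos[v$chrom == cfg$causal_chrom]
    cc <- cfg$causal_chrom
    cp <- vp[min(length(vp), cfg$causal_index)]
  }
  SimConfig(nLines = cfg$n_lines, plantsPerLine = cfg$plants_per_line,
            causalChrom = cc, causalPos = cp, effect = cfg$effect,
            baselineMean = cfg$baseline_mean, dispersion = cfg$dispersion,
            blockSd = cfg$block_sd, coverage = cfg$coverage,
            errorRate = cfg$error_rate, decoyFrac = cfg$decoy_frac,
            seed = cfg$seed)
}

#' Run the full mapping-by-sequencing pipeline on a simulated study
#'
#' Executes simulate, phenotype, filter, scan and markers in order,
#' writing every stage output under \code{outdir} and a
#' \code{manifest.json} recording the configuration, an md5 hash of every
#' file, and the detected intervals. Identical config and seed give
#' identical hashes. A stage failure aborts with the stage named; outputs
#' of earlier stages are retained.
#'
#' @param cfg config from \code{\link{defaultRunConfig}} or
#'   \code{\link{readRunConfig}}.
#' @param outdir output directory (created if needed).
#' @param stages stages to run (subset of simulate, phenotype, filter,
#'   scan, markers, in pipeline order; later stages require earlier ones
#'   in the same call).
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(cfg = defaultRunConfig(), outdir,
                        stages = c("simulate", "phenotype", "filter",
                                   "scan", "markers")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- match.arg(stages, several.ok = TRUE)
  state <- new.env(parent = emptyenv())
  files <- character(0)
  stageLog <- character(0)
  runStage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    ok <- try(fun(), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("pipeline stage '", name, "' failed: ",
           attr(ok, "condition")$message, call. = FALSE)
    stageLog <<- c(stageLog, name)
  }

  runStage("simulate", function() {
    map <- makeGeneticMap(nChrom = cfg$n_chrom,
                          variantsPerChrom = cfg$variants_per_chrom,
                          chromLenBp = cfg$chrom_len_bp,
                          chromLenCM = cfg$chrom_len_cm, seed = cfg$seed)
    sc <- .cfgSimConfig(cfg, map)
    state$map <- map
    state$sc <- sc
    state$geno <- simulateF2(map, sc)
    state$pheno <- simulatePhenotypes(state$geno, sc)
    p <- file.path(outdir, "phenotypes.tsv")
    utils::write.table(state$pheno, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tr <- data.frame(causal_chrom = sc@causalChrom,
                     causal_pos = sc@causalPos, effect = sc@effect)
    pt <- file.path(outdir, "truth.tsv")
    utils::write.table(tr, pt, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, p, pt)
  })

  runStage("phenotype", function() {
    adj <- adjustedMeans(state$pheno)
    state$summary <- lineSummary(adj)
    state$pools <- selectExtremes(state$summary, cfg$k_tol, cfg$k_sus,
                                  cfg$cv_max)
    p1 <- file.path(outdir, "line_summary.tsv")
    utils::write.table(state$summary, p1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pools <- data.frame(
      line_id = c(state$pools$tolerant, state$pools$susceptible),
      pool = rep(c("tolerant", "susceptible"),
                 c(length(state$pools$tolerant),
                   length(state$pools$susceptible))))
    p2 <- file.path(outdir, "pools.tsv")
    utils::write.table(pools, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, p1, p2)
  })

  runStage("filter", function() {
    vt <- simulatePoolReads(state$geno, state$pools$tolerant,
                            state$pools$susceptible, state$sc)
    state$raw <- vt
    p1 <- file.path(outdir, "variants_raw.vcf")
    writeVariantVcf(vt, p1)
    fl <- highConfidenceFilter(vt, minParentDepth = cfg$min_parent_depth,
                               minQual = cfg$min_qual)
    state$clean <- fl$variants
    p2 <- file.path(outdir, "variants_clean.vcf")
    writeVariantVcf(fl$variants, p2)
    p3 <- file.path(outdir, "filter_report.tsv")
    writeFilterReport(fl$report, p3)
    files <<- c(files, p1, p2, p3)
  })

  runStage("scan", function() {
    dafs <- perVariantDaf(state$clean, minDepth = cfg$min_depth)
    state$windows <- windowScan(dafs, cfg$window_size)
    state$intervals <- detectIntervals(state$windows, cfg$threshold,
                                       cfg$run_min)
    rep <- scanReport(state$windows, state$intervals)
    p0 <- file.path(outdir, "scan_track.tsv")
    utils::write.table(rep$track, p0, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ps <- writeScanOutputs(state$windows, state$intervals, outdir)
    state$scanSummary <- rep
    files <<- c(files, p0, ps)
  })

  runStage("markers", function() {
    ref <- simulateReference(state$map, state$raw, seed = cfg$seed)
    pf <- file.path(outdir, "reference.fasta")
    Biostrings::writeXStringSet(ref, pf)
    lenient <- SummarizedExperiment::rowRanges(state$raw)
    cand <- markerCandidates(state$clean, lenient, ref,
                             flankBp = cfg$flank_bp, maxGc = cfg$max_gc,
                             maxPerChrom = cfg$max_per_chrom,
                             maxPerUnplaced = cfg$max_per_unplaced)
    pm <- writeMarkerOutputs(cand, outdir)
    panel <- distributeSubset(cand, cfg$k_markers,
      stats::setNames(mapChromosomes(state$map)$lengthBp,
                      mapChromosomes(state$map)$name))
    pp <- file.path(outdir, "marker_panel.tsv")
    utils::write.table(panel, pp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, pf, pm, pp)
  })

  cfgPath <- file.path(outdir, "config.txt")
  writeRunConfig(cfg, cfgPath)
  files <- c(files, cfgPath)
  manifest <- list(
    package = "beetMBS",
    version = as.character(utils::packageVersion("beetMBS")),
    stages = stageLog,
    config = unclass(cfg),
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(md5 = unname(tools::md5sum(f)))),
    intervals = if (!is.null(state$intervals)) {
      iv <- state$intervals
      lapply(seq_along(iv), function(i) list(
        chrom = as.character(seqnames(iv))[i],
        start_pos = start(iv)[i], end_pos = end(iv)[i],
        n_snps = mcols(iv)$nSnps[i]))
    } else NULL)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
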