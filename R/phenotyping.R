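# Cyst-count phenotyping: square-root transform, incomplete-block
# adjustment by alternating least squares, within-line CV, extreme-pool
# selection.

#' Square-root transform of cyst counts
#'
#' \code{SN = sqrt(n + 3/8)}, the variance-stabilizing transform applied to
#' counted cysts before block adjustment so residuals are approximately
#' normal.
#'
#' @param n non-negative cyst counts.
#' @return Transformed values.
#' @export
#' @examples
#' snTransform(c(0, 13, 280))
snTransform <- function(n) {
  if (any(is.na(n)) || any(n < 0))
    stop("cyst counts must be non-negative", call. = FALSE)
  sqrt(n + 3 / 8)
}

# connectivity of the line/block incidence: blocks sharing a line are
# connected; returns list of block groups (singleton list == connected)
.blockGroups <- function(line, block) {
  blocks <- sort(unique(block))
  parent <- stats::setNames(seq_along(blocks), blocks)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ln in unique(line)) {
    bs <- match(unique(block[line == ln]), blocks)
    for (b in bs[-1]) {
      r1 <- find(bs[1]); r2 <- find(b)
      if (r1 != r2) parent[r2] <- r1
    }
  }
  roots <- vapply(seq_along(blocks), find, 0L)
  split(blocks, roots)
}

#' Block-adjusted line means by alternating least squares
#'
#' Fits the additive two-way model \code{SN = line + block + residual} to
#' plant-level transformed counts by alternating least squares (blocks as
#' incomplete blocks, lines as fixed effects), iterating until the largest
#' effect change is below \code{tol} or \code{maxIter} iterations. Block
#' effects are centered at zero. Each plant's adjusted value is its SN
#' minus the estimated effect of its block; a line's adjusted mean is the
#' mean of its plants' adjusted values. On balanced designs this coincides
#' with the closed-form two-way least-squares solution.
#'
#' @param pheno data.frame with columns \code{plant_id}, \code{line_id},
#'   \code{block_id}, \code{cysts} (or a precomputed \code{SN} column).
#' @param tol convergence tolerance on effect changes (default 1e-10).
#' @param maxIter maximum iterations (default 200).
#' @return List with \code{lines} (data.frame line_id, adjusted_mean,
#'   n_plants, rank), \code{plants} (input plus SN, block_effect,
#'   adjusted), \code{blockEffects} (named numeric), \code{iterations}.
#' @export
adjustedMeans <- function(pheno, tol = 1e-10, maxIter = 200L) {
  stopifnot(all(c("line_id", "block_id") %in% names(pheno)))
  if (length(unique(pheno$line_id)) < 2L)
    stop("need at least two lines", call. = FALSE)
  grp <- .blockGroups(pheno$line_id, pheno$block_id)
  if (length(grp) > 1L)
    stop("disconnected block design; disconnected block groups: ",
         paste(vapply(grp, paste, "", collapse = ","), collapse = " | "),
         call. = FALSE)
  sn <- if ("SN" %in% names(pheno)) pheno$SN else snTransform(pheno$cysts)
  line <- factor(pheno$line_id)
  block <- factor(pheno$block_id)
  bEff <- stats::setNames(rep(0, nlevels(block)), levels(block))
  lEff <- stats::setNames(rep(0, nlevels(line)), levels(line))
  it <- 0L
  repeat {
    it <- it + 1L
    lNew <- rowsum(sn - bEff[block], line)[, 1] / tabulate(line)
    bNew <- rowsum(sn - lNew[line], block)[, 1] / tabulate(block)
    bNew <- bNew - mean(bNew)
    delta <- max(abs(lNew - lEff), abs(bNew - bEff))
    lEff <- lNew; bEff <- bNew
    if (delta < tol || it >= maxIter) break
  }
  adjusted <- sn - bEff[block]
  lineIds <- levels(line)
  adjMean <- rowsum(adjusted, line)[, 1] / tabulate(line)
  out <- data.frame(line_id = lineIds, adjusted_mean = unname(adjMean),
                    n_plants = tabulate(line), stringsAsFactors = FALSE)
  out$rank <- rank(out$adjusted_mean, ties.method = "first")
  plants <- pheno
  plants$SN <- sn
  plants$block_effect <- unname(bEff[block])
  plants$adjusted <- unname(adjusted)
  list(lines = out, plants = plants, blockEffects = bEff, iterations = it)
}

#' Within-line coefficient of variation
#'
#' Sample standard deviation over mean of one line's adjusted plant values;
#' a small CV indicates a phenotypically homogeneous (non-segregating)
#' F2:3 family. Undefined (NA) when the mean is not positive.
#'
#' @param values adjusted plant values of one line (length >= 2).
#' @return CV, or NA when undefined.
#' @export
#' @examples
#' lineCV(c(4, 6))
lineCV <- function(values) {
  if (length(values) < 2L)
    stop("need at least two plants to compute a CV", call. = FALSE)
  m <- mean(values)
  if (m <= 0) return(NA_real_)
  stats::sd(values) / m
}

#' Add per-line CVs to a line summary
#'
#' @param adj result of \code{\link{adjustedMeans}}.
#' @return Its \code{lines} data.frame with a \code{cv} column.
#' @export
lineSummary <- function(adj) {
  cvs <- vapply(split(adj$plants$adjusted, adj$plants$line_id),
                function(v) if (length(v) < 2L) NA_real_ else lineCV(v),
                0)
  out <- adj$lines
  out$cv <- unname(cvs[out$line_id])
  out
}

#' Select phenotypic extreme lines for the sequencing pools
#'
#' Among lines passing the CV homogeneity screen (\code{cv <= cvMax};
#' lines whose CV is undefined are kept, since a near-zero mean count is
#' itself an extreme-tolerant signal), returns the \code{kTolerant} lines
#' with the lowest and the \code{kSusceptible} lines with the highest
#' adjusted means. Ties at a cutoff are broken by lexicographic line id.
#'
#' @param summaries data.frame with columns \code{line_id},
#'   \code{adjusted_mean} and (unless \code{cvMax = Inf}) \code{cv}.
#' @param kTolerant,kSusceptible pool sizes (defaults 20 and 16, the
#'   emulated study's pools).
#' @param cvMax CV eligibility threshold (default 0.3).
#' @return List with character vectors \code{tolerant} and
#'   \code{susceptible}, and \code{eligible} (all screened line ids).
#' @export
selectExtremes <- function(summaries, kTolerant = 20L, kSusceptible = 16L,
                           cvMax = 0.3) {
  stopifnot(all(c("line_id", "adjusted_mean") %in% names(summaries)))
  s <- summaries
  if (is.finite(cvMax)) {
    if (!"cv" %in% names(s)) stop("summaries lack a cv column")
    s <- s[is.na(s$cv) | s$cv <= cvMax, , drop = FALSE]
  }
  if (kTolerant + kSusceptible > nrow(s))
    stop("only ", nrow(s), " eligible lines for pools of ",
         kTolerant, " + ", kSusceptible, call. = FALSE)
  loOrd <- order(s$adjusted_mean, s$line_id)
  hiOrd <- order(-s$adjusted_mean, s$line_id)
  tolerant <- utils::head(s$line_id[loOrd], kTolerant)
  susceptible <- utils::head(s$line_id[hiOrd], kSusceptible)
  if (length(intersect(tolerant, susceptible)) > 0L)
    stop("pools overlap; population too small for requested pool sizes",
         call. = FALSE)
  list(tolerant = tolerant, susceptible = susceptible,
       eligible = s$line_id)
}
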