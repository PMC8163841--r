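#' Build the joint filtered dyad-region set across samples
#'
#' Every called dyad is enlarged to an `enlarge`-bp window centered on it,
#' windows are pooled across samples and overlapping or bookended windows
#' are joined. Joined regions are then filtered: regions closer than
#' `borderExclusion` bp to a tile border (contig starts/ends plus any
#' internal boundaries of the genome) and regions overlapping the
#' blacklist are removed.
#'
#' @param callsBySample List of width-1 `GRanges` call sets (one per
#'   sample), or a single `GRanges`.
#' @param genome [NucGenome-class]; supplies contig lengths and tile
#'   boundaries.
#' @param enlarge Even total window size per dyad in bp (default 20, i.e.
#'   dyad +/- 10).
#' @param borderExclusion Minimum distance to a tile border in bp
#'   (default 250).
#' @param blacklist `GRanges` of excluded regions (may be empty).
#' @return Sorted, disjoint `GRanges` of dyad regions.
#' @export
buildJointDyadSet <- function(callsBySample, genome, enlarge = 20L,
                              borderExclusion = 250L,
                              blacklist = GenomicRanges::GRanges()) {
  enlarge <- as.integer(enlarge)
  if (enlarge %% 2L != 0L) stop("enlarge must be even")
  if (methods::is(callsBySample, "GRanges"))
    callsBySample <- list(callsBySample)
  if (!length(callsBySample)) stop("need calls from at least one sample")
  lens <- contigLengths(genome)
  dy <- do.call(c, unname(lapply(callsBySample, GenomicRanges::granges)))
  half <- enlarge %/% 2L
  ctg <- as.character(GenomeInfoDb::seqnames(dy))
  s <- pmax(BiocGenerics::start(dy) - half, 1L)
  e <- pmin(BiocGenerics::start(dy) + half - 1L, lens[ctg])
  win <- GenomicRanges::GRanges(factor(ctg, names(lens)),
                                IRanges::IRanges(s, e))
  reg <- GenomicRanges::reduce(BiocGenerics::sort(win))
  # tile-border filter: distance of a region to any border < exclusion
  tb <- tileBoundaries(genome)
  keep <- rep(TRUE, length(reg))
  rCtg <- as.character(GenomeInfoDb::seqnames(reg))
  r0s <- BiocGenerics::start(reg) - 1L
  r0e <- BiocGenerics::end(reg)
  for (nm in names(lens)) {
    borders <- c(0L, lens[[nm]], as.integer(tb[[nm]]))
    i <- which(rCtg == nm)
    if (!length(i)) next
    for (b in borders) {
      d <- pmax(r0s[i] - b, b - r0e[i], 0L)
      keep[i][d < borderExclusion] <- FALSE
    }
  }
  reg <- reg[keep]
  if (length(blacklist))
    reg <- reg[GenomicRanges::countOverlaps(reg, blacklist) == 0L]
  reg
}

#' Count fragment centers per dyad region and sample
#'
#' @param regions Disjoint `GRanges` of dyad regions.
#' @param fragmentsBySample Named list of fragment `GRanges`, one per
#'   sample.
#' @return Integer matrix regions x samples of fragment-center counts.
#' @export
countCenters <- function(regions, fragmentsBySample) {
  x <- vapply(fragmentsBySample, function(fr) {
    if (length(fr) == 0L) return(integer(length(regions)))
    ctr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(fr),
                                  IRanges::IRanges(fragmentCenterPos(fr),
                                                   fragmentCenterPos(fr)))
    GenomicRanges::countOverlaps(regions, ctr)
  }, integer(length(regions)))
  if (length(regions) == 1L) x <- matrix(x, nrow = 1L,
                                         dimnames = list(NULL, names(fragmentsBySample)))
  x
}

#' Normalize a region-by-sample count matrix
#'
#' Applies, per sample, `v = log2(((x / sum(x)) * 1000) + 0.001)` where
#' `sum(x)` is the sample's total count over all regions.
#'
#' @param x Integer matrix regions x samples of fragment-center counts.
#' @return Numeric matrix of normalized occupancies, same shape as `x`.
#' @export
normalizeOccupancy <- function(x) {
  x <- as.matrix(x)
  tot <- colSums(x)
  if (any(tot == 0)) {
    bad <- colnames(x)[tot == 0]
    if (is.null(bad)) bad <- which(tot == 0)
    stop("sample(s) with zero total counts: ", paste(bad, collapse = ", "))
  }
  log2(sweep(x, 2L, tot, "/") * 1000 + 0.001)
}

#' Assemble a region-by-sample occupancy container
#'
#' @param regions `GRanges` of dyad regions.
#' @param fragmentsBySample Named list of fragment `GRanges`.
#' @return A \link[SummarizedExperiment]{RangedSummarizedExperiment} with
#'   assays `counts` (raw center counts) and `normocc` (normalized
#'   occupancy).
#' @export
occupancyMatrix <- function(regions, fragmentsBySample) {
  x <- countCenters(regions, fragmentsBySample)
  colnames(x) <- names(fragmentsBySample)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = x, normocc = normalizeOccupancy(x)),
    rowRanges = regions)
}

#' PCA of normalized occupancies
#'
#' Observations are regions, variables are samples. Variables are centered
#' (and optionally unit-scaled); components are ordered by decreasing
#' explained variance and signs are fixed so the largest-magnitude loading
#' of each component is positive.
#'
#' @param v Numeric matrix regions x samples of normalized occupancies.
#' @param scaleVariables Scale variables to unit variance before PCA
#'   (default `FALSE`; occupancies are already on a common log2 scale).
#' @return List with `scores` (regions x components), `loadings`
#'   (samples x components) and `explainedVariance`.
#' @export
pcaRegions <- function(v, scaleVariables = FALSE) {
  v <- as.matrix(v)
  if (ncol(v) < 2L) stop("PCA requires at least 2 samples")
  if (nrow(v) < 2L) stop("PCA requires at least 2 regions")
  p <- stats::prcomp(v, center = TRUE, scale. = scaleVariables)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  list(scores = p$x, loadings = p$rotation,
       explainedVariance = p$sdev^2 / sum(p$sdev^2))
}

# k-means++ seeding: spread initial centers with probability ~ D^2
.kmeansppInit <- function(X, k) {
  n <- nrow(X)
  idx <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[idx, ], "-")^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) stop("fewer than k distinct points")
    nxt <- sample.int(n, 1L, prob = d2)
    idx <- c(idx, nxt)
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[nxt, ], "-")^2))
  }
  X[idx, , drop = FALSE]
}

#' K-means clustering of principal-component scores
#'
#' Runs `nRestarts` k-means++-seeded runs and keeps the best-inertia
#' solution. Labels are renumbered `1..k` by decreasing cluster size (ties
#' broken by the first member region). The result is deterministic given
#' `seed`.
#'
#' @param pcScores Numeric matrix regions x components.
#' @param k Number of clusters (default 8).
#' @param seed Integer RNG seed.
#' @param nRestarts Number of seeded restarts (default 25).
#' @param components Optional component subset to cluster on (default all,
#'   which is Euclidean-equivalent to clustering the occupancies
#'   themselves).
#' @return Integer vector of labels in `1..k` with attribute `"inertia"`
#'   (total within-cluster sum of squares).
#' @export
kmeansRegions <- function(pcScores, k = 8L, seed = 1L, nRestarts = 25L,
                          components = NULL) {
  X <- as.matrix(pcScores)
  if (!is.null(components)) X <- X[, components, drop = FALSE]
  if (k > nrow(X)) stop("k exceeds the number of regions")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(nRestarts)) {
    km <- tryCatch(
      stats::kmeans(X, centers = .kmeansppInit(X, k), iter.max = 100L),
      error = function(e) NULL)
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
      best <- km
  }
  if (is.null(best)) stop("k-means failed on all restarts")
  sizes <- tabulate(best$cluster, nbins = k)
  firstIdx <- vapply(seq_len(k),
                     function(j) min(which(best$cluster == j)), integer(1))
  newOrder <- order(-sizes, firstIdx)
  relabel <- integer(k)
  relabel[newOrder] <- seq_len(k)
  labels <- relabel[best$cluster]
  attr(labels, "inertia") <- best$tot.withinss
  labels
}

#' Per-cluster occupancy scores and display order
#'
#' @param labels Integer cluster labels in `1..k`.
#' @param v Numeric matrix regions x samples of normalized occupancies.
#' @return List with `clusterScores` (k x samples mean occupancy),
#'   `rowScaled` (per-cluster z-scores across samples, sd computed with
#'   n - 1; zero-variance rows set to 0) and `clusterOrder` (hierarchical
#'   ordering of the row-scaled rows, Euclidean distance, average
#'   linkage).
#' @export
clusterSummary <- function(labels, v) {
  v <- as.matrix(v)
  k <- max(labels)
  score <- t(vapply(seq_len(k),
                    function(j) colMeans(v[labels == j, , drop = FALSE]),
                    numeric(ncol(v))))
  rownames(score) <- paste0("cluster", seq_len(k))
  rs <- t(apply(score, 1L, function(row) {
    s <- stats::sd(row)
    if (is.na(s) || s == 0) rep(0, length(row)) else (row - mean(row)) / s
  }))
  dimnames(rs) <- dimnames(score)
  ord <- if (k >= 2L)
    stats::hclust(stats::dist(rs), method = "average")$order
  else seq_len(k)
  list(clusterScores = score, rowScaled = rs, clusterOrder = as.integer(ord))
}

#' Full PCA / K-means clustering of an occupancy matrix
#'
#' Convenience wrapper chaining [pcaRegions()], [kmeansRegions()] and
#' [clusterSummary()] into a [NucClusterResult-class].
#'
#' @param v Numeric matrix regions x samples of normalized occupancies.
#' @inheritParams kmeansRegions
#' @inheritParams pcaRegions
#' @return A [NucClusterResult-class].
#' @export
clusterRegions <- function(v, k = 8L, seed = 1L, nRestarts = 25L,
                           components = NULL, scaleVariables = FALSE) {
  p <- pcaRegions(v, scaleVariables = scaleVariables)
  labels <- kmeansRegions(p$scores, k = k, seed = seed,
                          nRestarts = nRestarts, components = components)
  s <- clusterSummary(labels, v)
  methods::new("NucClusterResult", pcScores = p$scores,
               explainedVariance = p$explainedVariance,
               labels = as.integer(labels), clusterScores = s$clusterScores,
               rowScaled = s$rowScaled, clusterOrder = s$clusterOrder)
}
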