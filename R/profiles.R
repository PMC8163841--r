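#' Oriented per-bp track windows around anchors
#'
#' Extracts `[pos - halfwidth, pos + halfwidth]` values around each
#' anchor, reversing the window for `-` strand anchors so that positive
#' offsets point downstream in anchor orientation. Positions outside the
#' contig are `NA`.
#'
#' @param track A [BpTrack-class].
#' @param anchors Width-1 stranded `GRanges`.
#' @param halfwidth Window half-width in bp.
#' @return Numeric matrix anchors x offsets (`-halfwidth .. +halfwidth`).
#' @export
extractTrackWindows <- function(track, anchors, halfwidth) {
  vals <- trackValues(track)
  ctg <- as.character(GenomeInfoDb::seqnames(anchors))
  pos <- BiocGenerics::start(anchors)
  st <- as.character(BiocGenerics::strand(anchors))
  W <- 2L * halfwidth + 1L
  out <- matrix(NA_real_, nrow = length(anchors), ncol = W)
  for (i in seq_along(pos)) {
    v <- vals[[ctg[i]]]
    if (is.null(v)) stop("anchor contig absent from track: ", ctg[i])
    idx <- (pos[i] - halfwidth):(pos[i] + halfwidth)
    ok <- idx >= 1L & idx <= length(v)
    row <- rep(NA_real_, W)
    row[ok] <- v[idx[ok]]
    if (st[i] == "-") row <- rev(row)
    out[i, ] <- row
  }
  colnames(out) <- seq(-halfwidth, halfwidth)
  rownames(out) <- if ("id" %in% names(S4Vectors::mcols(anchors)))
    anchors$id else NULL
  out
}

#' Anchor-aligned composite profile
#'
#' Averages oriented signal windows over anchors. With per-anchor
#' normalization each window is first divided by its own mean (windows
#' with zero or undefined mean are dropped with a message), mirroring
#' per-gene normalization in a window centered on the alignment point.
#'
#' @param track A [BpTrack-class].
#' @param anchors Width-1 stranded `GRanges`.
#' @param halfwidth Window half-width in bp (default 1000, i.e. a 2001-bp
#'   window).
#' @param perAnchorNorm Normalize each window by its own mean
#'   (default `TRUE`).
#' @return `data.frame` with `offset`, `mean` and `n` (anchors
#'   contributing a defined value at that offset).
#' @export
compositeProfile <- function(track, anchors, halfwidth = 1000L,
                             perAnchorNorm = TRUE) {
  stopifnot(halfwidth >= 1L)
  W <- extractTrackWindows(track, anchors, halfwidth)
  if (perAnchorNorm) {
    m <- rowMeans(W, na.rm = TRUE)
    bad <- !is.finite(m) | m == 0
    if (any(bad))
      message(sum(bad), " anchor window(s) dropped (zero/undefined mean)")
    W <- W[!bad, , drop = FALSE] / m[!bad]
  }
  if (nrow(W) == 0L) stop("no surviving anchor windows")
  n <- colSums(!is.na(W))
  data.frame(offset = seq(-halfwidth, halfwidth),
             mean = ifelse(n > 0, colMeans(W, na.rm = TRUE), NA_real_),
             n = n)
}

#' Sorted anchor-by-offset heatmap matrix
#'
#' @param track A [BpTrack-class].
#' @param anchors Width-1 stranded `GRanges` with an `id` metadata column.
#' @param halfwidth Window half-width in bp.
#' @param sortKeys Numeric sort key per anchor (e.g. NDR length or Reb1
#'   signal score). Anchors with `NA` keys are dropped with a message.
#' @return Numeric matrix with rows ordered by decreasing key (ties by
#'   anchor id) and an attribute `"sortKeys"` with the retained keys.
#' @export
heatmapMatrix <- function(track, anchors, halfwidth, sortKeys) {
  stopifnot(length(sortKeys) == length(anchors))
  keep <- !is.na(sortKeys)
  if (any(!keep)) message(sum(!keep), " anchor(s) dropped: missing sort key")
  anchors <- anchors[keep]
  sortKeys <- sortKeys[keep]
  id <- if ("id" %in% names(S4Vectors::mcols(anchors))) anchors$id else
    as.character(seq_along(anchors))
  ord <- order(-sortKeys, id)
  M <- extractTrackWindows(track, anchors[ord], halfwidth)
  rownames(M) <- id[ord]
  attr(M, "sortKeys") <- sortKeys[ord]
  M
}

#' Signal score in a window upstream of +1 nucleosomes
#'
#' Scores each +1 anchor by the mean signal over a `window`-bp interval
#' whose downstream edge sits `upstreamOffset` bp upstream of the +1 dyad,
#' in gene orientation (for a +-strand dyad at 0-based position d, the
#' window is `[d - upstreamOffset - window, d - upstreamOffset)`). Used
#' e.g. to rank promoters by in vivo Reb1 binding signal.
#'
#' @param track A [BpTrack-class] of per-bp signal.
#' @param plus1Anchors Width-1 stranded `GRanges` of +1 dyads.
#' @param window Window length in bp (default 120).
#' @param upstreamOffset Distance from the dyad to the window's downstream
#'   edge in bp (default 160).
#' @return Numeric score per anchor (`NA` where the window leaves the
#'   contig, reported with a message).
#' @export
reb1Score <- function(track, plus1Anchors, window = 120L,
                      upstreamOffset = 160L) {
  stopifnot(window >= 0L, upstreamOffset >= 0L)
  vals <- trackValues(track)
  ctg <- as.character(GenomeInfoDb::seqnames(plus1Anchors))
  d <- BiocGenerics::start(plus1Anchors)
  st <- as.character(BiocGenerics::strand(plus1Anchors))
  sc <- rep(NA_real_, length(d))
  for (i in seq_along(d)) {
    v <- vals[[ctg[i]]]
    if (st[i] == "-") {
      s <- d[i] + upstreamOffset
      e <- s + window - 1L
    } else {
      e <- d[i] - upstreamOffset - 1L
      s <- e - window + 1L
    }
    if (s >= 1L && e <= length(v)) sc[i] <- mean(v[s:e])
  }
  if (anyNA(sc))
    message(sum(is.na(sc)), " anchor(s) with window outside contig")
  sc
}

#' Select the top fraction of anchors by score
#'
#' @param scores Numeric scores (`NA` excluded).
#' @param fraction Fraction to select (default 0.125, the "bound" group).
#' @return Logical vector marking the `ceiling(fraction * n)` top-scoring
#'   entries among non-`NA` scores.
#' @export
selectTopFraction <- function(scores, fraction = 0.125) {
  stopifnot(fraction > 0, fraction <= 1)
  ok <- which(!is.na(scores))
  sel <- ok[order(-scores[ok])][seq_len(ceiling(fraction * length(ok)))]
  out <- logical(length(scores))
  out[sel] <- TRUE
  out
}

#' Group promoters by Reb1 site orientation
#'
#' Retains Reb1 hits that carry a PWM motif within `maxPwmDist` bp and lie
#' within `maxUpstream` bp upstream of a gene's +1 dyad (gene
#' orientation). Group 1: PWM motif on the gene's sense strand; group 2:
#' antisense; group 3: the site serves two divergent genes (bidirectional
#' promoter), overriding groups 1/2.
#'
#' @param reb1Hits Width-1 `GRanges` of Reb1 binding-site hits.
#' @param pwmHits Width-1 stranded `GRanges` of Reb1 PWM motif hits.
#' @param plus1 `data.frame` from [annotatePlus1Minus1()] (columns
#'   `gene_id`, `contig`, `strand`, `plus1_dyad`).
#' @param maxPwmDist Maximum hit-to-PWM distance in bp (default 50).
#' @param maxUpstream Maximum hit-to-+1 upstream distance in bp
#'   (default 400).
#' @return `data.frame` with `gene_id`, `group` (1, 2 or 3), `reb1_pos`,
#'   `pwm_pos`, `pwm_strand`; ungrouped genes are omitted.
#' @export
groupPromoters <- function(reb1Hits, pwmHits, plus1, maxPwmDist = 50L,
                           maxUpstream = 400L) {
  hCtg <- as.character(GenomeInfoDb::seqnames(reb1Hits))
  hPos <- BiocGenerics::start(reb1Hits)
  pCtg <- as.character(GenomeInfoDb::seqnames(pwmHits))
  pPos <- BiocGenerics::start(pwmHits)
  pStr <- as.character(BiocGenerics::strand(pwmHits))
  ann <- plus1[!is.na(plus1$plus1_dyad), , drop = FALSE]
  out <- list()
  for (h in seq_along(reb1Hits)) {
    pw <- which(pCtg == hCtg[h] & abs(pPos - hPos[h]) <= maxPwmDist)
    if (!length(pw)) next
    pw <- pw[which.min(abs(pPos[pw] - hPos[h]))]
    sgn <- ifelse(ann$strand == "-", -1L, 1L)
    dUp <- (ann$plus1_dyad - hPos[h]) * sgn
    g <- which(ann$contig == hCtg[h] & dUp > 0 & dUp <= maxUpstream)
    if (!length(g)) next
    divergent <- length(unique(ann$strand[g])) == 2L
    grp <- if (divergent) rep(3L, length(g)) else
      ifelse(ann$strand[g] == pStr[pw], 1L, 2L)
    out[[length(out) + 1L]] <-
      data.frame(gene_id = ann$gene_id[g], group = grp,
                 reb1_pos = hPos[h], pwm_pos = pPos[pw],
                 pwm_strand = pStr[pw])
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), group = integer(0),
                      reb1_pos = integer(0), pwm_pos = integer(0),
                      pwm_strand = character(0)))
  res <- do.call(rbind, out)
  # group 3 overrides 1/2; otherwise keep the first assignment per gene
  res <- res[order(res$gene_id, res$group != 3L), , drop = FALSE]
  res[!duplicated(res$gene_id), , drop = FALSE]
}

#' Distance statistics between two +1 annotations
#'
#' For every gene with a defined +1 in both annotations, computes the
#' signed distance (downstream-positive in gene orientation) from the
#' reference (`invivo`) +1 dyad to the compared (`invitro`) +1 dyad, and
#' summarizes by median and interquartile range.
#'
#' @param invitro,invivo `data.frame`s from [annotatePlus1Minus1()].
#' @return List with `distances` (`data.frame` of `gene_id`, `distance`),
#'   `median`, `q25`, `q75`, `iqr`, `n`.
#' @export
plus1DistanceStats <- function(invitro, invivo) {
  m <- merge(invitro[, c("gene_id", "strand", "plus1_dyad")],
             invivo[, c("gene_id", "plus1_dyad")],
             by = "gene_id", suffixes = c("_vitro", "_vivo"))
  if (nrow(m) == 0L) stop("no shared gene ids between annotations")
  m <- m[!is.na(m$plus1_dyad_vitro) & !is.na(m$plus1_dyad_vivo), ,
         drop = FALSE]
  sgn <- ifelse(m$strand == "-", -1L, 1L)
  d <- (m$plus1_dyad_vitro - m$plus1_dyad_vivo) * sgn
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
  list(distances = data.frame(gene_id = m$gene_id, distance = d),
       median = stats::median(d), q25 = q[1L], q75 = q[2L],
       iqr = q[2L] - q[1L], n = length(d))
}

#' Anchor-relative dyad density distribution
#'
#' Pools oriented dyad-count offsets over all anchors, bins them and
#' normalizes so the density integrates to 1 over the window.
#'
#' @param dyads A [BpTrack-class] of dyad counts (e.g. from
#'   [fragmentCenters()]).
#' @param anchors Width-1 stranded `GRanges`.
#' @param halfwidth Window half-width in bp (default 1000).
#' @param bin Bin width in bp (default 5).
#' @return `data.frame` with `bin_mid`, `width` (bin width in bp),
#'   `count` and `density` (per bp; integrates to 1 over the window).
#' @export
dyadDensity <- function(dyads, anchors, halfwidth = 1000L, bin = 5L) {
  stopifnot(bin >= 1L)
  W <- extractTrackWindows(dyads, anchors, halfwidth)
  counts <- colSums(W, na.rm = TRUE)
  total <- sum(counts)
  if (total == 0) stop("no dyads in any anchor window")
  offsets <- seq(-halfwidth, halfwidth)
  idx <- (offsets + halfwidth) %/% bin + 1L
  cnt <- tapply(counts, idx, sum)
  widths <- tapply(offsets, idx, length)
  left <- -halfwidth + (as.integer(names(cnt)) - 1L) * bin
  data.frame(bin_mid = left + as.numeric(widths) / 2,
             width = as.numeric(widths),
             count = as.numeric(cnt),
             density = as.numeric(cnt) / (total * as.numeric(widths)))
}

#' Mode of a dyad density distribution
#'
#' @param density `data.frame` from [dyadDensity()].
#' @return `bin_mid` of the highest-density bin.
#' @export
densityMode <- function(density) {
  density$bin_mid[which.max(density$density)]
}
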