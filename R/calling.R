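#' Gaussian smoothing of a dyad track
#'
#' Convolves each contig with a normalized Gaussian kernel of
#' `2 * floor(width/2) + 1` taps (101 taps for `width = 100`), mean 0 and
#' the stated standard deviation. Contig edges are zero-padded, so interior
#' mass is preserved and edge mass decays into the padding.
#'
#' @param track A [BpTrack-class] of dyad counts.
#' @param width Kernel width parameter; the kernel spans
#'   `floor(width/2)` bp on each side (default 100, i.e. 101 taps).
#' @param sd Gaussian standard deviation in bp (default 25).
#' @return A [BpTrack-class] with provenance `"smoothed"`.
#' @export
gaussianSmooth <- function(track, width = 100L, sd = 25) {
  if (sd <= 0) stop("sd must be > 0")
  stopifnot(width >= 1L)
  half <- as.integer(width) %/% 2L
  kern <- stats::dnorm(seq(-half, half), mean = 0, sd = sd)
  kern <- kern / sum(kern)
  vals <- lapply(trackValues(track), function(x) {
    if (length(x) == 0L) return(x)
    pad <- c(numeric(half), x, numeric(half))
    y <- stats::filter(pad, kern, method = "convolution", sides = 2L)
    as.numeric(y[(half + 1L):(half + length(x))])
  })
  newBpTrack(vals, sampleId(track), "smoothed")
}

#' Greedy nucleosome dyad calling with an exclusion zone
#'
#' Iteratively selects the position with the highest smoothed value, adds
#' it to the call list and removes all values within `exclusion` bp of it;
#' selection stops when no positive value remains. The calls are then
#' ranked by score and the top `keepFraction` (ceiling rule; ties at the
#' cut resolved by coordinate order) constitute the final call set. Ties in
#' value are broken towards the earlier contig and the smaller coordinate.
#'
#' @param smoothed A [BpTrack-class] (typically from [gaussianSmooth()]).
#' @param exclusion Exclusion half-width in bp: values within
#'   `+/- exclusion` of an accepted call are masked (default 120), so
#'   retained calls on a contig are always more than `exclusion` bp apart.
#' @param keepFraction Fraction of recorded calls retained by score
#'   (default 0.9).
#' @return Width-1 `GRanges` of dyad calls, sorted by coordinate, with
#'   metadata columns `score` and `sample_id`.
#' @export
greedyCall <- function(smoothed, exclusion = 120L, keepFraction = 0.9) {
  stopifnot(keepFraction > 0, keepFraction <= 1)
  exclusion <- as.integer(exclusion)
  vals <- trackValues(smoothed)
  recs <- vector("list", length(vals))
  for (ci in seq_along(vals)) {
    v <- vals[[ci]]
    v[is.na(v)] <- 0
    n <- length(v)
    if (n == 0L) next
    ord <- order(v, decreasing = TRUE)  # stable: ties by position
    masked <- logical(n)
    pos <- integer(0); sco <- numeric(0)
    for (i in ord) {
      if (v[i] <= 0) break
      if (masked[i]) next
      pos <- c(pos, i); sco <- c(sco, v[i])
      masked[max(1L, i - exclusion):min(n, i + exclusion)] <- TRUE
    }
    if (length(pos))
      recs[[ci]] <- data.frame(ci = ci, pos = pos, score = sco)
  }
  rec <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(rec) || nrow(rec) == 0L)
    return(GenomicRanges::GRanges(score = numeric(0),
                                  sample_id = character(0)))
  keep <- utils::head(order(-rec$score, rec$ci, rec$pos),
                      ceiling(keepFraction * nrow(rec)))
  rec <- rec[keep, , drop = FALSE]
  rec <- rec[order(rec$ci, rec$pos), , drop = FALSE]
  GenomicRanges::GRanges(names(vals)[rec$ci],
                         IRanges::IRanges(rec$pos, rec$pos),
                         score = rec$score,
                         sample_id = rep(sampleId(smoothed), nrow(rec)))
}

#' FFT low-pass nucleosome dyad calling
#'
#' Per contig the signal is Fourier transformed, only the DC term plus the
#' lowest `ceiling(pcKeepComp * floor(N/2))` frequency components are
#' retained, and the signal is inverse-transformed. Calls are the strict
#' local maxima of the filtered signal that exceed the `thresholdPct`
#' percentile of the filtered values on that contig.
#'
#' @param coverage A [BpTrack-class] (typically dyad-trimmed coverage from
#'   [trimmedCoverage()]). Every contig must be at least 16 bp long.
#' @param pcKeepComp Fraction of frequency components kept (default 0.02).
#' @param thresholdPct Percentile (0-100) of filtered values used as call
#'   threshold, computed per contig over all positions (default 99).
#' @param minDistance Optional minimum distance between calls; 0 (default)
#'   performs no merging, otherwise lower peaks closer than `minDistance`
#'   bp to an accepted higher peak are discarded.
#' @return Width-1 `GRanges` of dyad calls with metadata columns `score`
#'   (filtered value) and `sample_id`.
#' @export
fftCall <- function(coverage, pcKeepComp = 0.02, thresholdPct = 99,
                    minDistance = 0L) {
  vals <- trackValues(coverage)
  pos <- integer(0); ctgs <- character(0); sco <- numeric(0)
  for (ctg in names(vals)) {
    x <- vals[[ctg]]
    n <- length(x)
    if (n < 16L) stop("contig ", ctg, " shorter than 16 bp")
    xf <- fftLowpass(x, pcKeepComp)
    thr <- stats::quantile(xf, thresholdPct / 100, names = FALSE)
    i <- which(xf > thr)
    i <- i[i > 1L & i < n]
    i <- i[xf[i] > xf[i - 1L] & xf[i] > xf[i + 1L]]
    if (minDistance > 0L && length(i) > 1L) {
      acc <- integer(0)
      for (j in i[order(-xf[i], i)]) {
        if (!length(acc) || all(abs(acc - j) >= minDistance))
          acc <- c(acc, j)
      }
      i <- sort(acc)
    }
    if (length(i)) {
      pos <- c(pos, i); ctgs <- c(ctgs, rep(ctg, length(i)))
      sco <- c(sco, xf[i])
    }
  }
  GenomicRanges::GRanges(factor(ctgs, names(vals)),
                         IRanges::IRanges(pos, pos), score = sco,
                         sample_id = rep(sampleId(coverage), length(pos)))
}

#' FFT low-pass filter of a numeric signal
#'
#' Keeps the DC term plus the `ceiling(pcKeepComp * floor(N/2))` lowest
#' frequency components (and their conjugates); all other components are
#' zeroed. No padding or windowing is applied, so ringing can occur at
#' sharp edges.
#'
#' @param x Numeric vector.
#' @param pcKeepComp Fraction of frequency components kept.
#' @return Filtered numeric vector of the same length.
#' @export
fftLowpass <- function(x, pcKeepComp = 0.02) {
  n <- length(x)
  f <- stats::fft(x)
  nf <- n %/% 2L
  k <- min(nf, ceiling(pcKeepComp * nf))
  mask <- logical(n)
  mask[1L] <- TRUE
  if (k >= 1L) {
    mask[2L:(k + 1L)] <- TRUE
    mask[(n - k + 1L):n] <- TRUE
  }
  Re(stats::fft(f * mask, inverse = TRUE)) / n
}

#' Annotate +1 and -1 nucleosomes per gene
#'
#' The +1 nucleosome of a gene is the called dyad nearest to its TSS
#' within a window of 0 to +500 bp downstream (in gene orientation); the
#' -1 nucleosome is the first called dyad upstream of the +1. Genes
#' without a candidate get `NA` entries.
#'
#' @param calls Width-1 `GRanges` of dyad calls.
#' @param genes Width-1 stranded `GRanges` of TSS anchors with an `id`
#'   metadata column (unstranded genes are treated as `+`).
#' @param window Numeric length-2: allowed signed TSS-to-dyad distance
#'   range for the +1 (default `c(0, 500)`).
#' @return A `data.frame` with one row per gene: `gene_id`, `contig`,
#'   `strand`, `tss`, `plus1_dyad`, `minus1_dyad` (1-based dyad bases) and
#'   `ndr_length` (signed distance from -1 to +1 dyad, bp).
#' @export
annotatePlus1Minus1 <- function(calls, genes, window = c(0, 500)) {
  gCtg <- as.character(GenomeInfoDb::seqnames(genes))
  gStr <- as.character(BiocGenerics::strand(genes))
  gStr[gStr == "*"] <- "+"
  gTss <- BiocGenerics::start(genes)
  gId <- if ("id" %in% names(S4Vectors::mcols(genes))) genes$id else
    paste0("gene", seq_along(genes))
  cCtg <- as.character(GenomeInfoDb::seqnames(calls))
  cPos <- BiocGenerics::start(calls)
  res <- data.frame(gene_id = gId, contig = gCtg, strand = gStr,
                    tss = gTss, plus1_dyad = NA_integer_,
                    minus1_dyad = NA_integer_, ndr_length = NA_integer_)
  for (g in seq_along(genes)) {
    onCtg <- which(cCtg == gCtg[g])
    if (!length(onCtg)) next
    sgn <- if (gStr[g] == "-") -1L else 1L
    signed <- (cPos[onCtg] - gTss[g]) * sgn
    cand <- which(signed >= window[1] & signed <= window[2])
    if (!length(cand)) next
    p1 <- cand[order(signed[cand], cPos[onCtg][cand])][1L]
    res$plus1_dyad[g] <- cPos[onCtg][p1]
    up <- which(signed < signed[p1])
    if (length(up)) {
      m1 <- up[order(-signed[up], cPos[onCtg][up])][1L]
      res$minus1_dyad[g] <- cPos[onCtg][m1]
      res$ndr_length[g] <- signed[p1] - signed[m1]
    }
  }
  res
}
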