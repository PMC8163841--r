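#' Configuration of the synthetic MNase-seq forward model
#'
#' Defines a tiled genome with planted, sequence-linked nucleosome
#' preferences: each gene has a true +1 dyad flanked by a rigid A-tract
#' centered 100 bp upstream and a flexible (TpA/GC-rich) element centered
#' 55 bp upstream (gene orientation), optionally a Reb1 motif (TTACCC)
#' starting 145 bp upstream of the dyad, and an alternative dyad 70 bp
#' downstream carrying a weak A-tract of its own. The first condition
#' prefers the true +1 dyads, the second the alternative dyads; fragments
#' are ~147 bp with Gaussian dyad jitter on top of a uniform background.
#'
#' @param nTiles Number of tiles (contigs; default 50).
#' @param tileLen Tile length in bp (default 10000).
#' @param gcFraction GC content of the background sequence (default 0.38).
#' @param genesPerTile Genes per tile (default 3).
#' @param rigidLen Length of the rigid A-tract (default 12).
#' @param rigidCenter Oriented offset of the A-tract center from the true
#'   +1 dyad (default -100).
#' @param flexElement Flexible element sequence planted centered at
#'   `flexCenter` (default a 12-bp TpA/GC repeat with zero rigidity).
#' @param flexCenter Oriented offset of the flexible element center
#'   (default -55).
#' @param reb1 Plant Reb1 motifs (default `TRUE`).
#' @param reb1Motif Motif sequence in sense-strand representation
#'   (default `"TTACCC"`).
#' @param reb1Offset Distance from the motif start (5' base in gene
#'   orientation) to the true +1 dyad in bp (default 145).
#' @param altOffset Oriented offset of the alternative dyad from the true
#'   +1 dyad (default +70).
#' @param altElementLen Length of the alternative dyad's weak A-tract
#'   (default 5).
#' @param tssOffset Distance from the TSS to the true +1 dyad in bp
#'   (default 60, i.e. the +1 dyad is 60 bp downstream of the TSS).
#' @param conditions Two condition labels; the first prefers true +1
#'   dyads, the second the alternative dyads
#'   (default `c("remodeled", "sgd")`).
#' @param primaryWeight Probability that a non-background fragment of the
#'   first condition sits on the true +1 dyad (mirrored for the second
#'   condition; default 0.85).
#' @param replicates Replicates per condition (default 2).
#' @param jitterSd Gaussian dyad jitter SD in bp (default 5).
#' @param backgroundFraction Fraction of fragments placed uniformly on the
#'   genome (default 0.3).
#' @param fragLenMean,fragLenSd,fragLenMin,fragLenMax Fragment length law:
#'   normal(147, 10) clipped to [120, 180].
#' @param nFragments Fragments per sample (default 200000).
#' @return Validated configuration list (class `"SyntheticConfig"`).
#' @export
syntheticConfig <- function(nTiles = 50L, tileLen = 10000L,
                            gcFraction = 0.38, genesPerTile = 3L,
                            rigidLen = 12L, rigidCenter = -100L,
                            flexElement = "CGTACGTACGTA",
                            flexCenter = -55L,
                            reb1 = TRUE, reb1Motif = "TTACCC",
                            reb1Offset = 145L,
                            altOffset = 70L, altElementLen = 5L,
                            tssOffset = 60L,
                            conditions = c("remodeled", "sgd"),
                            primaryWeight = 0.85, replicates = 2L,
                            jitterSd = 5, backgroundFraction = 0.3,
                            fragLenMean = 147, fragLenSd = 10,
                            fragLenMin = 120L, fragLenMax = 180L,
                            nFragments = 200000L) {
  cfg <- list(nTiles = as.integer(nTiles), tileLen = as.integer(tileLen),
              gcFraction = gcFraction, genesPerTile = as.integer(genesPerTile),
              rigidLen = as.integer(rigidLen),
              rigidCenter = as.integer(rigidCenter),
              flexElement = toupper(flexElement),
              flexCenter = as.integer(flexCenter),
              reb1 = isTRUE(reb1), reb1Motif = toupper(reb1Motif),
              reb1Offset = as.integer(reb1Offset),
              altOffset = as.integer(altOffset),
              altElementLen = as.integer(altElementLen),
              tssOffset = as.integer(tssOffset),
              conditions = as.character(conditions),
              primaryWeight = primaryWeight,
              replicates = as.integer(replicates),
              jitterSd = jitterSd,
              backgroundFraction = backgroundFraction,
              fragLenMean = fragLenMean, fragLenSd = fragLenSd,
              fragLenMin = as.integer(fragLenMin),
              fragLenMax = as.integer(fragLenMax),
              nFragments = as.integer(nFragments))
  stopifnot(cfg$nTiles >= 1L, cfg$tileLen >= 2000L,
            cfg$gcFraction > 0, cfg$gcFraction < 1,
            cfg$genesPerTile >= 1L, cfg$rigidLen >= 2L,
            length(cfg$conditions) == 2L,
            cfg$primaryWeight > 0.5, cfg$primaryWeight <= 1,
            cfg$jitterSd >= 0, cfg$backgroundFraction >= 0,
            cfg$backgroundFraction < 1,
            cfg$fragLenMin >= 1L, cfg$fragLenMax >= cfg$fragLenMin,
            cfg$nFragments >= 1L)
  class(cfg) <- "SyntheticConfig"
  cfg
}

# overwrite background sequence with an element; startOffset is the
# oriented offset of the element's most upstream base (gene orientation)
.plantElement <- function(chars, dyad, strand, startOffset, element) {
  len <- nchar(element)
  if (strand == "-") {
    # genomic span of oriented offsets [startOffset, startOffset+len-1]
    idx <- (dyad - startOffset - len + 1L):(dyad - startOffset)
    chars[idx] <- strsplit(revcompStr(element), "", fixed = TRUE)[[1L]]
  } else {
    idx <- (dyad + startOffset):(dyad + startOffset + len - 1L)
    chars[idx] <- strsplit(element, "", fixed = TRUE)[[1L]]
  }
  list(chars = chars, span = range(idx))
}

#' Generate the synthetic reference: genome, anchors and ground truth
#'
#' Draws i.i.d. background sequence at the configured GC content and
#' overwrites it with the planted elements of every gene. Deterministic
#' given `seed`; two seeds share the same plant geometry but different
#' backgrounds.
#'
#' @param config A [syntheticConfig()] object.
#' @param seed Integer RNG seed (`NULL` uses the current RNG stream).
#' @return List (class `"SyntheticReference"`) with `genome`
#'   ([NucGenome-class]), `tss`, `plus1`, `reb1` (width-1 stranded
#'   `GRanges` anchors with `id`), `truth` (`data.frame` with per-gene
#'   coordinates and preference labels) and `config`.
#' @export
generateReference <- function(config = syntheticConfig(), seed = 1L) {
  stopifnot(inherits(config, "SyntheticConfig"))
  withSeed(seed, {
    pA <- (1 - config$gcFraction) / 2
    pG <- config$gcFraction / 2
    tiles <- sprintf("tile%03d", seq_len(config$nTiles))
    seqs <- character(config$nTiles)
    truth <- list()
    for (t in seq_len(config$nTiles)) {
      chars <- sample(c("A", "C", "G", "T"), config$tileLen,
                      replace = TRUE, prob = c(pA, pG, pG, pA))
      spans <- list()
      for (g in seq_len(config$genesPerTile)) {
        d <- as.integer(round(config$tileLen * (g - 0.5) /
                                config$genesPerTile))
        strand <- if (g %% 2L == 1L) "+" else "-"
        sgn <- if (strand == "-") -1L else 1L
        if (min(d, config$tileLen - d) < 200L + abs(config$reb1Offset))
          stop("planted dyad too close to tile border; use longer tiles")
        rigidStart <- config$rigidCenter - (config$rigidLen - 1L) %/% 2L -
          ((config$rigidLen %% 2L == 0L))  # center -100, even len -> -106
        p <- .plantElement(chars, d, strand, rigidStart,
                           strrep("A", config$rigidLen))
        chars <- p$chars; spans <- c(spans, list(p$span))
        flexLen <- nchar(config$flexElement)
        flexStart <- config$flexCenter - (flexLen - 1L) %/% 2L -
          (flexLen %% 2L == 0L)
        p <- .plantElement(chars, d, strand, flexStart, config$flexElement)
        chars <- p$chars; spans <- c(spans, list(p$span))
        alt <- d + sgn * config$altOffset
        p <- .plantElement(chars, alt, strand, -100L,
                           strrep("A", config$altElementLen))
        chars <- p$chars; spans <- c(spans, list(p$span))
        reb1Pos <- NA_integer_
        if (config$reb1) {
          p <- .plantElement(chars, d, strand, -config$reb1Offset,
                             config$reb1Motif)
          chars <- p$chars; spans <- c(spans, list(p$span))
          reb1Pos <- d - sgn * config$reb1Offset
        }
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = sprintf("%sg%d", tiles[t], g), contig = tiles[t],
          strand = strand, tss = d - sgn * config$tssOffset,
          plus1_dyad = d, alt_dyad = alt, reb1_pos = reb1Pos,
          preferred_primary = config$conditions[1L],
          preferred_alt = config$conditions[2L])
      }
      sp <- do.call(rbind, spans)
      sp <- sp[order(sp[, 1L]), , drop = FALSE]
      if (nrow(sp) > 1L && any(sp[-1L, 1L] <= sp[-nrow(sp), 2L]))
        stop("planted elements collide; use a sparser gene layout")
      seqs[t] <- paste(chars, collapse = "")
    }
    truth <- do.call(rbind, truth)
    genome <- nucGenome(stats::setNames(seqs, tiles))
    mk <- function(pos, strand, id) {
      keep <- !is.na(pos)
      GenomicRanges::GRanges(truth$contig[keep],
                             IRanges::IRanges(pos[keep], pos[keep]),
                             strand = strand[keep], id = id[keep])
    }
    structure(list(genome = genome,
                   tss = mk(truth$tss, truth$strand, truth$gene_id),
                   plus1 = mk(truth$plus1_dyad, truth$strand,
                              truth$gene_id),
                   reb1 = mk(truth$reb1_pos, truth$strand,
                             paste0(truth$gene_id, "_reb1")),
                   truth = truth, config = config),
              class = "SyntheticReference")
  })
}

#' Simulate an MNase-seq fragment sample
#'
#' Fragment centers are either uniform background (with probability
#' `backgroundFraction`) or a planted dyad drawn according to the
#' condition's preference plus rounded Gaussian jitter; fragment lengths
#' follow the clipped-normal law. Fragments that would cross a contig end
#' are re-drawn (bounded retries, then dropped with a message).
#'
#' @param reference A `"SyntheticReference"` from [generateReference()].
#' @param condition One of the configured condition labels.
#' @param nFragments Number of fragments (default from the config).
#' @param seed Integer RNG seed (`NULL` uses the current RNG stream).
#' @param sampleId Sample label (default the condition name).
#' @return `GRanges` of fragments with a `sample_id` metadata column.
#' @export
simulateFragments <- function(reference, condition,
                              nFragments = NULL, seed = NULL,
                              sampleId = condition) {
  stopifnot(inherits(reference, "SyntheticReference"))
  cfg <- reference$config
  if (!condition %in% cfg$conditions)
    stop("unknown condition: ", condition)
  if (is.null(nFragments)) nFragments <- cfg$nFragments
  truth <- reference$truth
  lens <- contigLengths(reference$genome)
  wPrimary <- if (condition == cfg$conditions[1L]) cfg$primaryWeight else
    1 - cfg$primaryWeight
  withSeed(seed, {
    n <- as.integer(nFragments)
    contig <- character(n)
    center <- integer(n)
    drawCenters <- function(idx) {
      m <- length(idx)
      isBg <- stats::runif(m) < cfg$backgroundFraction
      nBg <- sum(isBg)
      if (nBg) {
        ctgB <- sample(names(lens), nBg, replace = TRUE, prob = lens)
        contig[idx[isBg]] <<- ctgB
        center[idx[isBg]] <<- floor(stats::runif(nBg) * lens[ctgB]) + 1L
      }
      if (m - nBg) {
        gi <- sample.int(nrow(truth), m - nBg, replace = TRUE)
        usePrim <- stats::runif(m - nBg) < wPrimary
        dy <- ifelse(usePrim, truth$plus1_dyad[gi], truth$alt_dyad[gi])
        contig[idx[!isBg]] <<- truth$contig[gi]
        center[idx[!isBg]] <<-
          as.integer(dy + round(stats::rnorm(m - nBg, 0, cfg$jitterSd)))
      }
    }
    drawLen <- function(m) {
      pmax(cfg$fragLenMin,
           pmin(cfg$fragLenMax,
                as.integer(round(stats::rnorm(m, cfg$fragLenMean,
                                              cfg$fragLenSd)))))
    }
    drawCenters(seq_len(n))
    len <- drawLen(n)
    s <- center - len %/% 2L
    e <- s + len - 1L
    bad <- which(s < 1L | e > lens[contig] | center < 1L |
                   center > lens[contig])
    tries <- 0L
    while (length(bad) && tries < 100L) {
      drawCenters(bad)
      len[bad] <- drawLen(length(bad))
      s <- center - len %/% 2L
      e <- s + len - 1L
      bad <- which(s < 1L | e > lens[contig] | center < 1L |
                     center > lens[contig])
      tries <- tries + 1L
    }
    if (length(bad)) {
      message(length(bad), " fragment(s) dropped after bounded retries")
      keep <- setdiff(seq_len(n), bad)
      contig <- contig[keep]; s <- s[keep]; e <- e[keep]
    }
    GenomicRanges::GRanges(contig, IRanges::IRanges(s, e),
                           sample_id = rep(sampleId, length(s)))
  })
}

#' Write a synthetic reference to disk
#'
#' Emits `genome.fa`, `tss.bed`, `plus1_truth.bed`, `reb1_sites.bed` and
#' `truth.tsv` into a directory.
#'
#' @param reference A `"SyntheticReference"`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeSyntheticReference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(genomeSeqs(reference$genome),
                              file.path(dir, "genome.fa"))
  writeAnchors(reference$tss, file.path(dir, "tss.bed"))
  writeAnchors(reference$plus1, file.path(dir, "plus1_truth.bed"))
  if (length(reference$reb1))
    writeAnchors(reference$reb1, file.path(dir, "reb1_sites.bed"))
  utils::write.table(reference$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
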