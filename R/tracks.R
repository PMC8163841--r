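# fragment center base, 1-based (floor rule for even lengths)
fragmentCenterPos <- function(fragments) {
  BiocGenerics::start(fragments) + BiocGenerics::width(fragments) %/% 2L
}

# coverage of clipped windows as a plain numeric list
.windowCoverage <- function(contig, s, e, lens) {
  vals <- emptyTrackValues(lens)
  s <- pmax(s, 1L)
  e <- pmin(e, lens[contig])
  keep <- e >= s
  contig <- contig[keep]; s <- s[keep]; e <- e[keep]
  if (length(contig)) {
    si <- GenomeInfoDb::Seqinfo(names(lens), unname(lens))
    gr <- GenomicRanges::GRanges(factor(contig, names(lens)),
                                 IRanges::IRanges(s, e), seqinfo = si)
    cov <- GenomicRanges::coverage(gr)
    for (ctg in names(vals)) vals[[ctg]] <- as.numeric(cov[[ctg]])
  }
  vals
}

.sampleIdOf <- function(gr, sampleId) {
  if (!is.null(sampleId)) return(sampleId)
  sid <- unique(S4Vectors::mcols(gr)$sample_id)
  if (length(sid) == 1L) sid else "sample"
}

#' Dyad-center counts from paired-end fragments
#'
#' Each fragment contributes one count at its center base,
#' `start + floor(length / 2)` in 0-based coordinates (so a 147-bp
#' fragment starting at 0-based 100 counts at 0-based 173). Total track
#' mass equals the number of fragments.
#'
#' @param fragments `GRanges` of fragments (e.g. from [readFragments()]).
#' @param genome [NucGenome-class] defining contigs and lengths.
#' @param sampleId Sample label; defaults to the fragments' `sample_id`.
#' @return A [BpTrack-class] of integer dyad-center counts
#'   (provenance `"raw"`).
#' @export
fragmentCenters <- function(fragments, genome, sampleId = NULL) {
  lens <- contigLengths(genome)
  vals <- emptyTrackValues(lens)
  if (length(fragments)) {
    ctg <- as.character(GenomeInfoDb::seqnames(fragments))
    .checkAgainstGenome(ctg, BiocGenerics::end(fragments), genome,
                        "fragment")
    ctr <- fragmentCenterPos(fragments)
    for (nm in unique(ctg)) {
      i <- ctg == nm
      vals[[nm]] <- as.numeric(tabulate(ctr[i], nbins = lens[[nm]]))
    }
  }
  newBpTrack(vals, .sampleIdOf(fragments, sampleId), "raw")
}

#' Dyad coverage from shifted single-end reads
#'
#' Each read's 5' position is shifted by `shift` bp towards the dyad
#' (downstream for `+` reads, upstream for `-` reads) and the dyad is
#' extended to an `extend`-bp window centered on it
#' (`[d - extend/2, d + extend/2)` in 0-based coordinates). Dyads falling
#' outside their contig are dropped with a message; windows crossing a
#' contig end are clipped.
#'
#' @param reads Width-1 stranded `GRanges` of read 5' positions (e.g. BED6
#'   reads via [readAnchors()]). Unstranded reads are treated as `+`.
#' @param genome [NucGenome-class].
#' @param shift Dyad shift in bp (default 73).
#' @param extend Extension window length in bp (default 50).
#' @param sampleId Sample label.
#' @return A [BpTrack-class] (provenance `"extended"`).
#' @export
singleEndDyads <- function(reads, genome, shift = 73L, extend = 50L,
                           sampleId = NULL) {
  stopifnot(shift >= 0L, extend >= 1L)
  lens <- contigLengths(genome)
  if (length(reads) == 0L)
    return(newBpTrack(emptyTrackValues(lens), .sampleIdOf(reads, sampleId),
                      "extended"))
  ctg <- as.character(GenomeInfoDb::seqnames(reads))
  .checkAgainstGenome(ctg, BiocGenerics::start(reads), genome, "read")
  st <- as.character(BiocGenerics::strand(reads))
  sgn <- ifelse(st == "-", -1L, 1L)
  d <- BiocGenerics::start(reads) + sgn * as.integer(shift)
  inside <- d >= 1L & d <= lens[ctg]
  if (any(!inside))
    message(sum(!inside), " read(s) dropped: shifted dyad outside contig")
  half <- as.integer(extend) %/% 2L
  s <- d[inside] - half
  e <- s + as.integer(extend) - 1L
  vals <- .windowCoverage(ctg[inside], s, e, lens)
  newBpTrack(vals, .sampleIdOf(reads, sampleId), "extended")
}

#' Dyad-trimmed fragment coverage
#'
#' Each fragment is reduced to a `trim`-bp window centered on its dyad
#' (center base) and the coverage of the trimmed windows is computed.
#' Windows crossing a contig end are clipped.
#'
#' @param fragments `GRanges` of fragments.
#' @param genome [NucGenome-class].
#' @param trim Even trimmed length in bp (default 40).
#' @param sampleId Sample label.
#' @return A [BpTrack-class] (provenance `"trimmed"`).
#' @export
trimmedCoverage <- function(fragments, genome, trim = 40L,
                            sampleId = NULL) {
  trim <- as.integer(trim)
  stopifnot(trim >= 2L, trim %% 2L == 0L)
  lens <- contigLengths(genome)
  if (length(fragments) == 0L)
    return(newBpTrack(emptyTrackValues(lens),
                      .sampleIdOf(fragments, sampleId), "trimmed"))
  ctg <- as.character(GenomeInfoDb::seqnames(fragments))
  .checkAgainstGenome(ctg, BiocGenerics::end(fragments), genome, "fragment")
  ctr <- fragmentCenterPos(fragments)
  s <- ctr - trim %/% 2L
  e <- s + trim - 1L
  vals <- .windowCoverage(ctg, s, e, lens)
  newBpTrack(vals, .sampleIdOf(fragments, sampleId), "trimmed")
}

#' Total mass of a track
#'
#' @param track A [BpTrack-class].
#' @return Sum of all defined per-bp values.
#' @export
trackMass <- function(track) {
  sum(vapply(trackValues(track), function(x) sum(x, na.rm = TRUE),
             numeric(1)))
}
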