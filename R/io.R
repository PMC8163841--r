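#' Read a genome FASTA file
#'
#' Reads a (multi-)FASTA file into a [NucGenome-class] object. Sequences
#' are uppercased; record order is preserved; contig names are the first
#' whitespace-delimited token of each header. Contigs containing ambiguous
#' bases (N) are reported with a message.
#'
#' @param path Path to a FASTA file.
#' @param tileBoundaries Optional named list of integer vectors giving
#'   internal tile boundaries per contig (0-based offsets). Contig starts
#'   and ends are always treated as boundaries and need not be listed.
#' @return A [NucGenome-class] object.
#' @export
readGenome <- function(path, tileBoundaries = list()) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(nm))) stop("FASTA record with empty name")
  if (anyDuplicated(nm)) stop("duplicate contig name: ",
                              nm[duplicated(nm)][1L])
  if (any(BiocGenerics::width(seqs) == 0L)) stop("empty FASTA record")
  chr <- toupper(as.character(seqs))
  if (any(grepl("[^ACGTN]", chr)))
    stop("genome contains characters outside {A,C,G,T,N}")
  nAmb <- sum(grepl("N", chr, fixed = TRUE))
  if (nAmb > 0L)
    message(nAmb, " contig(s) contain ambiguous bases (N)")
  nucGenome(stats::setNames(chr, nm), tileBoundaries)
}

#' Construct a NucGenome from character sequences
#'
#' @param seqs Named character vector of DNA sequences.
#' @param tileBoundaries Optional named list of internal tile boundaries
#'   (0-based offsets) per contig.
#' @return A [NucGenome-class] object.
#' @export
nucGenome <- function(seqs, tileBoundaries = list()) {
  methods::new("NucGenome",
               seqs = Biostrings::DNAStringSet(toupper(seqs)),
               tileBoundaries = tileBoundaries)
}

# whitespace-delimited BED-family table, skipping header-ish lines
.readBedTable <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln) & !grepl("^(track|browser|#)", ln)]
  if (length(ln) == 0L)
    return(data.frame())
  utils::read.table(text = ln, header = FALSE, sep = "", fill = TRUE,
                    stringsAsFactors = FALSE, colClasses = NA)
}

.checkAgainstGenome <- function(contig, endPos, genome, what) {
  lens <- contigLengths(genome)
  missing <- setdiff(unique(contig), names(lens))
  if (length(missing))
    stop(what, " reference contig(s) absent from genome: ",
         paste(missing, collapse = ", "))
  if (any(endPos > lens[contig]))
    stop(what, " extends past the end of its contig; ",
         "genome/", what, " mismatch")
  invisible(TRUE)
}

#' Read mapped fragments from BED or BEDPE
#'
#' BED rows (chrom, start, end, ...) map directly to fragments; BEDPE rows
#' (chrom1, start1, end1, chrom2, start2, end2, ...) are collapsed to the
#' span from the leftmost mate start to the rightmost mate end. Rows with a
#' non-positive span are rejected with a warning. Input coordinates are
#' 0-based half-open; the returned ranges are 1-based closed.
#'
#' @param path Path to a BED3+/BEDPE file.
#' @param sampleId Sample label stored in the `sample_id` metadata column.
#' @param genome Optional [NucGenome-class]; when supplied, fragments on
#'   unknown contigs or crossing a contig end are a hard error.
#' @param format `"auto"`, `"bed"` or `"bedpe"`.
#' @return A \link[GenomicRanges]{GRanges} of fragments.
#' @export
readFragments <- function(path, sampleId = "sample", genome = NULL,
                          format = c("auto", "bed", "bedpe")) {
  format <- match.arg(format)
  tab <- .readBedTable(path)
  if (nrow(tab) == 0L)
    return(GenomicRanges::GRanges(sample_id = character(0)))
  if (format == "auto") {
    isPE <- ncol(tab) >= 6L && is.character(tab[[4L]]) &&
      is.numeric(tab[[5L]]) && is.numeric(tab[[6L]]) &&
      all(tab[[4L]] %in% unique(c(tab[[1L]], tab[[4L]])))
    format <- if (isPE && any(tab[[4L]] %in% tab[[1L]])) "bedpe" else "bed"
  }
  if (format == "bedpe") {
    if (ncol(tab) < 6L) stop("BEDPE requires >= 6 columns")
    same <- tab[[1L]] == tab[[4L]]
    if (any(!same)) {
      warning(sum(!same), " interchromosomal BEDPE row(s) rejected")
      tab <- tab[same, , drop = FALSE]
    }
    contig <- tab[[1L]]
    s0 <- pmin(as.integer(tab[[2L]]), as.integer(tab[[5L]]))
    e0 <- pmax(as.integer(tab[[3L]]), as.integer(tab[[6L]]))
  } else {
    if (ncol(tab) < 3L) stop("BED requires >= 3 columns")
    contig <- tab[[1L]]
    s0 <- as.integer(tab[[2L]])
    e0 <- as.integer(tab[[3L]])
  }
  ok <- e0 > s0
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with end <= start rejected")
    contig <- contig[ok]; s0 <- s0[ok]; e0 <- e0[ok]
  }
  if (!is.null(genome)) .checkAgainstGenome(contig, e0, genome, "fragment")
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(s0 + 1L, e0),
                               sample_id = rep(sampleId, length(s0)))
  if (!is.null(genome))
    GenomeInfoDb::seqlevels(gr) <- names(contigLengths(genome))
  gr
}

#' Read single-bp anchors from BED
#'
#' Each interval is reduced to a single anchor base: the interval start for
#' `+` (or unstranded) rows, `end - 1` for `-` rows (file coordinates,
#' 0-based half-open). The BED score column, when present, is stored as the
#' sort key `score`.
#'
#' @param path Path to a BED3+/BED6 file.
#' @param genome Optional [NucGenome-class] for coordinate validation.
#' @return A width-1 \link[GenomicRanges]{GRanges} with metadata columns
#'   `id` and `score`.
#' @export
readAnchors <- function(path, genome = NULL) {
  tab <- .readBedTable(path)
  if (nrow(tab) == 0L)
    return(GenomicRanges::GRanges(id = character(0), score = numeric(0)))
  if (ncol(tab) < 3L) stop("anchor BED requires >= 3 columns")
  contig <- tab[[1L]]
  s0 <- as.integer(tab[[2L]])
  e0 <- as.integer(tab[[3L]])
  id <- if (ncol(tab) >= 4L) as.character(tab[[4L]]) else
    rep(NA_character_, length(s0))
  id[is.na(id)] <- paste0("anchor", which(is.na(id)))
  score <- if (ncol(tab) >= 5L) suppressWarnings(as.numeric(tab[[5L]]))
    else rep(NA_real_, length(s0))
  strand <- if (ncol(tab) >= 6L) as.character(tab[[6L]]) else
    rep(".", length(s0))
  strand[is.na(strand) | strand == ""] <- "."
  if (!all(strand %in% c("+", "-", "."))) stop("malformed strand character")
  pos1 <- ifelse(strand == "-", e0, s0 + 1L)  # 1-based anchor base
  if (!is.null(genome)) .checkAgainstGenome(contig, pos1, genome, "anchor")
  GenomicRanges::GRanges(contig, IRanges::IRanges(pos1, pos1),
                         strand = sub("^\\.$", "*", strand),
                         id = id, score = score)
}

#' Write single-bp anchors to BED6
#'
#' @param anchors Width-1 stranded `GRanges` with metadata columns `id`
#'   and (optionally) `score`.
#' @param path Output path.
#' @export
writeAnchors <- function(anchors, path) {
  stopifnot(all(BiocGenerics::width(anchors) == 1L))
  sc <- if ("score" %in% names(S4Vectors::mcols(anchors)))
    S4Vectors::mcols(anchors)$score else rep(0, length(anchors))
  sc[is.na(sc)] <- 0
  id <- if ("id" %in% names(S4Vectors::mcols(anchors)))
    S4Vectors::mcols(anchors)$id else paste0("anchor", seq_along(anchors))
  st <- as.character(BiocGenerics::strand(anchors))
  st[st == "*"] <- "."
  df <- data.frame(as.character(GenomeInfoDb::seqnames(anchors)),
                   BiocGenerics::start(anchors) - 1L,
                   BiocGenerics::start(anchors), id, sc, st)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write fragments to BEDPE or BED
#'
#' BEDPE output emits two pseudo-mates of up to 50 bp at the fragment ends
#' (the span of the mates reconstructs the fragment exactly on re-reading).
#'
#' @param fragments `GRanges` of fragments.
#' @param path Output path.
#' @param format `"bedpe"` or `"bed"`.
#' @export
writeFragments <- function(fragments, path, format = c("bedpe", "bed")) {
  format <- match.arg(format)
  chrom <- as.character(GenomeInfoDb::seqnames(fragments))
  s0 <- BiocGenerics::start(fragments) - 1L
  e0 <- BiocGenerics::end(fragments)
  if (format == "bed") {
    df <- data.frame(chrom, s0, e0)
  } else {
    mate <- pmin(50L, e0 - s0)
    df <- data.frame(chrom, s0, s0 + mate, chrom, e0 - mate, e0,
                     paste0("frag", seq_along(fragments)), 0L, "+", "-")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-bp track as bedGraph
#'
#' Adjacent equal values are run-length merged; intervals are 0-based
#' half-open; positions with `NA`/`NaN` values are omitted.
#'
#' @param track A [BpTrack-class].
#' @param path Output path.
#' @export
writeTrack <- function(track, path) {
  vals <- trackValues(track)
  parts <- lapply(names(vals), function(ctg) {
    r <- S4Vectors::Rle(vals[[ctg]])
    e <- cumsum(S4Vectors::runLength(r))
    s <- e - S4Vectors::runLength(r) + 1L  # 1-based starts
    v <- S4Vectors::runValue(r)
    keep <- !is.na(v)
    GenomicRanges::GRanges(rep(ctg, sum(keep)),
                           IRanges::IRanges(s[keep], e[keep]),
                           score = v[keep])
  })
  gr <- do.call(c, parts)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph track
#'
#' Positions absent from the file are filled with `fill` (0 by default) so
#' that a track written by [writeTrack()] round-trips exactly for finite
#' tracks.
#'
#' @param path Path to a bedGraph file.
#' @param genome [NucGenome-class] supplying contig names and lengths.
#' @param sampleId Sample label for the returned track.
#' @param provenance Provenance tag for the returned track.
#' @param fill Value for positions not covered by the file.
#' @return A [BpTrack-class].
#' @export
readTrack <- function(path, genome, sampleId = "track",
                      provenance = "filtered", fill = 0) {
  lens <- contigLengths(genome)
  vals <- lapply(lens, function(L) rep(fill, L))
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) > 0L) {
    ctgs <- as.character(GenomeInfoDb::seqnames(gr))
    .checkAgainstGenome(ctgs, BiocGenerics::end(gr), genome, "track")
    for (i in seq_along(gr)) {
      vals[[ctgs[i]]][BiocGenerics::start(gr)[i]:BiocGenerics::end(gr)[i]] <-
        gr$score[i]
    }
  }
  newBpTrack(vals, sampleId, provenance)
}
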