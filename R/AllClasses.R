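#' Genome sequence with tile boundaries
#'
#' Holds the reference sequence of a (plasmid-tiled) genome together with
#' the internal tile boundaries used by region filtering. Contig starts and
#' ends always count as tile borders; additional internal borders (e.g.
#' junctions of a tiled plasmid library) can be supplied per contig as
#' 0-based boundary offsets.
#'
#' @slot seqs A \link[Biostrings]{DNAStringSet} of uppercase contig
#'   sequences over the alphabet A, C, G, T, N.
#' @slot tileBoundaries Named list (one element per contig, may be empty)
#'   of integer vectors of internal boundary offsets; boundary `b` sits
#'   between base `b` and base `b + 1` (1-based), i.e. it is the 0-based
#'   coordinate of the first base of the next tile.
#'
#' @exportClass NucGenome
setClass("NucGenome",
  representation(seqs = "DNAStringSet", tileBoundaries = "list"))

setValidity("NucGenome", function(object) {
  nm <- names(object@seqs)
  if (is.null(nm) || any(!nzchar(nm))) return("contig names must be non-empty")
  if (anyDuplicated(nm)) return("contig names must be unique")
  if (any(BiocGenerics::width(object@seqs) < 1L)) return("empty contig sequence")
  bad <- vapply(as.character(object@seqs), function(s)
    grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) return("sequences must only contain A, C, G, T, N")
  tb <- object@tileBoundaries
  if (length(tb) && !all(names(tb) %in% nm))
    return("tileBoundaries names must be contig names")
  TRUE
})

#' Per-bp signal track
#'
#' One numeric value per base, per contig. Used for dyad-center counts,
#' extended/trimmed coverage, and smoothed or filtered occupancy signal.
#' Index `i` of a contig vector is base `i` (1-based).
#'
#' @slot values Named list of numeric vectors, one per contig.
#' @slot sampleId Single character sample label.
#' @slot provenance One of `"raw"`, `"extended"`, `"trimmed"`, `"smoothed"`,
#'   `"filtered"`.
#'
#' @exportClass BpTrack
setClass("BpTrack",
  representation(values = "list", sampleId = "character",
                 provenance = "character"))

setValidity("BpTrack", function(object) {
  v <- object@values
  if (length(v) && (is.null(names(v)) || anyDuplicated(names(v))))
    return("track contigs must be uniquely named")
  if (!all(vapply(v, is.numeric, logical(1))))
    return("track values must be numeric")
  if (length(object@sampleId) != 1L) return("sampleId must be length 1")
  if (!object@provenance %in% c("raw", "extended", "trimmed", "smoothed",
                                "filtered"))
    return("unknown provenance tag")
  if (object@provenance %in% c("raw", "extended", "trimmed")) {
    neg <- vapply(v, function(x) any(x < 0, na.rm = TRUE), logical(1))
    if (any(neg)) return("coverage-type tracks must be non-negative")
  }
  TRUE
})

#' PCA / K-means clustering result for dyad regions
#'
#' @slot pcScores Matrix of principal-component scores, regions x
#'   components.
#' @slot explainedVariance Numeric vector, fraction of variance per
#'   component.
#' @slot labels Integer cluster labels in `1..k`, renumbered by decreasing
#'   cluster size.
#' @slot clusterScores Matrix k x samples of mean normalized occupancy per
#'   cluster.
#' @slot rowScaled `clusterScores` z-scored within each cluster row
#'   (zero-variance rows set to 0).
#' @slot clusterOrder Integer ordering of clusters from hierarchical
#'   clustering of the row-scaled scores (Euclidean distance, average
#'   linkage).
#'
#' @exportClass NucClusterResult
setClass("NucClusterResult",
  representation(pcScores = "matrix", explainedVariance = "numeric",
                 labels = "integer", clusterScores = "matrix",
                 rowScaled = "matrix", clusterOrder = "integer"))

setValidity("NucClusterResult", function(object) {
  k <- nrow(object@clusterScores)
  if (length(object@labels) && (min(object@labels) < 1L ||
                                max(object@labels) > k))
    return("labels out of 1..k")
  if (!all(seq_len(k) %in% object@labels))
    return("every cluster must be non-empty")
  TRUE
})

setMethod("show", "NucGenome", function(object) {
  cat("NucGenome with", length(object@seqs), "contig(s),",
      sum(BiocGenerics::width(object@seqs)), "bp total\n")
  nb <- sum(lengths(object@tileBoundaries))
  if (nb) cat(" ", nb, "internal tile boundaries\n")
})

setMethod("show", "BpTrack", function(object) {
  cat("BpTrack [", object@provenance, "] sample '", object@sampleId,
      "': ", length(object@values), " contig(s), total mass ",
      format(sum(vapply(object@values, function(x) sum(x, na.rm = TRUE),
                        numeric(1)))), "\n", sep = "")
})

setMethod("show", "NucClusterResult", function(object) {
  cat("NucClusterResult:", length(object@labels), "regions,",
      nrow(object@clusterScores), "clusters,",
      ncol(object@clusterScores), "samples\n")
  cat("  explained variance:",
      paste0(round(100 * object@explainedVariance, 1), "%", collapse = ", "),
      "\n")
})

#' @describeIn NucGenome-class Contig sequences as a
#'   \link[Biostrings]{DNAStringSet}.
#' @param x A `NucGenome`, `BpTrack` or `NucClusterResult` object.
#' @export
genomeSeqs <- function(x) x@seqs

#' @describeIn NucGenome-class Named integer vector of contig lengths.
#' @export
contigLengths <- function(x) {
  stats::setNames(BiocGenerics::width(x@seqs), names(x@seqs))
}

#' @describeIn NucGenome-class Internal tile boundaries (0-based offsets),
#'   named list per contig.
#' @export
tileBoundaries <- function(x) x@tileBoundaries

#' @describeIn BpTrack-class Named list of per-contig numeric vectors.
#' @export
trackValues <- function(x) x@values

#' @describeIn BpTrack-class Sample label of a track.
#' @export
sampleId <- function(x) x@sampleId

#' @describeIn BpTrack-class Provenance tag of a track.
#' @export
trackProvenance <- function(x) x@provenance

#' @describeIn NucClusterResult-class Integer cluster labels per region.
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn NucClusterResult-class Principal-component scores.
#' @export
pcScores <- function(x) x@pcScores

#' @describeIn NucClusterResult-class Fraction of variance per component.
#' @export
explainedVariance <- function(x) x@explainedVariance

#' @describeIn NucClusterResult-class Mean normalized occupancy per cluster
#'   and sample.
#' @export
clusterScores <- function(x) x@clusterScores

#' @describeIn NucClusterResult-class Row-scaled cluster scores.
#' @export
rowScaledScores <- function(x) x@rowScaled

#' @describeIn NucClusterResult-class Hierarchical display order of
#'   clusters.
#' @export
clusterOrder <- function(x) x@clusterOrder

# internal constructor used throughout
newBpTrack <- function(values, sampleId = "sample", provenance = "raw") {
  methods::new("BpTrack", values = values, sampleId = as.character(sampleId),
               provenance = provenance)
}

# all-zero track matching a genome's contigs
emptyTrackValues <- function(lens) {
  lapply(stats::setNames(as.integer(lens), names(lens)), numeric)
}
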