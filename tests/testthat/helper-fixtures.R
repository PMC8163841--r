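# Small in-code fixtures shared across test files.

randomGenome <- function(lens, seed = 1, gc = 0.4) {
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, TRUE, prob = p), collapse = ""),
    character(1))
  nucGenome(seqs)
}

trackOf <- function(..., sampleId = "s", provenance = "raw") {
  nucposlab:::newBpTrack(list(...), sampleId = sampleId,
                         provenance = provenance)
}

anchorsAt <- function(contig, pos1, strand = "+", id = NULL) {
  if (is.null(id)) id <- paste0("a", seq_along(pos1))
  GenomicRanges::GRanges(contig, IRanges::IRanges(pos1, pos1),
                         strand = strand, id = id,
                         score = rep(NA_real_, length(pos1)))
}

fragmentsAt <- function(contig, start1, end1, sampleId = "s") {
  GenomicRanges::GRanges(contig, IRanges::IRanges(start1, end1),
                         sample_id = rep(sampleId, length(start1)))
}

writeLinesTmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

# The full-scale planted-truth benchmark, computed once per test session.
.benchCache <- new.env(parent = emptyenv())
acceptanceBenchmark <- function() {
  if (is.null(.benchCache$res))
    .benchCache$res <- suppressMessages(runSyntheticBenchmark(seed = 1))
  .benchCache$res
}
metricValue <- function(res, name) {
  res$metrics$value[match(name, res$metrics$metric)]
}
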