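# reverse complement of a plain character sequence
revcompStr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read a pentamer DNA shape table
#'
#' Expects a TSV with a header row and columns `pentamer`, `feature`,
#' `value` mapping each 5-mer to the value of a DNA shape feature (e.g.
#' propeller twist, helix twist, minor groove width, electrostatic
#' potential). A feature with all 1024 pentamers is flagged complete;
#' missing pentamers yield undefined (`NA`) profile values downstream.
#'
#' @param path Path to the TSV file.
#' @return Named list, one named numeric vector (pentamer -> value) per
#'   feature, each with a logical attribute `"complete"`.
#' @export
readPentamerTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("pentamer", "feature", "value")
  if (!all(need %in% names(tab)))
    stop("pentamer table needs columns: ", paste(need, collapse = ", "))
  tab$pentamer <- toupper(tab$pentamer)
  if (any(!grepl("^[ACGT]{5}$", tab$pentamer)))
    stop("invalid pentamer key in table")
  out <- lapply(split(tab, tab$feature), function(d) {
    if (anyDuplicated(d$pentamer)) stop("duplicate pentamer for a feature")
    v <- stats::setNames(as.numeric(d$value), d$pentamer)
    attr(v, "complete") <- length(v) == 1024L
    v
  })
  out
}

#' Per-bp DNA shape profile from pentamer lookup
#'
#' The value at position `i` is the table value of the pentamer centered
#' on `i`; the two outermost bases on each side, pentamers containing `N`
#' and pentamers absent from the table are undefined (`NA`). The raw
#' profile is then smoothed with a centered rolling mean whose window
#' propagates undefined values (no shrinking at edges).
#'
#' @param sequence Character DNA string (or `DNAString`).
#' @param table Pentamer table from [readPentamerTable()].
#' @param feature Feature name present in `table`.
#' @param smoothWindow Odd rolling-mean window in bp (default 5); 1
#'   disables smoothing.
#' @return Numeric vector of per-bp values, same length as the sequence.
#' @export
shapeProfile <- function(sequence, table, feature, smoothWindow = 5L) {
  if (!feature %in% names(table)) stop("unknown feature: ", feature)
  stopifnot(smoothWindow >= 1L, smoothWindow %% 2L == 1L)
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  vals <- rep(NA_real_, L)
  if (L >= 5L) {
    centers <- 3L:(L - 2L)
    pent <- substring(s, centers - 2L, centers + 2L)
    vals[centers] <- unname(table[[feature]][pent])
  }
  if (smoothWindow > 1L && L < smoothWindow) return(rep(NA_real_, L))
  if (smoothWindow > 1L && L >= 1L) {
    vals <- as.numeric(stats::filter(vals, rep(1 / smoothWindow,
                                               smoothWindow),
                                     method = "convolution", sides = 2L))
  }
  vals
}

#' DNA rigidity score
#'
#' The rigidity score of a position is the length of the longest
#' consecutive A(n)T(m) element (a run of A's followed by a run of T's,
#' with n >= 0, m >= 0 and n + m >= 2; no intervening TpA step or G/C/N
#' base) that contains the position. Positions inside no such element
#' score 0.
#'
#' @param sequence Character DNA string (or `DNAString`) over
#'   A, C, G, T, N.
#' @return Integer vector of per-bp rigidity scores.
#' @export
rigidityProfile <- function(sequence) {
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  score <- integer(L)
  if (L == 0L) return(score)
  r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- 1L
  nRuns <- length(r$values)
  while (i <= nRuns) {
    if (r$values[i] == "A") {
      if (i < nRuns && r$values[i + 1L] == "T") {
        len <- r$lengths[i] + r$lengths[i + 1L]
        if (len >= 2L) score[starts[i]:ends[i + 1L]] <- len
        i <- i + 2L
        next
      }
      if (r$lengths[i] >= 2L) score[starts[i]:ends[i]] <- r$lengths[i]
    } else if (r$values[i] == "T") {
      # a T-run reached here is not preceded by an A-run
      if (r$lengths[i] >= 2L) score[starts[i]:ends[i]] <- r$lengths[i]
    }
    i <- i + 1L
  }
  score
}

#' Poly(dA) / poly(dT) homopolymer coverage
#'
#' Identifies all (overlapping) k-mer matches of `A^k` and `T^k` and
#' assigns, in `count` mode, one unit of coverage per match to each of its
#' k positions; in `binary` mode positions covered by at least one match
#' get value 1.
#'
#' @param sequence Character DNA string (or `DNAString`).
#' @param k Homopolymer length (default 6).
#' @param mode `"count"` or `"binary"`.
#' @return List with numeric per-bp vectors `polyA` and `polyT`.
#' @export
polyATCoverage <- function(sequence, k = 6L, mode = c("count", "binary")) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  one <- function(base) {
    cov <- numeric(L)
    if (L == 0L) return(cov)
    r <- rle(ch == base)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= k)) {
      n <- r$lengths[j]
      pos <- seq_len(n)
      cov[starts[j]:ends[j]] <- pmin(pos, n - pos + 1L, k, n - k + 1L)
    }
    if (mode == "binary") cov <- as.numeric(cov > 0)
    cov
  }
  list(polyA = one("A"), polyT = one("T"))
}

#' Oriented per-position feature profiles around anchors
#'
#' Extracts the `[pos - halfwidth, pos + halfwidth]` window sequence
#' around each anchor (reverse complement for `-` strand anchors),
#' computes the requested per-bp feature, and stacks the profiles. The
#' per-offset mean ignores undefined values. Anchors whose window leaves
#' the contig are dropped with a message.
#'
#' @param genome [NucGenome-class].
#' @param positions Width-1 stranded `GRanges` of anchors (dyads, motif
#'   hits, ...). Unstranded anchors are treated as `+`.
#' @param halfwidth Window half-width in bp; profiles cover offsets
#'   `-halfwidth .. +halfwidth`.
#' @param feature One of `"rigidity"`, `"polyA"`, `"polyT"` or
#'   `"shape:<name>"` (requires `table`).
#' @param table Pentamer table for `shape:` features.
#' @param smoothWindow Rolling-mean window for shape features (default 5).
#' @param mode Counting mode for polyA/polyT (default `"count"`).
#' @param k Homopolymer length for polyA/polyT (default 6).
#' @return List with `profiles` (anchors x offsets matrix), `mean`
#'   (data.frame with `offset`, `mean`, `n`) and `offsets`.
#' @export
windowFeatures <- function(genome, positions, halfwidth, feature,
                           table = NULL, smoothWindow = 5L,
                           mode = "count", k = 6L) {
  lens <- contigLengths(genome)
  chr <- as.character(genomeSeqs(genome))
  ctg <- as.character(GenomeInfoDb::seqnames(positions))
  pos <- BiocGenerics::start(positions)
  st <- as.character(BiocGenerics::strand(positions))
  ok <- pos - halfwidth >= 1L & pos + halfwidth <= lens[ctg]
  if (any(!ok))
    message(sum(!ok), " anchor(s) dropped: window outside contig")
  if (!any(ok)) stop("no anchors with a full window survive")
  ctg <- ctg[ok]; pos <- pos[ok]; st <- st[ok]
  featFun <- if (feature == "rigidity") {
    function(s) as.numeric(rigidityProfile(s))
  } else if (feature %in% c("polyA", "polyT")) {
    function(s) polyATCoverage(s, k = k, mode = mode)[[feature]]
  } else if (startsWith(feature, "shape:")) {
    if (is.null(table)) stop("shape features require a pentamer table")
    nm <- sub("^shape:", "", feature)
    function(s) shapeProfile(s, table, nm, smoothWindow = smoothWindow)
  } else stop("unknown feature: ", feature)
  W <- 2L * halfwidth + 1L
  prof <- matrix(NA_real_, nrow = length(pos), ncol = W)
  for (i in seq_along(pos)) {
    seqi <- substr(chr[[ctg[i]]], pos[i] - halfwidth, pos[i] + halfwidth)
    if (st[i] == "-") seqi <- revcompStr(seqi)
    prof[i, ] <- featFun(seqi)
  }
  offsets <- seq(-halfwidth, halfwidth)
  colnames(prof) <- offsets
  n <- colSums(!is.na(prof))
  m <- ifelse(n > 0, colMeans(prof, na.rm = TRUE), NA_real_)
  list(profiles = prof,
       mean = data.frame(offset = offsets, mean = m, n = n),
       offsets = offsets)
}
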