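# Independent reference implementations used to verify the package's
# optimized code paths. These deliberately use different algorithms.

# Greedy caller: literal iterative masking over the global maximum.
oracleGreedy <- function(valsList, exclusion, keepFraction = 1) {
  vals <- lapply(valsList, function(v) { v[is.na(v)] <- 0; v })
  rec <- data.frame(ci = integer(0), pos = integer(0), score = numeric(0))
  repeat {
    best <- NULL
    for (ci in seq_along(vals)) {
      v <- vals[[ci]]
      if (!length(v)) next
      m <- max(v)
      if (m > 0 && (is.null(best) || m > best$m)) {
        best <- list(ci = ci, pos = which(v == m)[1L], m = m)
      }
    }
    if (is.null(best)) break
    rec <- rbind(rec, data.frame(ci = best$ci, pos = best$pos,
                                 score = best$m))
    v <- vals[[best$ci]]
    lo <- max(1L, best$pos - exclusion)
    hi <- min(length(v), best$pos + exclusion)
    v[lo:hi] <- -Inf
    vals[[best$ci]] <- v
  }
  if (nrow(rec) == 0L) return(rec)
  keep <- head(order(-rec$score, rec$ci, rec$pos),
               ceiling(keepFraction * nrow(rec)))
  rec <- rec[keep, , drop = FALSE]
  rec[order(rec$ci, rec$pos), , drop = FALSE]
}

# Rigidity: per start position, extend right as long as the substring
# still matches A^nT^m; every position of the longest valid extension is
# a candidate for that length.
oracleRigidity <- function(s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  L <- length(ch)
  score <- integer(L)
  for (i in seq_len(L)) {
    inT <- FALSE
    j <- i
    jmax <- i - 1L
    while (j <= L) {
      if (ch[j] == "A" && !inT) {
      } else if (ch[j] == "T") {
        inT <- TRUE
      } else break
      jmax <- j
      j <- j + 1L
    }
    len <- jmax - i + 1L
    if (len >= 2L)
      score[i:jmax] <- pmax(score[i:jmax], len)
  }
  score
}

# Interval union by brute-force per-bp mask.
oracleDyadUnion <- function(dyads1based, enlarge, L) {
  mask <- logical(L)
  half <- enlarge %/% 2L
  for (d in dyads1based) {
    lo <- max(1L, d - half)
    hi <- min(L, d + half - 1L)
    mask[lo:hi] <- TRUE
  }
  r <- rle(mask)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  data.frame(start = s[r$values], end = e[r$values])
}

# Composite profile without normalization: plain loop over anchors.
oracleComposite <- function(vals, ctg, pos, str, halfwidth) {
  W <- 2L * halfwidth + 1L
  M <- matrix(NA_real_, length(pos), W)
  for (i in seq_along(pos)) {
    v <- vals[[ctg[i]]]
    idx <- (pos[i] - halfwidth):(pos[i] + halfwidth)
    ok <- idx >= 1L & idx <= length(v)
    row <- rep(NA_real_, W)
    row[ok] <- v[idx[ok]]
    if (str[i] == "-") row <- rev(row)
    M[i, ] <- row
  }
  colMeans(M, na.rm = TRUE)
}

revcompChr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "",
                     fixed = TRUE)[[1L]]), collapse = "")
}
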