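test_that("Gaussian smoothing preserves mass and kernel shape", {
  g <- nucGenome(c(t1 = strrep("A", 1001)))
  x <- numeric(1001); x[501] <- 1
  sm <- trackValues(gaussianSmooth(trackOf(t1 = x)))$t1
  expect_equal(sum(sm), 1, tolerance = 1e-12)       # interior impulse
  expect_equal(sm[501] / sm[526], exp(0.5), tolerance = 1e-12)
  # constant input stays constant in the interior
  cm <- trackValues(gaussianSmooth(trackOf(t1 = rep(2, 400))))$t1
  expect_equal(cm[100:300], rep(2, 201), tolerance = 1e-12)
  expect_error(gaussianSmooth(trackOf(t1 = x), sd = 0), "sd")
})

test_that("greedy calling masks the exclusion zone and keeps top calls", {
  # peaks at 0-based 50 (5), 120 (4), 300 (3); exclusion 120 masks 120
  x <- numeric(500)
  x[c(51, 121, 301)] <- c(5, 4, 3)
  calls <- greedyCall(trackOf(t1 = x), exclusion = 120, keepFraction = 1)
  expect_equal(BiocGenerics::start(calls), c(51L, 301L))
  expect_equal(calls$score, c(5, 3))
  # single impulse -> single call
  y <- numeric(300); y[150] <- 1
  expect_equal(length(greedyCall(trackOf(t1 = y))), 1L)
  # all-zero track -> empty call set
  expect_equal(length(greedyCall(trackOf(t1 = numeric(300)))), 0L)
})

test_that("keep fraction retains ceiling(0.9 n) calls, ties by coordinate", {
  x <- numeric(3000)
  pos <- seq(100, 2800, by = 300)  # 10 impulses, equal priority
  x[pos] <- 1
  calls <- greedyCall(trackOf(t1 = x), exclusion = 120, keepFraction = 0.9)
  expect_equal(length(calls), 9L)
  expect_equal(BiocGenerics::start(calls), pos[1:9])
})

test_that("greedy calling matches the iterative-masking oracle", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(200:2000, 1)
    v <- numeric(n)
    k <- sample(5:40, 1)
    v[sample(n, k)] <- sample(1:5, k, TRUE)  # integer values force ties
    keep <- sample(c(1, 0.9), 1)
    calls <- greedyCall(trackOf(t1 = v), exclusion = 120,
                        keepFraction = keep)
    ref <- oracleGreedy(list(t1 = v), exclusion = 120, keepFraction = keep)
    expect_equal(BiocGenerics::start(calls), ref$pos)
    expect_equal(calls$score, ref$score)
    if (length(calls) > 1)
      expect_gt(min(diff(BiocGenerics::start(calls))), 120)
  }
})

test_that("greedy calling is globally consistent across contigs", {
  set.seed(5)
  vs <- list(t1 = numeric(800), t2 = numeric(600))
  vs$t1[sample(800, 12)] <- sample(1:4, 12, TRUE)
  vs$t2[sample(600, 9)] <- sample(1:4, 9, TRUE)
  calls <- greedyCall(nucposlab:::newBpTrack(vs), keepFraction = 0.9)
  ref <- oracleGreedy(vs, exclusion = 120, keepFraction = 0.9)
  expect_equal(as.character(GenomeInfoDb::seqnames(calls)),
               names(vs)[ref$ci])
  expect_equal(BiocGenerics::start(calls), ref$pos)
})

test_that("FFT low-pass keeps retained components exactly", {
  N <- 4096L
  i <- seq_len(N) - 1L
  x <- cos(2 * pi * 5 * i / N)          # frequency 5 of up to 40 kept
  xf <- fftLowpass(x, pcKeepComp = 0.02)
  expect_lt(max(abs(xf - x)) / max(abs(x)), 1e-9)
  # a component beyond the cutoff is removed entirely
  hi <- cos(2 * pi * 300 * i / N)
  expect_lt(max(abs(fftLowpass(hi, 0.02))), 1e-9)
})

test_that("FFT calling finds cosine crests and nothing on constants", {
  N <- 10000L
  i <- seq_len(N) - 1L
  x <- 1 + cos(2 * pi * 5 * (i - 1000) / N)  # crests at 0-based 1000 + 2000k
  calls <- fftCall(trackOf(t1 = x, provenance = "trimmed"))
  expect_equal(BiocGenerics::start(calls), c(1001L, 3001L, 5001L,
                                             7001L, 9001L))
  flat <- trackOf(t1 = rep(1, 10000), provenance = "trimmed")
  expect_equal(length(fftCall(flat)), 0L)
  expect_error(fftCall(trackOf(t1 = numeric(8))), "16")
})

test_that("+1/-1 annotation follows the 0..500 window and upstream rule", {
  # + gene, TSS 0-based 500; calls 0-based {480, 560, 900}
  calls <- anchorsAt("t1", c(481L, 561L, 901L))
  genes <- anchorsAt("t1", 501L, "+", id = "g1")
  ann <- annotatePlus1Minus1(calls, genes)
  expect_equal(ann$plus1_dyad, 561L)
  expect_equal(ann$minus1_dyad, 481L)
  expect_equal(ann$ndr_length, 80L)
  # - gene mirror: +1 is the call 20 bp downstream in gene orientation
  genesM <- anchorsAt("t1", 501L, "-", id = "g1")
  annM <- annotatePlus1Minus1(anchorsAt("t1", c(481L, 561L)), genesM)
  expect_equal(annM$plus1_dyad, 481L)
  expect_equal(annM$minus1_dyad, 561L)
  expect_equal(annM$ndr_length, 80L)
  # no candidate inside the window -> undefined
  annNA <- annotatePlus1Minus1(anchorsAt("t1", 1101L), genes)
  expect_true(is.na(annNA$plus1_dyad))
  expect_true(is.na(annNA$ndr_length))
})

test_that("+1/-1 annotation is translation invariant", {
  set.seed(3)
  cpos <- sort(sample(1000:4000, 25))
  calls <- anchorsAt("t1", cpos)
  genes <- anchorsAt("t1", c(1500L, 2500L), c("+", "-"),
                     id = c("g1", "g2"))
  a0 <- annotatePlus1Minus1(calls, genes)
  sh <- 10000L
  a1 <- annotatePlus1Minus1(anchorsAt("t1", cpos + sh),
                            anchorsAt("t1", c(1500L, 2500L) + sh,
                                      c("+", "-"), id = c("g1", "g2")))
  expect_equal(a1$plus1_dyad - sh, a0$plus1_dyad)
  expect_equal(a1$minus1_dyad - sh, a0$minus1_dyad)
  expect_equal(a1$ndr_length, a0$ndr_length)
})
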