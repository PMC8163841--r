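test_that("joint dyad regions enlarge, join, and filter by border", {
  g <- nucGenome(c(t1 = strrep("A", 2000)))
  # dyads 0-based 100 (sample A) and 105 (sample B) -> joined [90, 115)
  a <- anchorsAt("t1", 101L)
  b <- anchorsAt("t1", 106L)
  reg <- buildJointDyadSet(list(A = a, B = b), g, borderExclusion = 0)
  expect_equal(length(reg), 1L)
  expect_equal(BiocGenerics::start(reg) - 1L, 90L)  # 0-based start
  expect_equal(BiocGenerics::end(reg), 115L)        # 0-based end (half-open)
  # single dyad, no filters -> [90, 110)
  reg1 <- buildJointDyadSet(list(A = a), g, borderExclusion = 0)
  expect_equal(c(BiocGenerics::start(reg1) - 1L, BiocGenerics::end(reg1)),
               c(90L, 110L))
  # a dyad 240 bp from the tile border is removed at exclusion 250
  regB <- buildJointDyadSet(list(A = anchorsAt("t1", 241L)), g)
  expect_equal(length(regB), 0L)
  # blacklist removal and odd enlargement rejection
  bl <- GenomicRanges::GRanges("t1", IRanges::IRanges(100, 105))
  expect_equal(length(buildJointDyadSet(list(A = a), g,
                                        borderExclusion = 0,
                                        blacklist = bl)), 0L)
  expect_error(buildJointDyadSet(list(A = a), g, enlarge = 15), "even")
})

test_that("joint dyad regions match a per-bp mask union oracle", {
  set.seed(21)
  g <- nucGenome(c(t1 = strrep("A", 3000)))
  for (rep in 1:40) {
    dy <- sort(sample(300:2700, sample(2:25, 1)))
    reg <- buildJointDyadSet(list(A = anchorsAt("t1", dy)), g,
                             borderExclusion = 0)
    ref <- oracleDyadUnion(dy, 20L, 3000L)
    expect_equal(BiocGenerics::start(reg), ref$start)
    expect_equal(BiocGenerics::end(reg), ref$end)
  }
})

test_that("center counting respects region membership", {
  g <- nucGenome(c(t1 = strrep("A", 1000)))
  reg <- GenomicRanges::GRanges("t1", IRanges::IRanges(91, 115))
  # width-1 fragments are their own centers: 0-based {92, 114, 200}
  fr <- fragmentsAt("t1", c(93L, 115L, 201L), c(93L, 115L, 201L))
  x <- countCenters(reg, list(s1 = fr))
  expect_equal(unname(x[1, 1]), 2L)
  expect_true(sum(x) <= length(fr))
})

test_that("occupancy normalization follows the exact log2 formula", {
  expect_equal(normalizeOccupancy(matrix(c(0L, 10L), 2))[1, 1],
               log2(0.001))
  x <- matrix(c(1L, 999L), 2)  # sum 1000, x = 1
  expect_equal(normalizeOccupancy(x)[1, 1], log2(1.001))
  xAll <- matrix(c(500L, 0L), 2)  # one region holds all counts
  expect_equal(normalizeOccupancy(xAll)[1, 1], log2(1000.001))
  m <- matrix(c(1L, 0L, 0L, 0L), 2, dimnames = list(NULL, c("a", "bad")))
  expect_error(normalizeOccupancy(m), "bad")
})

test_that("normalization identity holds on random count matrices", {
  set.seed(9)
  for (rep in 1:20) {
    x <- matrix(rpois(80, 5), 20, 4)
    x[1, ] <- x[1, ] + 1L  # ensure non-zero columns
    v <- normalizeOccupancy(x)
    resid <- colSums(2^v) - nrow(x) * 0.001
    expect_equal(resid, rep(1000, 4), tolerance = 1e-6)
    # strictly monotone in x at fixed sample total
    expect_equal(rank(v[, 1]), rank(x[, 1]))
  }
})

test_that("PCA centers variables and decomposes exactly", {
  set.seed(2)
  a <- rnorm(50)
  v <- cbind(s1 = a, s2 = -a + 3)        # perfectly anti-correlated
  p <- pcaRegions(v)
  expect_equal(p$explainedVariance[1], 1, tolerance = 1e-12)
  # reconstruction from all components reproduces the centered matrix
  v2 <- matrix(rnorm(200), 50, 4)
  p2 <- pcaRegions(v2)
  rec <- p2$scores %*% t(p2$loadings)
  expect_equal(rec, scale(v2, scale = FALSE), tolerance = 1e-9,
               ignore_attr = TRUE)
  # sign convention: largest-magnitude loading is positive
  expect_true(all(apply(p2$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))
  expect_error(pcaRegions(v2[, 1, drop = FALSE]), "2 samples")
})

test_that("k-means recovers planted clouds and is seed-reproducible", {
  set.seed(4)
  X <- rbind(matrix(rnorm(60, 0, 0.1), 30),
             matrix(rnorm(60, 10, 0.1), 30))
  lab <- kmeansRegions(X, k = 2, seed = 1)
  truth <- rep(1:2, each = 30)
  expect_equal(mclust::adjustedRandIndex(lab, truth), 1)
  # bit-identical reproducibility given (seed, nRestarts)
  expect_identical(lab, kmeansRegions(X, k = 2, seed = 1))
  # row permutation gives the identical partition after renumbering
  perm <- sample(nrow(X))
  labP <- kmeansRegions(X[perm, ], k = 2, seed = 1)
  expect_equal(mclust::adjustedRandIndex(labP, truth[perm]), 1)
  expect_equal(unname(kmeansRegions(X, k = 1, seed = 1)[1:60]),
               rep(1L, 60))
  expect_error(kmeansRegions(X[1:3, ], k = 8, seed = 1), "exceeds")
})

test_that("cluster summaries average, z-score and order clusters", {
  v <- rbind(c(1, 0), c(3, 0), c(2, 2), c(2, 2))
  labels <- c(1L, 1L, 2L, 2L)
  s <- clusterSummary(labels, v)
  expect_equal(unname(s$clusterScores[1, ]), c(2, 0))
  expect_equal(unname(s$rowScaled[2, ]), c(0, 0))  # zero-variance row
  # z-score of the (2, 0) row with sd over n-1: +/- 1/sqrt(2)
  expect_equal(unname(s$rowScaled[1, ]), c(1, -1) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(sort(s$clusterOrder), 1:2)
})
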