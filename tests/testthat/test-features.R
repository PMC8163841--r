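allPentamers <- function() {
  b <- c("A", "C", "G", "T")
  apply(expand.grid(b, b, b, b, b), 1, paste, collapse = "")
}

toyTable <- function(values) {
  v <- setNames(rep(0, 1024), allPentamers())
  v[names(values)] <- values
  list(toy = v)
}

test_that("shape profiles look up centered pentamers then smooth", {
  tab <- toyTable(c(AAAAA = -10))
  raw <- shapeProfile("GGAAAAAGG", tab, "toy", smoothWindow = 1)
  expect_equal(raw, c(NA, NA, 0, 0, -10, 0, 0, NA, NA))
  sm <- shapeProfile("GGAAAAAGG", tab, "toy", smoothWindow = 5)
  expect_equal(sm[5], -2)                  # mean of (0, 0, -10, 0, 0)
  expect_true(all(is.na(sm[c(1:4, 6:9)]))) # undefined propagation
  expect_true(all(is.na(shapeProfile("ACGT", tab, "toy"))))
  expect_error(shapeProfile("ACGTA", tab, "missing"), "unknown feature")
  # N-containing pentamers are undefined
  withN <- shapeProfile("GGAANAAGG", tab, "toy", smoothWindow = 1)
  expect_true(all(is.na(withN[3:7])))
})

test_that("rigidity scores A(n)T(m) elements", {
  expect_equal(rigidityProfile("AAATTT"), rep(6L, 6))
  expect_equal(rigidityProfile("TA"), c(0L, 0L))    # TpA step disallowed
  expect_equal(rigidityProfile("GAAC"), c(0L, 2L, 2L, 0L))
  expect_equal(rigidityProfile("AT"), c(2L, 2L))
  expect_equal(rigidityProfile("TTAA"), c(2L, 2L, 2L, 2L))
  expect_equal(rigidityProfile("NAAN"), c(0L, 2L, 2L, 0L))
})

test_that("rigidity equals the substring-enumeration oracle", {
  set.seed(31)
  for (rep in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(5:60, 1), TRUE,
                      prob = c(0.35, 0.15, 0.15, 0.35)), collapse = "")
    expect_identical(rigidityProfile(s), oracleRigidity(s))
  }
})

test_that("rigidity respects G/C padding and reverse-complement symmetry", {
  set.seed(32)
  for (rep in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    r <- rigidityProfile(s)
    # appending/prepending G or C leaves existing scores unchanged
    expect_identical(rigidityProfile(paste0("G", s, "C"))[2:41], r)
    # A^nT^m maps to A^mT^n under reverse complement
    expect_identical(rigidityProfile(revcompChr(s)), rev(r))
  }
})

test_that("poly(dA)/poly(dT) hexamer coverage counts overlapping matches", {
  pa <- polyATCoverage(strrep("A", 7))$polyA
  expect_equal(pa, c(1, 2, 2, 2, 2, 2, 1))
  expect_equal(polyATCoverage(strrep("A", 7), mode = "binary")$polyA,
               rep(1, 7))
  expect_equal(polyATCoverage("ACACAC")$polyA, rep(0, 6))
  expect_equal(polyATCoverage("ACACAC")$polyT, rep(0, 6))
  tt <- polyATCoverage(paste0("GG", strrep("T", 6), "GG"))$polyT
  expect_equal(tt, c(0, 0, rep(1, 6), 0, 0))
  # coverage within a maximal run of length r sums to k * (r - k + 1)
  set.seed(33)
  for (r in 6:12) {
    s <- paste0("C", strrep("A", r), "C")
    expect_equal(sum(polyATCoverage(s)$polyA), 6 * (r - 6 + 1))
  }
})

test_that("window features are oriented and averaged per offset", {
  g <- nucGenome(c(t1 = paste0(strrep("G", 20), "AAATTT", strrep("G", 20)),
                   t2 = strrep("C", 46)))
  # + anchor at the element start, halfwidth 5
  aP <- anchorsAt("t1", 21L, "+")
  wf <- windowFeatures(g, aP, halfwidth = 5, feature = "rigidity")
  expect_equal(unname(wf$profiles[1, ]), c(0, 0, 0, 0, 0, 6, 6, 6, 6, 6, 6))
  # - anchor sees the reverse complement, reversed
  aM <- anchorsAt("t1", 21L, "-")
  wfM <- windowFeatures(g, aM, halfwidth = 5, feature = "rigidity")
  # first column is offset -5 = genomic position 26 on the - strand
  expect_equal(unname(wfM$profiles[1, ]),
               as.numeric(rigidityProfile(revcompChr(substr(
                 as.character(genomeSeqs(g)[["t1"]]), 16, 26)))))
  expect_equal(unname(wfM$profiles[1, ]), c(6, 6, 6, 6, 6, 6, 0, 0, 0, 0, 0))
  # identical windows: mean equals the single-window profile
  aa <- anchorsAt("t1", c(21L, 21L), c("+", "+"))
  wf2 <- windowFeatures(g, aa, halfwidth = 5, feature = "rigidity")
  expect_equal(wf2$mean$mean, unname(wf2$profiles[1, ]))
  expect_equal(unique(wf2$mean$n), 2L)
  # out-of-range anchors are dropped; none surviving is an error
  expect_message(windowFeatures(g, anchorsAt("t1", c(21L, 2L)),
                                halfwidth = 5, feature = "rigidity"),
                 "dropped")
  expect_error(suppressMessages(
    windowFeatures(g, anchorsAt("t1", 2L), halfwidth = 5,
                   feature = "rigidity")), "no anchors")
})

test_that("shape profiles of reverse-complement-closed tables mirror", {
  set.seed(34)
  pent <- allPentamers()
  v <- rnorm(1024)
  names(v) <- pent
  rc <- vapply(pent, revcompChr, character(1))
  v <- (v + v[rc]) / 2                      # force value(p) = value(rc(p))
  tab <- list(sym = v)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    p <- shapeProfile(s, tab, "sym", smoothWindow = 1)
    pr <- shapeProfile(revcompChr(s), tab, "sym", smoothWindow = 1)
    expect_equal(pr, rev(p))
  }
})
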