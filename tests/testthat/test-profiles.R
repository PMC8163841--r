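test_that("composite profiles normalize per anchor and orient windows", {
  v <- rep(2, 3000)
  tr <- trackOf(t1 = v)
  a <- anchorsAt("t1", c(1000L, 2000L))
  cp <- compositeProfile(tr, a, halfwidth = 100)
  expect_equal(unique(cp$mean), 1)          # self-normalization
  expect_equal(unique(cp$n), 2L)
  # impulse 10 bp downstream of a + anchor peaks at offset +10
  v2 <- numeric(3000); v2[1011] <- 5; v2[1:3000] <- v2[1:3000] + 1
  tr2 <- trackOf(t1 = v2)
  cpP <- compositeProfile(tr2, anchorsAt("t1", 1001L, "+"),
                          halfwidth = 50, perAnchorNorm = FALSE)
  expect_equal(cpP$offset[which.max(cpP$mean)], 10)
  cpM <- compositeProfile(tr2, anchorsAt("t1", 1001L, "-"),
                          halfwidth = 50, perAnchorNorm = FALSE)
  expect_equal(cpM$offset[which.max(cpM$mean)], -10)
  # zero-mean windows are dropped; none surviving is an error
  z <- trackOf(t1 = numeric(3000))
  expect_error(suppressMessages(
    compositeProfile(z, a, halfwidth = 100)), "no surviving")
})

test_that("unnormalized composites equal the naive window mean", {
  set.seed(41)
  vals <- list(t1 = runif(2000), t2 = runif(1500))
  tr <- nucposlab:::newBpTrack(vals)
  ctg <- sample(c("t1", "t2"), 20, TRUE)
  pos <- sample(300:1200, 20)
  str <- sample(c("+", "-"), 20, TRUE)
  a <- GenomicRanges::GRanges(ctg, IRanges::IRanges(pos, pos),
                              strand = str)
  cp <- compositeProfile(tr, a, halfwidth = 150, perAnchorNorm = FALSE)
  expect_equal(cp$mean, unname(oracleComposite(vals, ctg, pos, str, 150)))
})

test_that("heatmap rows sort by key descending with id tie-break", {
  tr <- trackOf(t1 = seq_len(5000) * 1.0)
  a <- anchorsAt("t1", c(1000L, 2000L, 3000L),
                 id = c("g1", "g2", "g3"))
  M <- heatmapMatrix(tr, a, halfwidth = 10, sortKeys = c(5, 9, 5))
  expect_equal(rownames(M), c("g2", "g1", "g3"))
  expect_message(M2 <- heatmapMatrix(tr, a, halfwidth = 10,
                                     sortKeys = c(5, NA, 5)),
                 "missing sort key")
  expect_equal(nrow(M2), 2L)
})

test_that("upstream signal scoring uses the 120-bp window 160 bp upstream", {
  # + strand +1 dyad at 0-based 1000 -> window 0-based [720, 840)
  v <- numeric(2000)
  v[721:840] <- 1                      # exactly the expected window
  tr <- trackOf(t1 = v)
  a <- anchorsAt("t1", 1001L, "+")
  expect_equal(reb1Score(tr, a), 1)
  # mass just outside the window does not contribute
  v2 <- numeric(2000); v2[720] <- 120; v2[841] <- 120
  expect_equal(reb1Score(trackOf(t1 = v2), a), 0)
  # impulse of mass 120 inside the window -> mean 1
  v3 <- numeric(2000); v3[800] <- 120
  expect_equal(reb1Score(trackOf(t1 = v3), a), 1)
  # uniform signal scores 1 everywhere, both strands
  u <- trackOf(t1 = rep(1, 2000))
  aM <- anchorsAt("t1", 1001L, "-")
  expect_equal(reb1Score(u, c(a, aM)), c(1, 1))
  # window outside the contig -> NA with a message
  expect_message(sc <- reb1Score(tr, anchorsAt("t1", 100L, "+")),
                 "outside")
  expect_true(is.na(sc))
  expect_equal(selectTopFraction(c(3, 1, 2, NA, 5), 0.25),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("promoter grouping follows PWM strand and bidirectionality", {
  # + gene with +1 at 0-based 1000, Reb1 hit 100 bp upstream
  plus1 <- data.frame(gene_id = "g1", contig = "t1", strand = "+",
                      tss = 941L, plus1_dyad = 1001L,
                      minus1_dyad = NA_integer_, ndr_length = NA_integer_)
  hit <- anchorsAt("t1", 901L)
  pwmP <- anchorsAt("t1", 905L, "+")
  expect_equal(groupPromoters(hit, pwmP, plus1)$group, 1L)
  pwmM <- anchorsAt("t1", 905L, "-")
  expect_equal(groupPromoters(hit, pwmM, plus1)$group, 2L)
  # divergent gene pair sharing the site -> group 3 for both
  plus2 <- rbind(plus1, data.frame(gene_id = "g2", contig = "t1",
                                   strand = "-", tss = 761L,
                                   plus1_dyad = 701L,
                                   minus1_dyad = NA_integer_,
                                   ndr_length = NA_integer_))
  gp <- groupPromoters(hit, pwmP, plus2)
  expect_equal(sort(gp$gene_id), c("g1", "g2"))
  expect_equal(gp$group, c(3L, 3L))
  # hits beyond 400 bp upstream or without a PWM are not grouped
  farHit <- anchorsAt("t1", 401L)
  expect_equal(nrow(groupPromoters(farHit, pwmP, plus1)), 0L)
  expect_equal(nrow(groupPromoters(hit, anchorsAt("t1", 2000L, "+"),
                                   plus1)), 0L)
})

test_that("+1 distance statistics are signed downstream-positive", {
  vivo <- data.frame(gene_id = c("g1", "g2"), contig = "t1",
                     strand = c("+", "-"), tss = c(1L, 1L),
                     plus1_dyad = c(1000L, 1000L),
                     minus1_dyad = NA_integer_, ndr_length = NA_integer_)
  vitro <- vivo
  st <- plus1DistanceStats(vitro, vivo)
  expect_equal(st$median, 0)
  expect_equal(st$iqr, 0)
  expect_equal(st$n, 2L)
  vitro$plus1_dyad <- c(1010L, 1010L)
  st2 <- plus1DistanceStats(vitro, vivo)
  expect_equal(sort(st2$distances$distance), c(-10, 10))
  expect_error(plus1DistanceStats(vitro,
                                  transform(vivo, gene_id = c("x", "y"))),
               "shared")
})

test_that("dyad densities integrate to one and are depth invariant", {
  counts <- numeric(5000)
  counts[c(1000, 2000, 3000)] <- 4      # dyads exactly at the anchors
  tr <- trackOf(t1 = counts)
  a <- anchorsAt("t1", c(1000L, 2000L, 3000L))
  dd <- dyadDensity(tr, a, halfwidth = 100, bin = 5)
  expect_equal(sum(dd$density * dd$width), 1, tolerance = 1e-9)
  occupied <- dd$bin_mid[dd$count > 0]
  expect_length(occupied, 1L)
  expect_true(abs(occupied - 0) <= 2.5)
  # uniform dyads -> flat density; doubling depth changes nothing
  u <- trackOf(t1 = rep(2, 5000))
  du <- dyadDensity(u, a, halfwidth = 100, bin = 5)
  expect_equal(unique(round(du$density, 12)),
               round(1 / 201, 12))
  d2 <- dyadDensity(trackOf(t1 = rep(4, 5000)), a, halfwidth = 100,
                    bin = 5)
  expect_equal(du$density, d2$density)
  expect_error(dyadDensity(trackOf(t1 = numeric(5000)), a,
                           halfwidth = 100), "no dyads")
})
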