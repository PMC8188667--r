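genome <- makeGenome(c(c1 = 100000, c2 = 100000))

## reads placed one per `per` bp across [lo0, hi0)
denseReads <- function(chrom, lo0, hi0, per, genome, width = 50) {
  starts <- seq(lo0, hi0 - width, by = per)
  bedRanges(rep(chrom, length(starts)), starts, starts + width, genome)
}

test_that("callIslands chains eligible windows across at most `gap` holes", {
  ## 50 reads in windows 3 and 7 over an empty background; the three
  ## empty windows between them are bridged by gap = 3
  r <- c(denseReads("c1", 10000, 15000, 100, genome),
         denseReads("c1", 30000, 35000, 100, genome))
  isl <- callIslands(r, genome, window = 5000, gap = 3, level = 0.01)
  expect_equal(bedFrame(isl), data.frame(chrom = "c1", start = 10000,
                                         end = 35000))
  ## four empty windows between them -> two islands
  r2 <- c(denseReads("c1", 10000, 15000, 100, genome),
          denseReads("c1", 35000, 40000, 100, genome))
  isl2 <- callIslands(r2, genome, window = 5000, gap = 3, level = 0.01)
  expect_equal(nrow(bedFrame(isl2)), 2)
  expect_error(callIslands(GRanges(seqinfo = genome), genome), "reads")
})

test_that("callIslands keeps the eligible-window false-positive rate at the level", {
  set.seed(21)
  ## uniform background at about 25 reads per 5-kb window
  n <- 1000
  starts <- floor(runif(n) * 99900)
  r <- bedRanges(rep("c1", n), starts, starts + 100,
                 makeGenome(c(c1 = 1e5)))
  isl <- callIslands(r, makeGenome(c(c1 = 1e5)), window = 5000, gap = 0,
                     level = 1e-2)
  ## 20 windows at level 1e-2: expected eligible < 0.2, allow a couple
  expect_lte(sum(width(isl)) / 5000, 3)
})

deltaTracks <- function(delta, genome, bw = 5000) {
  E <- BinnedTrack(genome, bw, list(c1 = delta,
                                    c2 = numeric(ceiling(100000 / bw))),
                   units = "RPM")
  B <- BinnedTrack(genome, bw, units = "RPM")
  list(E = E, B = B)
}

wholeGenomeIslands <- function(genome)
  GRanges(seqnames(genome), IRanges(1, seqlengths(genome)),
          seqinfo = genome)

test_that("callEBPeaks reproduces the seed-and-extend hand trace", {
  delta <- c(-0.1, 0.1, 0.4, 0.2, 0.5, 0.1, 0.05, -0.2,
             rep(-1, 12))
  tr <- deltaTracks(delta, genome)
  pk <- callEBPeaks(tr$E, tr$B, wholeGenomeIslands(genome))
  ## bins 2-7 (1-based) = BED [5000, 35000), 30 kb > 20 kb
  expect_equal(bedFrame(pk), data.frame(chrom = "c1", start = 5000,
                                        end = 35000))
  expect_equal(mcols(pk)$score, 0.5)
})

test_that("callEBPeaks drops short regions and sub-threshold signal", {
  ## no bin exceeds the seed threshold
  tr <- deltaTracks(c(rep(0.25, 10), rep(-1, 10)), genome)
  expect_length(callEBPeaks(tr$E, tr$B, wholeGenomeIslands(genome)), 0)

  ## isolated seed bin: 5-kb region, discarded by the > 20 kb rule
  d <- rep(-1, 20); d[5] <- 0.6
  tr2 <- deltaTracks(d, genome)
  expect_length(callEBPeaks(tr2$E, tr2$B, wholeGenomeIslands(genome)), 0)

  ## exactly 20 kb (4 bins) is not > 20 kb
  d3 <- rep(-1, 20); d3[5:8] <- c(0.4, 0.4, 0.4, 0.4)
  tr3 <- deltaTracks(d3, genome)
  expect_length(callEBPeaks(tr3$E, tr3$B, wholeGenomeIslands(genome)), 0)

  ## 25 kb (5 bins) passes
  d4 <- rep(-1, 20); d4[5:9] <- 0.4
  tr4 <- deltaTracks(d4, genome)
  expect_length(callEBPeaks(tr4$E, tr4$B, wholeGenomeIslands(genome)), 1)
})

test_that("callEBPeaks enforces island containment", {
  d <- rep(-1, 20); d[3:8] <- 0.4           # 30-kb region [10000,40000)
  tr <- deltaTracks(d, genome)
  ## island covering only 10 kb of the region: 1/3 < 50% -> dropped
  smallIsland <- bedRanges("c1", 10000, 20000, genome)
  expect_length(callEBPeaks(tr$E, tr$B, smallIsland), 0)
  ## but kept in "any"-overlap mode
  expect_length(callEBPeaks(tr$E, tr$B, smallIsland, islandMode = "any"), 1)
  ## island covering 20 kb: 2/3 >= 50% -> kept
  bigIsland <- bedRanges("c1", 10000, 30000, genome)
  expect_length(callEBPeaks(tr$E, tr$B, bigIsland), 1)
})

test_that("callEBPeaks output bins are positive with at least one seed, maximal", {
  set.seed(5)
  for (i in 1:10) {
    delta <- round(rnorm(20, 0, 0.3), 3)
    tr <- deltaTracks(delta, genome)
    pk <- callEBPeaks(tr$E, tr$B, wholeGenomeIslands(genome),
                      minLength = 0)
    for (j in seq_along(pk)) {
      bins <- (start(pk[j]) - 1) / 5000 + seq_len(width(pk[j]) / 5000)
      expect_true(all(delta[bins] > 0))
      expect_true(any(delta[bins] > 0.3))
      ## maximality: adjacent bins are non-positive or absent
      lo <- min(bins) - 1; hi <- max(bins) + 1
      if (lo >= 1) expect_lte(delta[lo], 0)
      if (hi <= 20) expect_lte(delta[hi], 0)
    }
  }
})

test_that("reproduciblePeaks keeps supported peaks and unions them", {
  a <- bedRanges(c("c1", "c1"), c(0, 50000), c(30000, 70000), genome)
  expect_equal(bedFrame(reproduciblePeaks(list(a, a))), bedFrame(a))

  rep1 <- bedRanges(c("c1", "c2"), c(0, 0), c(30000, 10000), genome)
  rep2 <- bedRanges("c1", 25000, 60000, genome)
  out <- reproduciblePeaks(list(rep1, rep2))
  ## c2 peak unsupported; c1 peaks union to [0, 60000)
  expect_equal(bedFrame(out), data.frame(chrom = "c1", start = 0,
                                         end = 60000))
  expect_error(reproduciblePeaks(list(rep1)), "replicate")
})

test_that("callPoissonPeaks applies scan, fold, merge, size and exclusion rules", {
  set.seed(8)
  gsc <- makeGenome(c(c1 = 2e6))
  bg <- denseReads("c1", 0, 2e6, 10000, gsc)   # 0.1 reads/kb background
  ## two dense 4-kb blocks, gap 9.5 kb: each ~100 reads/kb
  p1 <- denseReads("c1", 100000, 104000, 10, gsc)
  p2 <- denseReads("c1", 113500, 117500, 10, gsc)
  pk <- callPoissonPeaks(c(bg, p1, p2), gsc, mergeGap = 10000,
                         minSize = 10000)
  expect_equal(nrow(bedFrame(pk)), 1)
  expect_lte(abs(start(pk) - 100001), 1500)
  expect_gte(end(pk), 117000)
  expect_gte(mcols(pk)$fold, 400)

  ## same two blocks with mergeGap 5 kb: two 4-kb peaks, both < minSize
  pk2 <- callPoissonPeaks(c(bg, p1, p2), gsc, mergeGap = 5000,
                          minSize = 10000)
  expect_length(pk2, 0)

  ## a 100x block fails the 400-fold filter
  weak <- denseReads("c1", 500000, 512000, 100, gsc)  # 10 reads/kb
  pk3 <- callPoissonPeaks(c(bg, weak), gsc)
  expect_length(pk3, 0)
})

test_that("callPoissonPeaks removes excluded chromosomes and blacklist hits", {
  gsc <- makeGenome(c(c1 = 1e6, chrY = 1e6))
  bg <- c(denseReads("c1", 0, 1e6, 10000, gsc),
          denseReads("chrY", 0, 1e6, 10000, gsc))
  hot1 <- denseReads("c1", 100000, 112000, 20, gsc)
  hotY <- denseReads("chrY", 100000, 112000, 20, gsc)
  pk <- callPoissonPeaks(c(bg, hot1, hotY), gsc)
  expect_identical(unique(as.character(seqnames(pk))), "c1")

  bl <- bedRanges("c1", 110000, 115000, gsc)
  pk2 <- callPoissonPeaks(c(bg, hot1, hotY), gsc, blacklist = bl)
  expect_length(pk2, 0)
})

test_that("defineErizs partitions peaks and labels timing", {
  hu <- bedRanges(c("c1", "c1"), c(0, 50000), c(20000, 80000), genome)
  eb <- bedRanges("c1", 10000, 30000, genome)
  res <- defineErizs(hu, eb)
  expect_length(erizs(res), 1)
  expect_length(nonErizs(res), 1)
  expect_identical(bedFrame(sort(c(erizs(res), nonErizs(res)))),
                   bedFrame(sort(hu)))
  expect_identical(mcols(erizs(res))$timingClass, "unknown")

  ## empty E-B set: everything non-ERIZ
  res2 <- defineErizs(hu, GRanges(seqinfo = genome))
  expect_length(erizs(res2), 0)
  expect_length(nonErizs(res2), 2)

  ## constant timing 0.6 -> all early
  tim <- BinnedTrack(genome, 5000,
                     list(c1 = rep(0.6, 20), c2 = rep(0.6, 20)),
                     units = "timing")
  res3 <- defineErizs(hu, eb, timing = tim)
  expect_identical(mcols(erizs(res3))$timingClass, "early")
  expect_identical(mcols(nonErizs(res3))$timingClass, "early")
  expect_equal(mcols(erizs(res3))$timing, 0.6)
})

test_that("scoreRecovery measures recall, precision and per-zone Jaccard", {
  zones <- bedRanges(c("c1", "c1"), c(0, 50000), c(20000, 70000), genome)
  called <- bedRanges(c("c1", "c1"), c(0, 80000), c(20000, 90000), genome)
  sc <- scoreRecovery(called, zones)
  expect_equal(sc$recall, 0.5)
  expect_equal(sc$precision, 0.5)
  expect_equal(sc$meanJaccard, 1)
  sc2 <- scoreRecovery(bedRanges("c1", 10000, 20000, genome),
                       bedRanges("c1", 0, 20000, genome))
  expect_equal(sc2$meanJaccard, 0.5)
})
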