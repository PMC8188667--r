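genome <- makeGenome(c(c1 = 500000))

geneSet <- function(starts, ends, pd, rpk, strand = NULL) {
  g <- bedRanges(rep("c1", length(starts)), starts, ends, genome,
                 gene_id = sprintf("g%02d", seq_along(starts)),
                 promoter_density = pd, body_rpk = rpk)
  if (!is.null(strand)) strand(g) <- strand
  g
}

test_that("classifyGenes applies the human and mouse activity rules", {
  g <- geneSet(c(0, 100000, 200000), c(50000, 150000, 250000),
               pd = c(0.5, 0, 0), rpk = c(4.1, 1.0, 2))
  h <- classifyGenes(g, "human")
  expect_identical(mcols(h)$activity,
                   c("active", "silent", "intermediate"))
  ## boundaries: RPK exactly 4 is not active; RPK exactly 1 is silent
  g2 <- geneSet(c(0, 100000), c(50000, 150000), pd = c(1, 0),
                rpk = c(4, 1))
  expect_identical(mcols(classifyGenes(g2, "human"))$activity,
                   c("intermediate", "silent"))
  m <- classifyGenes(geneSet(c(0, 100000, 200000),
                             c(50000, 150000, 250000),
                             pd = c(0, 0, 0), rpk = c(1.5, 0, 0.5)),
                     "mouse")
  expect_identical(mcols(m)$activity,
                   c("active", "silent", "intermediate"))
  expect_error(classifyGenes(bedRanges("c1", 0, 100, genome)), "columns")
})

test_that("defineNonTR keeps gaps flanked by two active genes", {
  comp <- bedRanges("c1", 0, 300000, genome)
  ## two active genes 50 kb apart, one silent gene elsewhere
  g <- geneSet(c(50000, 150000, 260000), c(100000, 200000, 280000),
               pd = c(1, 1, 0), rpk = c(10, 10, 0))
  g <- classifyGenes(g, "human")
  ntr <- defineNonTR(g, comp)
  expect_equal(bedFrame(ntr), data.frame(chrom = "c1", start = 100000,
                                         end = 150000))
  expect_identical(mcols(ntr)$upstreamGene, "g01")
  expect_identical(mcols(ntr)$downstreamGene, "g02")
  expect_equal(mcols(ntr)$midpoint, 125000)

  ## width filter: 150-kb gap excluded
  gWide <- classifyGenes(geneSet(c(50000, 250000), c(100000, 290000),
                                 pd = c(1, 1), rpk = c(10, 10)), "human")
  expect_length(defineNonTR(gWide, comp), 0)
  expect_length(defineNonTR(gWide, comp, widthRange = NULL), 1)

  ## no active genes -> no flanked gaps
  gSil <- classifyGenes(geneSet(50000, 100000, pd = 0, rpk = 0), "human")
  expect_length(defineNonTR(gSil, comp), 0)

  ## ERIZ overlap filter
  eriz <- bedRanges("c1", 120000, 130000, genome)
  expect_length(defineNonTR(g, comp, erizs = eriz), 1)
  farEriz <- bedRanges("c1", 280000, 290000, genome)
  expect_length(defineNonTR(g, comp, erizs = farEriz), 0)
})

test_that("non-TRs never overlap active gene bodies", {
  set.seed(11)
  comp <- bedRanges("c1", 0, 500000, genome)
  starts <- sort(sample(seq(0, 450000, by = 1000), 8))
  ends <- pmin(starts + sample(20000:40000, 8), 500000)
  keep <- c(TRUE, diff(starts) > 42000)
  g <- classifyGenes(geneSet(starts[keep], ends[keep],
                             pd = rep(1, sum(keep)),
                             rpk = rep(10, sum(keep))), "human")
  ntr <- defineNonTR(g, comp, widthRange = NULL)
  if (length(ntr))
    expect_false(any(overlapsAny(ntr, g[mcols(g)$activity == "active"])))
})

test_that("densityLog2Ratio recovers planted density contrasts", {
  comp <- bedRanges("c1", 0, 300000, genome)
  g <- classifyGenes(geneSet(c(50000, 150000), c(100000, 200000),
                             pd = c(1, 1), rpk = c(10, 10)), "human")
  ntr <- defineNonTR(g, comp)
  ## 4 reads/kb in the non-TR, 1 read/kb in the flanks
  rNtr <- bedRanges(rep("c1", 199), seq(100250, 149750, by = 250),
                    seq(100300, 149800, by = 250), genome)
  rTr <- bedRanges(rep("c1", 99),
                   c(seq(50500, 99500, by = 1000),
                     seq(150500, 198500, by = 1000)),
                   c(seq(50550, 99550, by = 1000),
                     seq(150550, 198550, by = 1000)), genome)
  out <- densityLog2Ratio(c(rNtr, rTr), ntr, g, pseudocount = 0)
  expect_equal(nrow(out), 1)
  expect_equal(out$log2_ratio, 2, tolerance = 0.05)

  ## antisymmetry under swapping region and flank densities
  swapped <- log2(out$d_tr / out$d_nontr)
  expect_equal(swapped, -out$log2_ratio)

  ## all reads in flanks with a pseudocount: large negative but finite
  out2 <- densityLog2Ratio(rTr, ntr, g)
  expect_true(is.finite(out2$log2_ratio))
  expect_lt(out2$log2_ratio, 0)
})

test_that("rankSumTest matches exact enumeration and handles degeneracy", {
  r <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p.value, 0.1)           # 2/20 arrangements as extreme
  expect_equal(r$statistic, 0)

  same <- rankSumTest(c(5, 5, 5), c(5, 5))
  expect_equal(same$p.value, 1)

  set.seed(13)
  for (i in 1:5) {
    x <- round(rnorm(6), 4); y <- round(rnorm(7) + 0.5, 4)
    expect_equal(rankSumTest(x, y)$p.value, bfWilcoxExact(x, y),
                 tolerance = 1e-10)
  }
  ## same multiset split differently: p = 1 within tolerance
  expect_gte(rankSumTest(c(1, 4, 2, 3), c(2.5, 1.5, 3.5, 2.2))$p.value, 0.5)
})

test_that("heatmapMatrix aligns midpoint rows and orders by width", {
  gH <- makeGenome(c(c1 = 1e6))
  const <- BinnedTrack(gH, 1000, list(c1 = rep(3, 1000)), units = "score")
  regions <- bedRanges(c("c1", "c1"), c(400000, 600000),
                       c(480000, 620000), gH)
  m <- heatmapMatrix(const, regions, mode = "midpoint", flank = 100000)
  expect_equal(dim(m), c(2, 200))
  expect_true(all(m == 3))
  ## rows ordered by increasing width: the 20-kb region first
  expect_equal(attr(m, "order"), c(2, 1))

  ## a delta at a region's midpoint lights the central columns
  v <- rep(0, 1000); v[501] <- 100      # bin [500000, 501000)
  spike <- BinnedTrack(gH, 1000, list(c1 = v), units = "score")
  reg <- bedRanges("c1", 460000, 540000, gH)   # midpoint 500000
  m2 <- heatmapMatrix(spike, reg, mode = "midpoint", flank = 100000)
  expect_equal(which(m2[1, ] > 0), 101)

  ## off-chromosome columns are NA
  edge <- bedRanges("c1", 0, 40000, gH)
  m3 <- heatmapMatrix(const, edge, mode = "midpoint", flank = 100000)
  expect_true(anyNA(m3[1, 1:50]))
})

test_that("heatmapMatrix scaled mode aligns TSS/TTS and flips minus strand", {
  gH <- makeGenome(c(c1 = 1e6))
  ## signal high only inside the gene body
  v <- rep(0, 1000); v[301:400] <- 5    # [300000, 400000)
  tr <- BinnedTrack(gH, 1000, list(c1 = v), units = "score")
  gene <- bedRanges("c1", 300000, 400000, gH)
  strand(gene) <- "+"
  m <- heatmapMatrix(tr, gene, mode = "scaled", flank = 50000,
                     bodyBins = 100)
  expect_equal(ncol(m), 200)
  expect_true(all(m[1, 51:150] == 5))
  expect_true(all(m[1, c(1:50, 151:200)] == 0))

  ## minus-strand gene with signal near its TTS (left edge) is flipped
  v2 <- rep(0, 1000); v2[301:310] <- 7
  tr2 <- BinnedTrack(gH, 1000, list(c1 = v2), units = "score")
  gm <- gene; strand(gm) <- "-"
  mp <- heatmapMatrix(tr2, gene, mode = "scaled")
  mm <- heatmapMatrix(tr2, gm, mode = "scaled")
  expect_equal(mm[1, ], rev(mp[1, ]))
})
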