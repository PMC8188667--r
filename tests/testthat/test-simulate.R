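smallCfg <- simConfig(chromLengths = c(chrS1 = 1e7, chrS2 = 1e7),
                      nZones = 12L)

test_that("generateTruth is deterministic and respects placement rules", {
  t1 <- generateTruth(smallCfg, seed = 3)
  t2 <- generateTruth(smallCfg, seed = 3)
  expect_identical(bedFrame(plantedZones(t1)), bedFrame(plantedZones(t2)))
  expect_identical(bedFrame(truthGenes(t1)), bedFrame(truthGenes(t2)))

  zones <- plantedZones(t1)
  expect_length(zones, 12)
  expect_true(isDisjoint(zones))
  ## zones live entirely inside A compartments...
  expect_equal(fractionWidthIn(zones, compartments(t1, "A")), 1)
  ## ...and never touch active gene bodies
  act <- truthGenes(t1)[mcols(truthGenes(t1))$activity == "active"]
  expect_false(any(overlapsAny(zones, act)))

  ## A and B partition each chromosome
  both <- reduce(c(granges(compartments(t1, "A")),
                   granges(compartments(t1, "B"))))
  expect_equal(sum(width(both)), sum(seqlengths(t1@genome)))

  expect_error(generateTruth(simConfig(nZones = 10000L), seed = 1),
               "infeasible")
})

test_that("stored gene densities reproduce the activity labels", {
  t1 <- generateTruth(smallCfg, seed = 8)
  relabelled <- classifyGenes(truthGenes(t1), "human")
  expect_identical(mcols(relabelled)$activity,
                   mcols(truthGenes(t1))$activity)
})

test_that("perturbation mode relocates zones into active gene bodies", {
  cfgP <- simConfig(chromLengths = c(chrS1 = 1e7, chrS2 = 1e7),
                    nZones = 12L, perturbFraction = 0.5)
  tp <- generateTruth(cfgP, seed = 4)
  zones <- plantedZones(tp)
  moved <- mcols(zones)$relocated
  expect_equal(sum(moved), 6)
  act <- truthGenes(tp)[mcols(truthGenes(tp))$activity == "active"]
  expect_true(all(overlapsAny(zones[moved], act)))
  expect_false(any(overlapsAny(zones[!moved], act)))
})

test_that("dual-label simulation has the promised signal structure", {
  truth <- generateTruth(smallCfg, seed = 5)
  dl <- simulateDualLabel(truth, seed = 50)
  dl2 <- simulateDualLabel(truth, seed = 50)
  expect_identical(bedFrame(dl$edu), bedFrame(dl2$edu))

  cfg <- truth@config
  nBins <- sum(ceiling(seqlengths(truth@genome) / cfg$ebBinWidth))
  nZoneBp <- sum(width(plantedZones(truth)))
  expEdu <- cfg$ebBackgroundPerBin * nBins +
    cfg$ebZoneExcessPerBin * nZoneBp / cfg$ebBinWidth
  expect_lt(abs(length(dl$edu) - expEdu) / expEdu, 0.05)
  expect_lt(abs(length(dl$brdu) - expEdu) / expEdu, 0.05)

  ## per-zone maximum delta-EB beats the seed threshold for >=95% of zones
  E <- normalizeTrack(binReads(dl$edu, truth@genome, cfg$ebBinWidth),
                      "RPM", libSize = cfg$rpmDenominator)
  B <- normalizeTrack(binReads(dl$brdu, truth@genome, cfg$ebBinWidth),
                      "RPM", libSize = cfg$rpmDenominator)
  maxDelta <- vapply(seq_along(plantedZones(truth)), function(i) {
    z <- plantedZones(truth)[i]
    chr <- as.character(seqnames(z))
    bins <- ((start(z) - 1) %/% cfg$ebBinWidth + 1):
      ((end(z) - 1) %/% cfg$ebBinWidth + 1)
    max(trackValues(E)[[chr]][bins] - trackValues(B)[[chr]][bins])
  }, numeric(1))
  expect_gte(mean(maxDelta > 0.3), 0.95)
})

test_that("EdU/HU simulation concentrates reads on zones at the set fold", {
  truth <- generateTruth(smallCfg, seed = 6)
  hu <- simulateEduHu(truth, seed = 60)
  zones <- plantedZones(truth)
  inZones <- sum(countOverlaps(zones, hu))
  zoneDens <- inZones / sum(width(zones))
  bgDens <- (length(hu) - inZones) /
    (sum(seqlengths(truth@genome)) - sum(width(zones)))
  ## zone density over the out-of-zone background approximates the
  ## configured 1000x fold; comfortably above the 400-fold filter
  expect_gt(zoneDens / bgDens, 400)

  ## zero zones -> essentially background only
  cfg0 <- simConfig(chromLengths = c(chrS1 = 1e7, chrS2 = 1e7),
                    nZones = 0L)
  hu0 <- simulateEduHu(generateTruth(cfg0, seed = 6), seed = 60)
  expect_lt(length(hu0), 3000)
})

test_that("marker and timing simulation matches the planted geometry", {
  truth <- generateTruth(smallCfg, seed = 7)
  mk <- simulateMarkers(truth, seed = 70)
  expect_named(mk$markers, c("posMarker", "negMarker"))
  ## timing above 0.5 over every planted zone -> all labelled early
  tv <- meanOver(mk$timing, plantedZones(truth))
  expect_true(all(tv > 0.5))
  ## marker peaks are enriched in their target territory relative to
  ## that territory's share of the genome
  act <- truthGenes(truth)[mcols(truthGenes(truth))$activity == "active"]
  posIn <- mean(overlapsAny(mk$markers$posMarker, plantedZones(truth)))
  negIn <- mean(overlapsAny(mk$markers$negMarker, act))
  zoneFrac <- sum(width(plantedZones(truth))) / sum(seqlengths(truth@genome))
  actFrac <- sum(width(reduce(act))) / sum(seqlengths(truth@genome))
  expect_gt(posIn, 3 * zoneFrac)
  expect_gt(negIn, 2 * actFrac)
})

test_that("written simulations round-trip through the package readers", {
  dir <- withr::local_tempdir()
  truth <- generateTruth(smallCfg, seed = 9)
  mk <- simulateMarkers(truth, seed = 90)
  writeSimulation(truth, dir, assays = list(timing = mk$timing,
                                            posMarker = mk$markers$posMarker),
                  seed = 9)
  genome <- readChromSizes(file.path(dir, "genome.chrom.sizes"))
  expect_identical(seqlengths(genome), seqlengths(truth@genome))
  zones <- readBed(file.path(dir, "zones.bed"), genome)
  expect_identical(bedFrame(zones), bedFrame(plantedZones(truth)))
  genes <- readGeneTable(file.path(dir, "genes.tsv"), genome)
  expect_identical(bedFrame(genes), bedFrame(truthGenes(truth)))
  expect_equal(mcols(genes)$body_rpk,
               mcols(truthGenes(truth))$body_rpk, tolerance = 1e-6)
  timing <- readBedGraph(file.path(dir, "timing.bedGraph"), genome,
                         smallCfg$timingBinWidth)
  expect_equal(unlist(trackValues(timing)),
               unlist(trackValues(mk$timing)), tolerance = 1e-6)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 9)
  ## deposited-style zone tables read back through the schema reader
  erizTab <- readErizTable(file.path(dir, "zones.bed"))
  expect_equal(length(erizTab), length(plantedZones(truth)))
})

test_that("a single seed recovers planted zones end to end", {
  cfg <- simConfig()
  truth <- generateTruth(cfg, seed = 14)
  dl1 <- simulateDualLabel(truth, seed = 141)
  dl2 <- simulateDualLabel(truth, seed = 142)
  hu <- simulateEduHu(truth, seed = 143)
  res <- runErizPipeline(list(dl1$edu, dl2$edu), list(dl1$brdu, dl2$brdu),
                         hu, truth@genome,
                         rpmLibSize = cfg$rpmDenominator)
  sc <- scoreRecovery(erizs(res$erizResult), plantedZones(truth))
  expect_gte(sc$recall, 0.9)
  expect_gte(sc$precision, 0.9)
  expect_gte(sc$meanJaccard, 0.7)
})
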