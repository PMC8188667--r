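## Synthetic-data generator: a toy genome with A/B compartments,
## genes, planted early-initiation zones confined to non-transcribed
## gaps between active genes, and per-assay read sets with the signal
## structure each caller assumes.  Everything is deterministic under
## (config, seed).

#' Configuration of the synthetic study
#'
#' Defaults describe the study conditions the generator emulates: two
#' 20-Mb chromosomes segmented into alternating A/B compartments
#' (1.5-2.5 Mb segments), genes laid down densely inside A
#' compartments (70-120 kb bodies, 60-130 kb intergenic gaps, so
#' transcribed bp dominate A territory as they do in real active
#' compartments), 70% of genes active, and 40 planted initiation
#' zones (log-normal widths, median about 70 kb) confined to the
#' non-transcribed intergenic gaps.
#' Dual-label tracks are scaled to a fixed 1e8-read RPM denominator so
#' per-bin RPM values sit on the genome-scale footing the 0.3-RPM seed
#' threshold assumes; see the methods vignette for the reasoning
#' behind each default.
#'
#' @param chromLengths Named numeric vector of chromosome lengths.
#' @param compartmentRange Uniform range of compartment segment
#'   lengths in bp.
#' @param geneLengthRange,gapRange Uniform ranges of gene-body and
#'   intergenic-gap lengths in bp.
#' @param activeFraction Fraction of genes labelled active.
#' @param nZones Number of planted initiation zones.
#' @param zoneWidthMeanLog,zoneWidthSdLog Log-normal width parameters
#'   (defaults give median ~70 kb).
#' @param zoneMargin Minimum clearance between a zone and its
#'   flanking genes in bp.
#' @param perturbFraction Fraction of zones relocated into active
#'   gene bodies (the transcription-perturbation mode).
#' @param ebBinWidth Dual-label bin width in bp.
#' @param ebBackgroundPerBin Expected background reads per 5-kb bin
#'   per label.
#' @param ebZoneExcessPerBin Expected extra first-label reads per
#'   zone bin.
#' @param brduOffset Outward displacement of the second-label
#'   elongation flanks in bp.
#' @param rpmDenominator Fixed library-size denominator for RPM
#'   tracks.
#' @param readLength Fragment length in bp.
#' @param eduhuBackgroundPerKb Background EdU/HU read rate per kb.
#' @param eduhuZoneFold Zone read density over background (default
#'   1000, so the 400-fold filter is exercised from both sides).
#' @param timingBinWidth,timingNoiseSd Replication-timing track grid
#'   and noise.
#' @param markerPeakWidth,markerProb,markerPeaksPerSite,markerBackgroundCount
#'   Marker-peak geometry: co-location probability, peaks per chosen
#'   site, and uniformly placed background peaks per marker.
#' @param barrierBackgroundPerKb,barrierFold,barrierReplicates dCas9
#'   barrier simulation: uniform background rate, upstream pileup
#'   fold, replicate count.
#' @param replicates Dual-label biological replicates.
#' @return A validated named list.
#' @export
simConfig <- function(chromLengths = c(chrS1 = 2e7, chrS2 = 2e7),
                      compartmentRange = c(1.5e6, 2.5e6),
                      geneLengthRange = c(7e4, 1.2e5),
                      gapRange = c(6e4, 1.3e5),
                      activeFraction = 0.7,
                      nZones = 40L,
                      zoneWidthMeanLog = log(7e4),
                      zoneWidthSdLog = 0.25,
                      zoneMargin = 2000,
                      perturbFraction = 0,
                      ebBinWidth = 5000L,
                      ebBackgroundPerBin = 20,
                      ebZoneExcessPerBin = 100,
                      brduOffset = 25000,
                      rpmDenominator = 1e8,
                      readLength = 150L,
                      eduhuBackgroundPerKb = 0.05,
                      eduhuZoneFold = 1000,
                      timingBinWidth = 5000L,
                      timingNoiseSd = 0.05,
                      markerPeakWidth = 2000L,
                      markerProb = 0.8,
                      markerPeaksPerSite = 2L,
                      markerBackgroundCount = 100L,
                      barrierBackgroundPerKb = 5,
                      barrierFold = 5,
                      barrierReplicates = 3L,
                      replicates = 2L) {
  cfg <- as.list(environment())
  rates <- c(cfg$ebBackgroundPerBin, cfg$ebZoneExcessPerBin,
             cfg$eduhuBackgroundPerKb, cfg$eduhuZoneFold,
             cfg$barrierBackgroundPerKb, cfg$barrierFold)
  if (any(rates < 0)) stop("rates must be non-negative")
  if (any(chromLengths <= 0)) stop("chromosome lengths must be positive")
  if (cfg$perturbFraction < 0 || cfg$perturbFraction > 1)
    stop("'perturbFraction' must be in [0, 1]")
  cfg
}

.simGenome <- function(cfg)
  GenomeInfoDb::Seqinfo(seqnames = names(cfg$chromLengths),
                        seqlengths = cfg$chromLengths)

## uniform reads of fixed length within [lo0, hi0) (BED coords)
.uniformReads <- function(n, chrom, lo0, hi0, readLen, genome) {
  if (n <= 0) return(GenomicRanges::GRanges(seqinfo = genome))
  span <- hi0 - lo0 - readLen
  if (span < 0) { readLen <- max(1, hi0 - lo0); span <- hi0 - lo0 - readLen }
  start0 <- lo0 + floor(runif(n) * (span + 1))
  GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start0 + 1, width = readLen), seqinfo = genome)
}

## Poisson numbers of uniform reads inside each of several regions
## (BED coords lo0/hi0), built as one GRanges
.regionReads <- function(mu, chrom, lo0, hi0, readLen, genome) {
  n <- rpois(length(mu), mu)
  idx <- rep(seq_along(mu), n)
  if (!length(idx)) return(GenomicRanges::GRanges(seqinfo = genome))
  span <- pmax(hi0[idx] - lo0[idx] - readLen, 0)
  start0 <- lo0[idx] + floor(runif(length(idx)) * (span + 1))
  GenomicRanges::GRanges(chrom[idx],
    IRanges::IRanges(start0 + 1, width = readLen), seqinfo = genome)
}

## uniform genome-wide background reads
.backgroundReads <- function(n, genome, readLen) {
  sl <- GenomeInfoDb::seqlengths(genome)
  chrom <- sample(names(sl), n, replace = TRUE, prob = sl / sum(sl))
  out <- lapply(names(sl), function(chr) {
    k <- sum(chrom == chr)
    .uniformReads(k, chr, 0, sl[[chr]], readLen, genome)
  })
  sort(do.call(c, out))
}

#' Generate the planted ground truth
#'
#' Builds the synthetic genome: alternating A/B compartments, genes
#' tiled through the A compartments with nascent-transcription
#' densities consistent with their activity labels, and `nZones`
#' disjoint initiation zones placed uniformly among the
#' non-transcribed intergenic gaps.  With `perturbFraction > 0` the
#' stated fraction of zones is relocated into active gene bodies,
#' emulating replication penetrating transcribed regions under
#' transcription inhibition.
#'
#' @param cfg A [simConfig()] list.
#' @param seed Integer seed; the truth is deterministic under
#'   `(cfg, seed)`.
#' @return A [SyntheticTruth-class].
#' @export
generateTruth <- function(cfg = simConfig(), seed = 1L) {
  genome <- .simGenome(cfg)
  withSeed(seed, {
    sl <- GenomeInfoDb::seqlengths(genome)
    compA <- list(); compB <- list()
    for (chr in names(sl)) {
      pos <- 0; isA <- TRUE
      while (pos < sl[[chr]]) {
        len <- runif(1, cfg$compartmentRange[1], cfg$compartmentRange[2])
        end <- min(pos + len, sl[[chr]])
        seg <- GenomicRanges::GRanges(chr,
          IRanges::IRanges(pos + 1, end), seqinfo = genome)
        if (isA) compA[[length(compA) + 1]] <- seg
        else compB[[length(compB) + 1]] <- seg
        pos <- end; isA <- !isA
      }
    }
    compA <- sort(do.call(c, compA)); compB <- sort(do.call(c, compB))

    gChr <- character(); gStart <- numeric(); gEnd <- numeric()
    gapList <- list()
    compChr <- as.character(GenomeInfoDb::seqnames(compA))
    for (i in seq_along(compA)) {
      chr <- compChr[i]
      cs <- BiocGenerics::start(compA)[i]; ce <- BiocGenerics::end(compA)[i]
      pos <- cs + round(runif(1, 1e4, 3e4))
      prevEnd <- NA_real_
      repeat {
        len <- round(runif(1, cfg$geneLengthRange[1], cfg$geneLengthRange[2]))
        if (pos + len > ce - 1e4) break
        gChr <- c(gChr, chr); gStart <- c(gStart, pos)
        gEnd <- c(gEnd, pos + len - 1)
        k <- length(gStart)
        if (!is.na(prevEnd))
          gapList[[length(gapList) + 1]] <-
            list(chrom = chr, start = prevEnd + 1, end = pos - 1,
                 left = k - 1L, right = k)
        prevEnd <- pos + len - 1
        pos <- pos + len + round(runif(1, cfg$gapRange[1], cfg$gapRange[2]))
      }
    }
    n <- length(gStart)
    genes <- GenomicRanges::GRanges(gChr, IRanges::IRanges(gStart, gEnd),
                                    strand = sample(c("+", "-"), n,
                                                    replace = TRUE),
                                    seqinfo = genome)
    S4Vectors::mcols(genes)$gene_id <- sprintf("gene%04d", seq_len(n))
    u <- runif(n)
    activity <- ifelse(u < cfg$activeFraction, "active",
                       ifelse(u < cfg$activeFraction +
                                (1 - cfg$activeFraction) / 2,
                              "silent", "intermediate"))
    pd <- ifelse(activity == "active", runif(n, 0.5, 5), 0)
    rpk <- ifelse(activity == "active", 4 + rexp(n, 1 / 6),
                  ifelse(activity == "silent", runif(n, 0, 1),
                         runif(n, 1.5, 3.5)))
    S4Vectors::mcols(genes)$promoter_density <- pd
    S4Vectors::mcols(genes)$body_rpk <- rpk
    S4Vectors::mcols(genes)$activity <- activity

    ## gaps eligible for zones: any intergenic gap with enough room
    ## (non-transcribed by construction; flank activity is irrelevant
    ## for placement and only filters the non-TR analysis later)
    elig <- Filter(function(g)
      (g$end - g$start + 1) - 2 * cfg$zoneMargin > 2e4, gapList)
    if (cfg$nZones > 0 && length(elig) < cfg$nZones)
      stop(sprintf("infeasible placement: %d zones requested, %d eligible gaps",
                   cfg$nZones, length(elig)))
    zones <- GenomicRanges::GRanges(seqinfo = genome)
    if (cfg$nZones > 0) {
      pick <- sample(length(elig), cfg$nZones)
      sel <- elig[pick]
      usable <- vapply(sel, function(g)
        (g$end - g$start + 1) - 2 * cfg$zoneMargin, numeric(1))
      w <- pmax(2e4, pmin(round(rlnorm(cfg$nZones, cfg$zoneWidthMeanLog,
                                       cfg$zoneWidthSdLog)), usable))
      s <- vapply(sel, `[[`, numeric(1), "start") + cfg$zoneMargin +
        floor(runif(cfg$nZones) * (usable - w + 1))
      zones <- sort(GenomicRanges::GRanges(
        vapply(sel, `[[`, character(1), "chrom"),
        IRanges::IRanges(s, s + w - 1), seqinfo = genome))
      S4Vectors::mcols(zones)$zone_id <-
        sprintf("zone%03d", seq_along(zones))
      S4Vectors::mcols(zones)$relocated <- FALSE
      if (cfg$perturbFraction > 0) {
        nMove <- round(cfg$perturbFraction * length(zones))
        if (nMove > 0) {
          mv <- sample(length(zones), nMove)
          act <- genes[activity == "active"]
          ## distinct host genes keep relocated zones pairwise disjoint
          hosts <- act[sample(length(act), nMove)]
          zChr <- as.character(GenomeInfoDb::seqnames(zones))
          zStart <- BiocGenerics::start(zones)
          zEnd <- BiocGenerics::end(zones)
          for (j in seq_along(mv)) {
            k <- mv[j]; host <- hosts[j]
            w <- min(zEnd[k] - zStart[k] + 1, BiocGenerics::width(host))
            s <- BiocGenerics::start(host) +
              floor(runif(1) * (BiocGenerics::width(host) - w + 1))
            zChr[k] <- as.character(GenomeInfoDb::seqnames(host))
            zStart[k] <- s; zEnd[k] <- s + w - 1
          }
          moved <- S4Vectors::mcols(zones)$relocated
          moved[mv] <- TRUE
          zones <- GenomicRanges::GRanges(zChr,
            IRanges::IRanges(zStart, zEnd), seqinfo = genome,
            zone_id = S4Vectors::mcols(zones)$zone_id, relocated = moved)
          zones <- sort(zones)
        }
      }
    }
    methods::new("SyntheticTruth", genome = genome, compartmentsA = compA,
                 compartmentsB = compB, genes = genes, zones = zones,
                 config = cfg)
  })
}

#' Simulate a dual-label (first/second label) replicate
#'
#' First-label reads pile up over the planted zones on top of a
#' uniform Poisson background; second-label reads carry the same
#' background plus elongation signal displaced outward into
#' `brduOffset`-wide flanks on both sides of each zone (initiation in
#' the middle, elongation moving outward).
#'
#' @param truth A [SyntheticTruth-class].
#' @param seed Replicate seed.
#' @return List with read `GRanges` elements `edu` and `brdu`.
#' @export
simulateDualLabel <- function(truth, seed = 1L) {
  cfg <- truth@config
  genome <- truth@genome
  sl <- GenomeInfoDb::seqlengths(genome)
  nBins <- sum(ceiling(sl / cfg$ebBinWidth))
  zones <- truth@zones
  withSeed(seed, {
    lab <- function(zoneReads) {
      bg <- .backgroundReads(rpois(1, cfg$ebBackgroundPerBin * nBins),
                             genome, cfg$readLength)
      sort(c(bg, zoneReads))
    }
    chrom <- as.character(GenomeInfoDb::seqnames(zones))
    zs0 <- BiocGenerics::start(zones) - 1; ze0 <- BiocGenerics::end(zones)
    mu <- cfg$ebZoneExcessPerBin * (ze0 - zs0) / cfg$ebBinWidth
    zoneE <- .regionReads(mu, chrom, zs0, ze0, cfg$readLength, genome)
    loL <- pmax(0, zs0 - cfg$brduOffset)
    hiR <- pmin(sl[chrom], ze0 + cfg$brduOffset)
    zoneB <- c(
      .regionReads(mu / 2, chrom, loL, zs0, cfg$readLength, genome),
      .regionReads(mu / 2, chrom, ze0, hiR, cfg$readLength, genome))
    list(edu = lab(zoneE), brdu = lab(zoneB))
  })
}

#' Simulate an EdU/HU (stalled-fork) read set
#'
#' Reads concentrate on the planted zones at `eduhuZoneFold` times the
#' sparse uniform background rate.
#'
#' @param truth A [SyntheticTruth-class].
#' @param seed Replicate seed.
#' @return Read `GRanges`.
#' @export
simulateEduHu <- function(truth, seed = 1L) {
  cfg <- truth@config
  genome <- truth@genome
  sl <- GenomeInfoDb::seqlengths(genome)
  withSeed(seed, {
    bg <- .backgroundReads(
      rpois(1, cfg$eduhuBackgroundPerKb * sum(sl) / 1e3),
      genome, cfg$readLength)
    zones <- truth@zones
    mu <- cfg$eduhuZoneFold * cfg$eduhuBackgroundPerKb *
      as.numeric(BiocGenerics::width(zones)) / 1e3
    sort(c(bg, .regionReads(mu, as.character(GenomeInfoDb::seqnames(zones)),
                            BiocGenerics::start(zones) - 1,
                            BiocGenerics::end(zones),
                            cfg$readLength, genome)))
  })
}

#' Simulate marker peak sets and the replication-timing track
#'
#' The positive marker drops peaks inside planted zones with
#' probability `markerProb` per zone; the negative marker does the
#' same inside active gene bodies; both add uniformly placed
#' background peaks.  The timing track is high (about 0.8) over A
#' compartments and low (about 0.2) over B, plus Gaussian noise, so
#' zones inherit early timing.
#'
#' @param truth A [SyntheticTruth-class].
#' @param seed Seed.
#' @return List with `markers` (named list of peak `GRanges`:
#'   `posMarker`, `negMarker`) and `timing` (a [BinnedTrack-class]).
#' @export
simulateMarkers <- function(truth, seed = 1L) {
  cfg <- truth@config
  genome <- truth@genome
  withSeed(seed, {
    dropPeaks <- function(sites) {
      sel <- sites[runif(length(sites)) < cfg$markerProb]
      idx <- rep(seq_along(sel), each = cfg$markerPeaksPerSite)
      pk <- if (length(idx)) {
        lo0 <- BiocGenerics::start(sel)[idx] - 1
        span <- pmax(BiocGenerics::end(sel)[idx] - lo0 -
                       cfg$markerPeakWidth, 0)
        s0 <- lo0 + floor(runif(length(idx)) * (span + 1))
        GenomicRanges::GRanges(
          as.character(GenomeInfoDb::seqnames(sel))[idx],
          IRanges::IRanges(s0 + 1, width = cfg$markerPeakWidth),
          seqinfo = genome)
      } else GenomicRanges::GRanges(seqinfo = genome)
      bg <- .backgroundReads(cfg$markerBackgroundCount, genome,
                             cfg$markerPeakWidth)
      sort(c(bg, pk))
    }
    act <- truth@genes[
      S4Vectors::mcols(truth@genes)$activity == "active"]
    ## negative marker emulates broad elongation-mark domains: the
    ## chosen active gene bodies themselves, not point peaks inside
    ## them (zones are gene-adjacent, so point peaks would not deplete)
    negSel <- GenomicRanges::granges(act)[runif(length(act)) <
                                            cfg$markerProb]
    negBg <- .backgroundReads(cfg$markerBackgroundCount, genome,
                              cfg$markerPeakWidth)
    markers <- list(posMarker = dropPeaks(truth@zones),
                    negMarker = sort(c(negSel, negBg)))

    timing <- BinnedTrack(genome, cfg$timingBinWidth, units = "timing")
    vals <- timing@values
    for (chr in names(vals)) {
      n <- length(vals[[chr]])
      mid <- GenomicRanges::GRanges(chr, IRanges::IRanges(
        pmin((seq_len(n) - 1) * cfg$timingBinWidth +
               cfg$timingBinWidth %/% 2 + 1,
             GenomeInfoDb::seqlengths(genome)[[chr]]), width = 1))
      inA <- IRanges::overlapsAny(mid, truth@compartmentsA,
                                        ignore.strand = TRUE)
      v <- ifelse(inA, 0.8, 0.2) + rnorm(n, 0, cfg$timingNoiseSd)
      vals[[chr]] <- pmin(pmax(v, 0.01), 0.99)
    }
    list(markers = markers, timing = methods::initialize(timing,
                                                         values = vals))
  })
}

#' Simulate dCas9 transcription-barrier replicates
#'
#' Chooses a designated active gene, anchors the barrier at its
#' midpoint, and emits replicate read sets: a uniform genome-wide
#' background, plus, in `"blocked"` mode, a pileup over the 2-kb
#' window immediately upstream of the barrier (in the direction
#' transcription arrives from) at `barrierFold` times background.
#' `"scramble"` mode omits the pileup.
#'
#' @param truth A [SyntheticTruth-class].
#' @param seed Seed.
#' @param mode `"blocked"` or `"scramble"`.
#' @return List with `replicates` (list of read `GRanges`), `chrom`,
#'   `center`, `upstreamSide`, `gene_id`, `mode`.
#' @export
simulateBarrier <- function(truth, seed = 1L,
                            mode = c("blocked", "scramble")) {
  mode <- match.arg(mode)
  cfg <- truth@config
  genome <- truth@genome
  sl <- GenomeInfoDb::seqlengths(genome)
  act <- truth@genes[S4Vectors::mcols(truth@genes)$activity == "active"]
  act <- act[BiocGenerics::width(act) >= 2e4]
  if (length(act) == 0L) stop("no active gene wide enough for a barrier")
  gene <- act[which.max(BiocGenerics::width(act))]
  center <- (BiocGenerics::start(gene) + BiocGenerics::end(gene)) %/% 2L
  chrom <- as.character(GenomeInfoDb::seqnames(gene))
  upstreamSide <- if (as.character(GenomicRanges::strand(gene)) == "-")
    "right" else "left"
  withSeed(seed, {
    reps <- lapply(seq_len(cfg$barrierReplicates), function(r) {
      bg <- .backgroundReads(
        rpois(1, cfg$barrierBackgroundPerKb * sum(sl) / 1e3),
        genome, cfg$readLength)
      if (mode == "scramble") return(bg)
      lo0 <- if (upstreamSide == "left") center - 2000L - 1L
             else center - 1L
      extra <- rpois(1, (cfg$barrierFold - 1) *
                       cfg$barrierBackgroundPerKb * 2)
      sort(c(bg, .uniformReads(extra, chrom, lo0, lo0 + 2000L,
                               cfg$readLength, genome)))
    })
    list(replicates = reps, chrom = chrom, center = center,
         upstreamSide = upstreamSide,
         gene_id = S4Vectors::mcols(gene)$gene_id, mode = mode)
  })
}

#' Write a synthetic data set to plain-text files
#'
#' Emits zones/compartments/genes as BED/TSV, read sets as BED,
#' the timing track as bedGraph, marker peaks as BED, and a manifest
#' JSON recording the configuration and seeds.  Every file round-trips
#' through the package's own readers.
#'
#' @param truth A [SyntheticTruth-class].
#' @param dir Output directory (created if needed).
#' @param assays Optional named list of extra `GRanges` read sets /
#'   tracks to write: elements named `*.bed` are written as BED,
#'   `BinnedTrack`s as bedGraph.
#' @param seed Seed recorded in the manifest.
#' @return Invisibly, the manifest path.
#' @export
writeSimulation <- function(truth, dir, assays = list(), seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeChromSizes(truth@genome, p("genome.chrom.sizes"))
  writeBed(truth@zones, p("zones.bed"))
  writeBed(truth@compartmentsA, p("compartments_A.bed"))
  writeBed(truth@compartmentsB, p("compartments_B.bed"))
  writeGeneTable(truth@genes, p("genes.tsv"))
  for (nm in names(assays)) {
    x <- assays[[nm]]
    if (methods::is(x, "BinnedTrack"))
      writeBedGraph(x, p(paste0(nm, ".bedGraph")))
    else writeBed(x, p(paste0(nm, ".bed")))
  }
  manifest <- list(package = "repliZones", seed = seed,
                   config = truth@config[!vapply(truth@config, is.function,
                                                 logical(1))])
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(p("manifest.json"))
}
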