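## The core callers: broad EdU islands (SICER-style window/gap
## chaining), the delta-EB seed-and-extend dual-label caller with
## replicate support, the global-rate Poisson scan with fold-change
## filtering for EdU/HU hotspots, and the ERIZ definition.

#' Call broad enrichment islands from reads
#'
#' A window/gap island caller in the SICER spirit: fixed-width windows
#' whose read count is Poisson-improbable against the genome-wide rate
#' become eligible, and eligible windows separated by at most `gap`
#' ineligible windows are chained into one island.
#'
#' @param reads `GRanges` of reads.
#' @param genome `Seqinfo`.
#' @param window Window width in bp (default 5 kb).
#' @param gap Maximum number of ineligible windows bridged inside an
#'   island (default 3).
#' @param level Per-window significance level against the global
#'   Poisson rate (default 0.01).
#' @return `GRanges` of islands, spanning the first to last eligible
#'   window of each chain.
#' @export
callIslands <- function(reads, genome, window = 5000L, gap = 3L,
                        level = 0.01) {
  track <- binReads(reads, genome, window)
  counts <- unlist(track@values, use.names = FALSE)
  total <- sum(counts)
  if (total == 0) stop("no reads: island rate undefined")
  lambda <- total / length(counts)
  sl <- GenomeInfoDb::seqlengths(genome)
  out <- lapply(names(track@values), function(chr) {
    v <- track@values[[chr]]
    elig <- which(ppois(v - 1, lambda, lower.tail = FALSE) < level)
    if (!length(elig)) return(GenomicRanges::GRanges(seqinfo = genome))
    grp <- cumsum(c(1L, diff(elig) > gap + 1L))
    first <- tapply(elig, grp, min); last <- tapply(elig, grp, max)
    GenomicRanges::GRanges(chr,
      IRanges::IRanges((first - 1) * window + 1,
                       pmin(last * window, sl[[chr]])),
      seqinfo = genome)
  })
  sort(do.call(c, out))
}

#' Call E-B peaks by delta-EB seed and extend
#'
#' The dual-label caller.  On the shared 5-kb RPM grid the per-bin
#' difference `delta = E - B` is computed; bins with
#' `delta > seedThreshold` seed regions that are extended through
#' contiguous neighbours with `delta > extendThreshold` (strict).
#' Regions longer than `minLength` (strict) that fall inside the EdU
#' islands are returned.
#'
#' @param E,B RPM-normalized `BinnedTrack`s (first and second label).
#' @param islands `GRanges` of broad EdU islands from [callIslands()].
#' @param seedThreshold Seed cutoff on delta (RPM units, default 0.3).
#' @param extendThreshold Extension cutoff (default 0, exclusive).
#' @param minLength Minimum peak length in bp (default 20 kb,
#'   exclusive).
#' @param islandMode `"fraction"` keeps a region when at least
#'   `minIslandCover` of its length is covered by islands; `"any"`
#'   keeps regions with any island overlap.
#' @param minIslandCover Coverage fraction for `islandMode =
#'   "fraction"` (default 0.5).
#' @return `GRanges` of peaks with metadata column `score` (maximum
#'   delta in the peak).
#' @export
callEBPeaks <- function(E, B, islands, seedThreshold = 0.3,
                        extendThreshold = 0, minLength = 20000,
                        islandMode = c("fraction", "any"),
                        minIslandCover = 0.5) {
  islandMode <- match.arg(islandMode)
  if (!identical(GenomeInfoDb::seqlengths(E@genome),
                 GenomeInfoDb::seqlengths(B@genome)) ||
      binWidth(E) != binWidth(B))
    stop("E and B tracks are on different grids")
  if (seedThreshold <= extendThreshold)
    stop("'seedThreshold' must exceed 'extendThreshold'")
  bw <- as.numeric(binWidth(E))
  sl <- GenomeInfoDb::seqlengths(E@genome)
  peaks <- lapply(names(E@values), function(chr) {
    delta <- E@values[[chr]] - B@values[[chr]]
    pos <- delta > extendThreshold
    r <- rle(pos)
    endIdx <- cumsum(r$lengths)
    startIdx <- endIdx - r$lengths + 1L
    runs <- which(r$values)
    if (!length(runs)) return(GenomicRanges::GRanges(seqinfo = E@genome))
    keep <- vapply(runs, function(k)
      any(delta[startIdx[k]:endIdx[k]] > seedThreshold), logical(1))
    runs <- runs[keep]
    if (!length(runs)) return(GenomicRanges::GRanges(seqinfo = E@genome))
    GenomicRanges::GRanges(chr,
      IRanges::IRanges((startIdx[runs] - 1) * bw + 1,
                       pmin(endIdx[runs] * bw, sl[[chr]])),
      score = vapply(runs, function(k)
        max(delta[startIdx[k]:endIdx[k]]), numeric(1)),
      seqinfo = E@genome)
  })
  peaks <- sort(do.call(c, peaks))
  peaks <- peaks[BiocGenerics::width(peaks) > minLength]
  if (length(peaks) == 0L) return(peaks)
  inIsland <- if (islandMode == "any") {
    IRanges::overlapsAny(peaks, islands, ignore.strand = TRUE)
  } else {
    isl <- GenomicRanges::reduce(islands, ignore.strand = TRUE)
    h <- GenomicRanges::findOverlaps(peaks, isl, ignore.strand = TRUE)
    ovw <- BiocGenerics::width(IRanges::pintersect(
      peaks[S4Vectors::queryHits(h)], isl[S4Vectors::subjectHits(h)]))
    cov <- numeric(length(peaks))
    agg <- tapply(ovw, S4Vectors::queryHits(h), sum)
    cov[as.integer(names(agg))] <- agg
    cov / as.numeric(BiocGenerics::width(peaks)) >= minIslandCover
  }
  peaks[inIsland]
}

#' Keep peaks supported by multiple biological replicates
#'
#' A peak is supported when it overlaps (>= 1 bp) peaks in at least
#' `minSupport - 1` other replicates; the union of all supported peaks
#' is returned.
#'
#' @param peakSets A list of `GRanges`, one per replicate.
#' @param minSupport Minimum number of replicates a peak must occur in
#'   (default 2).
#' @return Merged `GRanges` of reproducible peaks.
#' @export
reproduciblePeaks <- function(peakSets, minSupport = 2L) {
  if (!is.list(peakSets) || length(peakSets) < minSupport)
    stop("need at least 'minSupport' replicate peak sets")
  supported <- lapply(seq_along(peakSets), function(i) {
    x <- peakSets[[i]]
    if (!length(x)) return(x)
    others <- vapply(seq_along(peakSets)[-i], function(j)
      IRanges::overlapsAny(x, peakSets[[j]], ignore.strand = TRUE),
      logical(length(x)))
    nSup <- 1L + rowSums(matrix(others, nrow = length(x)))
    x[nSup >= minSupport]
  })
  sort(GenomicRanges::reduce(do.call(c, lapply(supported, GenomicRanges::granges)),
                             ignore.strand = TRUE))
}

#' Call EdU/HU hotspots by a global-rate Poisson scan
#'
#' The stalled-fork hotspot caller.  Scan bins whose count is
#' Poisson-improbable against the genome-wide mean rate (no local
#' rate, no shift model) are fused into candidate peaks; each
#' candidate's fold enrichment is its read density over the background
#' rate, estimated from the non-candidate bins so that strong peaks do
#' not inflate their own background on small genomes.  Candidates with
#' fold at or above `minFold` are merged across gaps shorter than
#' `mergeGap`, merged peaks shorter than `minSize` are discarded, and
#' peaks on excluded chromosomes or overlapping the blacklist are
#' removed.
#'
#' @param reads `GRanges` of reads.
#' @param genome `Seqinfo`.
#' @param scanBinWidth Scan bin width in bp (default 1 kb).
#' @param pThreshold Upper-tail Poisson p-value cutoff (default 1e-5).
#' @param minFold Minimum fold enrichment (default 400, inclusive).
#' @param mergeGap Neighbour peaks closer than this are merged
#'   (default 10 kb; 20 kb reproduces the GM12878 setting).
#' @param minSize Merged peaks shorter than this are dropped
#'   (default 10 kb).
#' @param excludeChroms Chromosomes removed from the output.
#' @param blacklist Optional `GRanges`; overlapping peaks are removed.
#' @return `GRanges` of peaks with metadata column `fold`.
#' @export
callPoissonPeaks <- function(reads, genome, scanBinWidth = 1000L,
                             pThreshold = 1e-5, minFold = 400,
                             mergeGap = 10000L, minSize = 10000L,
                             excludeChroms = c("chrY", "chrM"),
                             blacklist = NULL) {
  if (pThreshold <= 0 || pThreshold >= 1) stop("'pThreshold' not in (0,1)")
  if (minFold <= 0) stop("'minFold' must be positive")
  track <- binReads(reads, genome, scanBinWidth)
  counts <- unlist(track@values, use.names = FALSE)
  if (sum(counts) == 0) stop("no reads: scan rate undefined")
  lambda <- mean(counts)
  bw <- as.numeric(scanBinWidth)
  sl <- GenomeInfoDb::seqlengths(genome)

  candPerChr <- lapply(names(track@values), function(chr) {
    v <- track@values[[chr]]
    which(ppois(v - 1, lambda, lower.tail = FALSE) < pThreshold)
  })
  names(candPerChr) <- names(track@values)

  ## background rate per bp from non-candidate bins (falls back to the
  ## global mean when everything is background or everything is signal)
  isCand <- unlist(lapply(names(track@values), function(chr) {
    flag <- logical(length(track@values[[chr]]))
    flag[candPerChr[[chr]]] <- TRUE
    flag
  }))
  bgRate <- if (any(!isCand)) mean(counts[!isCand]) / bw else lambda / bw
  if (bgRate <= 0) bgRate <- lambda / bw

  peaks <- lapply(names(track@values), function(chr) {
    cand <- candPerChr[[chr]]
    if (!length(cand)) return(GenomicRanges::GRanges(seqinfo = genome))
    grp <- cumsum(c(1L, diff(cand) > 1L))
    first <- tapply(cand, grp, min); last <- tapply(cand, grp, max)
    gr <- GenomicRanges::GRanges(chr,
      IRanges::IRanges((first - 1) * bw + 1, pmin(last * bw, sl[[chr]])),
      seqinfo = genome)
    dens <- vapply(seq_along(gr), function(i) {
      idx <- first[i]:last[i]
      sum(track@values[[chr]][idx]) /
        as.numeric(BiocGenerics::width(gr[i]))
    }, numeric(1))
    S4Vectors::mcols(gr)$fold <- dens / bgRate
    gr
  })
  peaks <- sort(do.call(c, peaks))
  peaks <- peaks[S4Vectors::mcols(peaks)$fold >= minFold]
  merged <- mergeWithin(peaks, mergeGap)
  merged <- merged[BiocGenerics::width(merged) >= minSize]
  merged <- merged[!as.character(GenomeInfoDb::seqnames(merged)) %in%
                     excludeChroms]
  if (!is.null(blacklist) && length(merged))
    merged <- merged[!IRanges::overlapsAny(merged, blacklist,
                                                 ignore.strand = TRUE)]
  if (length(merged)) {
    ## recompute whole-peak density fold on the merged intervals
    cnt <- countMidpointsIn(reads, merged)
    S4Vectors::mcols(merged)$fold <-
      (cnt / as.numeric(BiocGenerics::width(merged))) / bgRate
  }
  merged
}

#' Define ERIZs from EdU/HU peaks and E-B peaks
#'
#' ERIZs are the EdU/HU peaks that overlap at least one E-B peak;
#' non-ERIZs are the rest.  When a replication-timing track is given,
#' each peak is labelled `"early"` if its mean timing value exceeds
#' `earlyCut`, `"late"` otherwise, and `"unknown"` when the peak lacks
#' timing coverage.
#'
#' @param eduhuPeaks `GRanges` of EdU/HU hotspots.
#' @param ebPeaks `GRanges` of reproducible E-B peaks.
#' @param timing Optional [BinnedTrack-class] of replication timing.
#' @param earlyCut Early/late cutoff on mean timing (default 0.5,
#'   exclusive for early).
#' @return An [ErizResult-class].
#' @export
defineErizs <- function(eduhuPeaks, ebPeaks, timing = NULL,
                        earlyCut = 0.5) {
  parts <- intersectSelect(eduhuPeaks, ebPeaks)
  lab <- function(g) {
    g <- GenomicRanges::granges(g)
    if (is.null(timing) || length(g) == 0L) {
      S4Vectors::mcols(g)$timing <- rep(NA_real_, length(g))
      S4Vectors::mcols(g)$timingClass <- rep("unknown", length(g))
      return(g)
    }
    tv <- meanOver(timing, g)
    S4Vectors::mcols(g)$timing <- tv
    S4Vectors::mcols(g)$timingClass <-
      ifelse(is.na(tv), "unknown", ifelse(tv > earlyCut, "early", "late"))
    g
  }
  methods::new("ErizResult", erizs = lab(parts$hits),
               nonErizs = lab(parts$misses))
}

#' Score recovery of planted zones by called intervals
#'
#' Zone-level recall (planted zones hit by at least one called
#' interval), precision (called intervals hitting at least one zone),
#' and the mean per-recovered-zone Jaccard index between a zone and
#' the union of its overlapping calls.
#'
#' @param called `GRanges` of called intervals.
#' @param zones `GRanges` of planted zones.
#' @return List with `recall`, `precision`, `meanJaccard`,
#'   `perZoneJaccard`.
#' @export
scoreRecovery <- function(called, zones) {
  if (length(zones) == 0L)
    return(list(recall = NA_real_, precision = NA_real_,
                meanJaccard = NA_real_, perZoneJaccard = numeric(0)))
  hit <- IRanges::overlapsAny(zones, called, ignore.strand = TRUE)
  prec <- if (length(called)) mean(IRanges::overlapsAny(
    called, zones, ignore.strand = TRUE)) else NA_real_
  jac <- vapply(which(hit), function(i) {
    z <- zones[i]
    ov <- called[IRanges::overlapsAny(called, z, ignore.strand = TRUE)]
    inter <- sum(as.numeric(BiocGenerics::width(
      GenomicRanges::intersect(z, ov, ignore.strand = TRUE))))
    uni <- sum(as.numeric(BiocGenerics::width(
      GenomicRanges::union(z, ov, ignore.strand = TRUE))))
    inter / uni
  }, numeric(1))
  list(recall = mean(hit), precision = prec,
       meanJaccard = if (length(jac)) mean(jac) else NA_real_,
       perZoneJaccard = jac)
}
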