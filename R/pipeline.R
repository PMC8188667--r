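## End-to-end composition of the callers: dual-label replicates to
## reproducible E-B peaks, EdU/HU reads to hotspots, and their
## intersection to ERIZs.

#' Run the full initiation-zone pipeline on read sets
#'
#' Per dual-label replicate, broad EdU islands are called, both labels
#' are binned and RPM-normalized on the 5-kb grid, and E-B peaks are
#' called by seed-and-extend; peaks supported by at least
#' `minSupport` replicates are kept.  EdU/HU hotspots are called by
#' the global-rate Poisson scan with the 400-fold filter, and ERIZs
#' are the hotspots overlapping a reproducible E-B peak.
#'
#' @param eduReps,brduReps Lists of read `GRanges`, one per replicate
#'   (first and second label).
#' @param eduhuReads Read `GRanges` from the EdU/HU assay.
#' @param genome `Seqinfo`.
#' @param rpmLibSize Fixed RPM denominator; `NULL` uses each track's
#'   own total.
#' @param ebBinWidth Dual-label bin width (default 5 kb).
#' @param seedThreshold,minLength E-B caller thresholds (0.3 RPM,
#'   20 kb).
#' @param islandLevel,islandGap Island-caller settings.
#' @param minSupport Replicate support for E-B peaks (default 2).
#' @param scanBinWidth,pThreshold,minFold,mergeGap,minSize,excludeChroms,blacklist
#'   EdU/HU caller settings; see [callPoissonPeaks()].
#' @param timing Optional timing [BinnedTrack-class].
#' @param earlyCut Early/late timing cutoff (default 0.5).
#' @return A list with `erizResult` ([ErizResult-class]), `ebPeaks`
#'   and `eduhuPeaks`.
#' @export
runErizPipeline <- function(eduReps, brduReps, eduhuReads, genome,
                            rpmLibSize = NULL, ebBinWidth = 5000L,
                            seedThreshold = 0.3, minLength = 20000,
                            islandLevel = 0.01, islandGap = 3L,
                            minSupport = 2L, scanBinWidth = 1000L,
                            pThreshold = 1e-5, minFold = 400,
                            mergeGap = 10000L, minSize = 10000L,
                            excludeChroms = c("chrY", "chrM"),
                            blacklist = NULL, timing = NULL,
                            earlyCut = 0.5) {
  if (length(eduReps) != length(brduReps))
    stop("need matched first/second-label replicates")
  perRep <- lapply(seq_along(eduReps), function(i) {
    islands <- callIslands(eduReps[[i]], genome, window = ebBinWidth,
                           gap = islandGap, level = islandLevel)
    E <- normalizeTrack(binReads(eduReps[[i]], genome, ebBinWidth),
                        "RPM", libSize = rpmLibSize)
    B <- normalizeTrack(binReads(brduReps[[i]], genome, ebBinWidth),
                        "RPM", libSize = rpmLibSize)
    callEBPeaks(E, B, islands, seedThreshold = seedThreshold,
                minLength = minLength)
  })
  ebPeaks <- if (length(perRep) == 1L) perRep[[1]]
             else reproduciblePeaks(perRep, minSupport = minSupport)
  eduhuPeaks <- callPoissonPeaks(eduhuReads, genome,
                                 scanBinWidth = scanBinWidth,
                                 pThreshold = pThreshold,
                                 minFold = minFold, mergeGap = mergeGap,
                                 minSize = minSize,
                                 excludeChroms = excludeChroms,
                                 blacklist = blacklist)
  list(erizResult = defineErizs(eduhuPeaks, ebPeaks, timing = timing,
                                earlyCut = earlyCut),
       ebPeaks = ebPeaks, eduhuPeaks = eduhuPeaks)
}
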