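## Binned coverage and the pipeline's normalizations (RPM/RPK/RPKM,
## treatment/control fold change, z-score, length-weighted means).

#' Bin reads into fixed-width genome bins
#'
#' Each read (fragment) is assigned to exactly one bin by its midpoint,
#' so the total over all bins equals the number of reads.
#'
#' @param reads `GRanges` of read/fragment positions.
#' @param genome `Seqinfo` genome layout.
#' @param binWidth Bin width in bp (5 kb for the dual-label caller,
#'   1 kb for the EdU/HU scan).
#' @return A [BinnedTrack-class] with `units = "count"`.
#' @export
binReads <- function(reads, genome, binWidth) {
  stopIfNotGRanges(reads, "reads")
  if (binWidth <= 0) stop("'binWidth' must be positive")
  sl <- GenomeInfoDb::seqlengths(genome)
  chrom <- as.character(GenomeInfoDb::seqnames(reads))
  if (!all(chrom %in% names(sl)))
    stop("read chromosome absent from genome layout")
  if (any(BiocGenerics::start(reads) < 1) ||
      any(BiocGenerics::end(reads) > sl[chrom]))
    stop("read outside chromosome bounds")
  bw <- as.integer(binWidth)
  mid0 <- (BiocGenerics::start(reads) - 1L + BiocGenerics::end(reads)) %/% 2L
  bin <- mid0 %/% bw + 1L
  vals <- lapply(setNames(names(sl), names(sl)), function(chr) {
    n <- as.integer(ceiling(sl[[chr]] / bw))
    tabulate(bin[chrom == chr], nbins = n)
  })
  BinnedTrack(genome, bw, vals, units = "count")
}

#' Library-size normalization of a count track
#'
#' RPM scales each bin count by 1e6 over the library size; RPKM
#' additionally divides by the bin width in kb.  `libSize` defaults to
#' the track total but can be fixed to a reference depth, which keeps
#' per-bin values on a genome-scale footing when the track comes from
#' a small synthetic genome.
#'
#' @param track A `BinnedTrack` with `units = "count"`.
#' @param mode `"RPM"` or `"RPKM"`.
#' @param libSize Total-read denominator; default `sum(counts)`.
#' @return A normalized `BinnedTrack`.
#' @export
normalizeTrack <- function(track, mode = c("RPM", "RPKM"), libSize = NULL) {
  mode <- match.arg(mode)
  if (trackUnits(track) != "count")
    stop("normalizeTrack() expects a count track")
  total <- if (is.null(libSize)) sum(unlist(track@values)) else libSize
  if (total <= 0) stop("total reads must be positive")
  f <- switch(mode,
    RPM = 1e6 / total,
    RPKM = 1e9 / (total * as.numeric(binWidth(track))))
  methods::initialize(track, values = lapply(track@values, `*`, f),
                      units = mode)
}

#' Read density per kilobase over arbitrary regions
#'
#' RPK of a region is reads-with-midpoint-inside times 1e3 over the
#' region length; `scaleTo` rescales to a reference library size
#' (e.g. `1e7` for per-10-million normalization of human
#' nascent-transcription densities, `1e6` for mouse).
#'
#' @param reads `GRanges` of reads.
#' @param regions `GRanges` of regions.
#' @param scaleTo Optional reference library size.
#' @param libSize Actual library size; default `length(reads)`.
#' @return Numeric vector of RPK values, one per region.
#' @export
rpkOver <- function(reads, regions, scaleTo = NULL, libSize = NULL) {
  n <- countMidpointsIn(reads, regions)
  rpk <- n * 1e3 / as.numeric(BiocGenerics::width(regions))
  if (!is.null(scaleTo)) {
    total <- if (is.null(libSize)) length(reads) else libSize
    if (total <= 0) stop("library size must be positive")
    rpk <- rpk * scaleTo / total
  }
  rpk
}

#' Bin-wise fold change between a treatment and a control track
#'
#' `(t + pseudocount) / (c + pseudocount)` on a shared grid; the
#' pseudocount guards sparse control bins.
#'
#' @param treat,control `BinnedTrack`s on the same genome and grid.
#' @param pseudocount Non-negative stabilizer added to both sides.
#' @return A `BinnedTrack` with `units = "fold_change"`.
#' @export
foldChangeTrack <- function(treat, control, pseudocount = 0) {
  if (!identical(GenomeInfoDb::seqlengths(treat@genome),
                 GenomeInfoDb::seqlengths(control@genome)) ||
      binWidth(treat) != binWidth(control))
    stop("treatment and control tracks are on different grids")
  if (pseudocount < 0) stop("'pseudocount' must be non-negative")
  vals <- lapply(names(treat@values), function(chr)
    (treat@values[[chr]] + pseudocount) /
      (control@values[[chr]] + pseudocount))
  names(vals) <- names(treat@values)
  methods::initialize(treat, values = vals, units = "fold_change")
}

#' Genome-wide z-score transform of a track
#'
#' Centers and scales all bins jointly (sample standard deviation).
#' Chromosomes in `excludeChroms` are left out of the mean/sd
#' estimation, mirroring the peak-calling exclusions, but are still
#' transformed.
#'
#' @param track A `BinnedTrack`.
#' @param excludeChroms Chromosomes excluded from the moments.
#' @return A `BinnedTrack` with `units = "zscore"`.
#' @export
zscoreTrack <- function(track, excludeChroms = c("chrY", "chrM")) {
  keep <- setdiff(names(track@values), excludeChroms)
  v <- unlist(track@values[keep], use.names = FALSE)
  if (length(v) < 2) stop("need at least two bins")
  m <- mean(v); s <- sd(v)
  if (!is.finite(s) || s == 0) stop("zero variance: z-score undefined")
  methods::initialize(track,
    values = lapply(track@values, function(x) (x - m) / s),
    units = "zscore")
}

#' Length-weighted mean of a track over regions
#'
#' Averages bin values over the bases of each region, weighting
#' partial bins by their overlap width (the `bwtool summary` behaviour
#' used for per-peak replication timing).
#'
#' @param track A `BinnedTrack`.
#' @param regions `GRanges`; each must overlap the track's genome.
#' @return Numeric vector of means, one per region.
#' @export
meanOver <- function(track, regions) {
  stopIfNotGRanges(regions, "regions")
  sl <- GenomeInfoDb::seqlengths(track@genome)
  bw <- as.numeric(binWidth(track))
  vapply(seq_along(regions), function(i) {
    r <- regions[i]
    chr <- as.character(GenomeInfoDb::seqnames(r))
    if (!chr %in% names(sl)) stop("region chromosome not in track genome")
    s <- BiocGenerics::start(r); e <- min(BiocGenerics::end(r), sl[[chr]])
    if (s > sl[[chr]]) stop("region outside chromosome")
    from <- (s - 1) %/% bw + 1
    to <- (e - 1) %/% bw + 1
    idx <- from:to
    binStart <- (idx - 1) * bw + 1
    binEnd <- pmin(idx * bw, sl[[chr]])
    w <- pmin(binEnd, e) - pmax(binStart, s) + 1
    sum(track@values[[chr]][idx] * w) / sum(w)
  }, numeric(1))
}
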