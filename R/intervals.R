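## Interval set operations on strandless BED-style regions.  All
## functions take and return GRanges; strand is ignored throughout
## (strand information lives only on gene records).

#' Merge intervals closer than a gap threshold
#'
#' Joins neighbouring intervals whose edge-to-edge gap is strictly
#' smaller than `maxGap`, applied transitively after sorting.
#' `maxGap = 0` merges only overlapping intervals.  This is the rule
#' used to fuse neighbouring EdU/HU peaks (10 kb in K562, 20 kb in
#' GM12878) and ORC-like ChIP peaks (500 bp).
#'
#' @param x A `GRanges`.
#' @param maxGap Non-negative gap threshold in bp (strict `<`).
#' @return Sorted, non-overlapping `GRanges`.
#' @examples
#' mergeWithin(bedRanges(c("c","c"), c(0, 19999), c(10000, 30000)), 10000)
#' @export
mergeWithin <- function(x, maxGap) {
  stopIfNotGRanges(x)
  if (length(maxGap) != 1L || is.na(maxGap) || maxGap < 0)
    stop("'maxGap' must be a single non-negative number")
  ## reduce() fuses ranges separated by a gap < min.gapwidth, which is
  ## exactly the strict-inequality merging rule.
  sort(GenomicRanges::reduce(x, min.gapwidth = as.integer(maxGap),
                             ignore.strand = TRUE))
}

#' Partition one interval set by overlap with another
#'
#' Element selection, not clipping: every interval of `a` that shares
#' at least one base with any interval of `b` goes to `hits`, the rest
#' to `misses`.  This is the ERIZ definition step (EdU/HU peaks that
#' overlap E-B peaks).
#'
#' @param a,b `GRanges` objects.
#' @return A list with elements `hits` and `misses`; their
#'   concatenation is exactly `a`.
#' @export
intersectSelect <- function(a, b) {
  stopIfNotGRanges(a, "a"); stopIfNotGRanges(b, "b")
  hit <- IRanges::overlapsAny(a, b, ignore.strand = TRUE)
  list(hits = a[hit], misses = a[!hit])
}

#' Base-pair subtraction of interval sets
#'
#' Returns the bases of `a` not covered by `b` (the `bedtools
#' subtract` operation used to carve non-transcribed gaps out of A
#' compartments).
#'
#' @param a,b `GRanges` objects.
#' @return `GRanges` covering `union(a)` minus `union(b)`.
#' @export
subtractRegions <- function(a, b) {
  stopIfNotGRanges(a, "a"); stopIfNotGRanges(b, "b")
  sort(GenomicRanges::setdiff(a, b, ignore.strand = TRUE))
}

#' Select intervals within a distance of another set
#'
#' Keeps elements of `a` whose edge-to-edge distance to the nearest
#' element of `b` is at most `maxDist`; overlap counts as distance 0.
#' Used for reproducible-ChIP-peak matching ("peaks within 500 bp").
#'
#' @param a,b `GRanges` objects.
#' @param maxDist Maximum edge-to-edge distance in bp (inclusive).
#' @return The matching subset of `a`.
#' @export
proximityMatch <- function(a, b, maxDist) {
  stopIfNotGRanges(a, "a"); stopIfNotGRanges(b, "b")
  if (maxDist < 0) stop("'maxDist' must be non-negative")
  if (length(a) == 0L || length(b) == 0L) return(a[integer(0)])
  h <- GenomicRanges::distanceToNearest(a, b, ignore.strand = TRUE)
  keep <- S4Vectors::queryHits(h)[S4Vectors::mcols(h)$distance <= maxDist]
  a[sort(unique(keep))]
}

#' Shuffle intervals uniformly within their own chromosomes
#'
#' Each interval keeps its chromosome and width and receives an
#' independent uniform random start.  Shuffled intervals may overlap
#' one another (the simplest within-chromosome null, used for the
#' expected marker-peak occupancy of the ERIZ predictor).
#'
#' @param x A `GRanges`.
#' @param genome A `Seqinfo` with the chromosome lengths.
#' @param seed Optional integer; fixing it makes the shuffle
#'   deterministic without disturbing the caller's RNG stream.
#' @return `GRanges` of shuffled intervals, same widths and
#'   chromosomes as `x`.
#' @export
shuffleWithinChrom <- function(x, genome, seed = NULL) {
  stopIfNotGRanges(x)
  sl <- GenomeInfoDb::seqlengths(genome)
  chrom <- as.character(GenomeInfoDb::seqnames(x))
  if (!all(chrom %in% names(sl)))
    stop("interval chromosome absent from genome layout")
  w <- BiocGenerics::width(x)
  maxStart0 <- sl[chrom] - w           # 0-based start can be 0..maxStart0
  if (any(maxStart0 < 0)) stop("interval longer than its chromosome")
  withSeed(seed, {
    start0 <- floor(runif(length(x)) * (maxStart0 + 1))
    start0 <- pmin(start0, maxStart0)  # guard the runif(1)==1 edge
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, width = w),
                           seqinfo = genome)
  })
}

#' Fraction of one set's width covered by another
#'
#' Computes (total bp of `a` covered by `b`) / (total bp of `a`), the
#' statistic behind the "percentage of ERIZ width inside A
#' compartments" summary.  Both sets are reduced first, so duplicated
#' coverage is not double-counted.
#'
#' @param a,b `GRanges` objects; `a` must be non-empty.
#' @return A proportion in [0, 1].
#' @export
fractionWidthIn <- function(a, b) {
  stopIfNotGRanges(a, "a"); stopIfNotGRanges(b, "b")
  if (length(a) == 0L) stop("'a' is empty: fraction undefined")
  ra <- GenomicRanges::reduce(a, ignore.strand = TRUE)
  covered <- GenomicRanges::intersect(ra,
    GenomicRanges::reduce(b, ignore.strand = TRUE), ignore.strand = TRUE)
  sum(as.numeric(BiocGenerics::width(covered))) /
    sum(as.numeric(BiocGenerics::width(ra)))
}

#' Per-element overlap fractions between two peak sets
#'
#' The Venn-style summary reported for EdU/HU hotspots versus E-B
#' peaks: the fraction of `a`'s elements overlapping `b`, and vice
#' versa.
#'
#' @param a,b Non-empty `GRanges` objects.
#' @return Named numeric vector `c(fracA =, fracB =)`.
#' @export
overlapFractions <- function(a, b) {
  stopIfNotGRanges(a, "a"); stopIfNotGRanges(b, "b")
  if (length(a) == 0L || length(b) == 0L) stop("empty peak set")
  c(fracA = mean(IRanges::overlapsAny(a, b, ignore.strand = TRUE)),
    fracB = mean(IRanges::overlapsAny(b, a, ignore.strand = TRUE)))
}
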