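#' @import methods
#' @importFrom stats ppois rpois runif rnorm rexp rlnorm sd t.test wilcox.test
#'   glm binomial glm.control coef complete.cases setNames quantile median
#' @importFrom utils read.table write.table head tail
NULL

## Evaluate `expr` under a fixed RNG state without disturbing the caller's
## stream.  All seeded operations in the package route through this.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a base seed, staying inside 32-bit integer range.
childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1103L + as.integer(k) * 12289L) %% 2147483587L
}

#' Construct genomic ranges from BED-style half-open coordinates
#'
#' The package stores intervals as [GenomicRanges::GRanges] (1-based,
#' closed).  All on-disk coordinates follow BED semantics (0-based,
#' half-open); this pair of helpers converts between the two.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors of 0-based half-open coordinates.
#' @param genome Optional [GenomeInfoDb::Seqinfo] supplying chromosome
#'   lengths; coordinates are validated against it.
#' @param ... Named vectors stored as metadata columns.
#' @return `bedRanges()` a `GRanges`; `bedFrame()` a `data.frame` with
#'   columns `chrom`, `start`, `end` in BED convention.
#' @examples
#' bedRanges("chr1", 0, 100)
#' @export
bedRanges <- function(chrom, start, end, genome = NULL, ...) {
  if (any(start < 0) || any(end <= start))
    stop("invalid BED interval: need 0 <= start < end")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end), ...)
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
    bad <- BiocGenerics::end(gr) >
      GenomeInfoDb::seqlengths(genome)[as.character(GenomeInfoDb::seqnames(gr))]
    if (any(bad)) stop("interval extends beyond chromosome end")
  }
  gr
}

#' @rdname bedRanges
#' @param gr A `GRanges` object.
#' @export
bedFrame <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr))
}

## Count reads whose fragment midpoint lies inside each region.
## Midpoint of a BED fragment [s, e) is floor((s + e) / 2), i.e. the
## 1-based position (start + end) %/% 2 of the corresponding GRanges.
midpointPositions <- function(reads) {
  GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(reads),
    IRanges::IRanges(start = (BiocGenerics::start(reads) - 1L +
                                BiocGenerics::end(reads)) %/% 2L + 1L,
                     width = 1L))
}

countMidpointsIn <- function(reads, regions) {
  GenomicRanges::countOverlaps(regions, midpointPositions(reads),
                               ignore.strand = TRUE)
}

stopIfNotGRanges <- function(x, what = "input") {
  if (!methods::is(x, "GRanges"))
    stop(sprintf("'%s' must be a GRanges object", what))
}
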