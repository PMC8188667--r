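## dCas9 transcription-barrier quantification: sliding-bin RPK
## profiles normalized by the B-compartment background of the same
## chromosome, replicate mean +/- SE, and the 2-kb upstream-vs-
## downstream t-test.

.bCompartmentRpk <- function(reads, chrom, compartmentsB) {
  bChr <- compartmentsB[as.character(
    GenomeInfoDb::seqnames(compartmentsB)) == chrom]
  if (length(bChr) == 0L)
    stop("no B compartments on chromosome ", chrom)
  bChr <- GenomicRanges::reduce(GenomicRanges::granges(bChr),
                                ignore.strand = TRUE)
  n <- sum(countMidpointsIn(reads, bChr))
  if (n == 0) stop("zero B-compartment reads: background undefined")
  n * 1e3 / sum(as.numeric(BiocGenerics::width(bChr)))
}

#' RPK-ratio profile around a dCas9 binding site
#'
#' Sliding bins of width `bin` stepped by `slide` across
#' `center +/- halfWidth` (only fully contained bins are reported).
#' Each bin's reads-per-kilobase is divided by the mean RPK of the B
#' compartments on the same chromosome, the background normalization
#' that makes replicates comparable.
#'
#' @param reads `GRanges` of reads for one replicate.
#' @param chrom Chromosome of the binding site.
#' @param center Binding-site midpoint (1-based bp).
#' @param compartmentsB `GRanges` of B compartments.
#' @param halfWidth Half-window in bp (5 kb CMIP-style, 6 kb
#'   GALNT10-style).
#' @param bin Bin width in bp (1 kb / 3 kb).
#' @param slide Step in bp (200 / 300); must not exceed `bin`.
#' @return `data.frame` with `offset` (bin center minus site center)
#'   and `ratio`.
#' @export
rpkRatioProfile <- function(reads, chrom, center, compartmentsB,
                            halfWidth = 5000L, bin = 1000L,
                            slide = 200L) {
  if (slide > bin) stop("'slide' must not exceed 'bin'")
  if (halfWidth < bin) stop("'halfWidth' must be at least 'bin'")
  bg <- .bCompartmentRpk(reads, chrom, compartmentsB)
  starts <- seq.int(center - halfWidth, center + halfWidth - bin,
                    by = slide)
  bins <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(starts, starts + bin - 1L))
  rpk <- countMidpointsIn(reads, bins) * 1e3 / as.numeric(bin)
  data.frame(offset = starts + bin / 2 - center, ratio = rpk / bg)
}

#' Replicate-averaged RPK-ratio profile
#'
#' @param replicates List of read `GRanges`, one per biological
#'   replicate.
#' @inheritParams rpkRatioProfile
#' @return `data.frame` with `offset`, one `ratio.<i>` column per
#'   replicate, `mean` and `se`.
#' @export
barrierProfile <- function(replicates, chrom, center, compartmentsB,
                           halfWidth = 5000L, bin = 1000L,
                           slide = 200L) {
  if (length(replicates) < 1L) stop("need at least one replicate")
  profs <- lapply(replicates, rpkRatioProfile, chrom = chrom,
                  center = center, compartmentsB = compartmentsB,
                  halfWidth = halfWidth, bin = bin, slide = slide)
  m <- sapply(profs, `[[`, "ratio")
  m <- matrix(m, ncol = length(profs))
  colnames(m) <- paste0("ratio.", seq_along(profs))
  out <- data.frame(offset = profs[[1]]$offset, m)
  out$mean <- rowMeans(m)
  out$se <- apply(m, 1, sd) / sqrt(ncol(m))
  out
}

#' Upstream-vs-downstream replication test at a barrier
#'
#' For each replicate, one background-normalized RPK value is computed
#' for the 2-kb bin immediately upstream and one immediately
#' downstream of the binding site (upstream meaning against the
#' direction transcription arrives from, set by `upstreamSide`), then
#' the two sides are compared by a classic two-sample equal-variance
#' Student t-test across replicates.
#'
#' @param replicates List of at least two read `GRanges`.
#' @inheritParams rpkRatioProfile
#' @param testBin Side bin width in bp (default 2 kb).
#' @param upstreamSide `"left"` when transcription travels left to
#'   right across the site (plus-strand gene), `"right"` otherwise.
#' @return List with `statistic`, `p.value`, `meanUp`, `meanDown` and
#'   per-replicate `up`, `down` vectors.
#' @export
updownTest <- function(replicates, chrom, center, compartmentsB,
                       testBin = 2000L,
                       upstreamSide = c("left", "right")) {
  upstreamSide <- match.arg(upstreamSide)
  if (length(replicates) < 2L) stop("need at least two replicates")
  left <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(center - testBin, center - 1L))
  right <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(center, center + testBin - 1L))
  if (upstreamSide == "right") { tmp <- left; left <- right; right <- tmp }
  side <- function(reads, reg)
    countMidpointsIn(reads, reg) * 1e3 / as.numeric(testBin) /
      .bCompartmentRpk(reads, chrom, compartmentsB)
  up <- vapply(replicates, side, numeric(1), reg = left)
  down <- vapply(replicates, side, numeric(1), reg = right)
  if (all(up == down))
    return(list(statistic = 0, p.value = 1, meanUp = mean(up),
                meanDown = mean(down), up = up, down = down))
  tt <- t.test(up, down, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       meanUp = mean(up), meanDown = mean(down), up = up, down = down)
}
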