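## Transcription context: gene activity classes from nascent-RNA
## densities, non-transcribed regions between active genes inside A
## compartments, the non-TR/TR log2 density-ratio statistic, and the
## heatmap matrices used for the midpoint- and gene-scaled displays.

#' Classify genes as active, silent or intermediate
#'
#' Human rule: active needs promoter read density > 0 and gene-body
#' RPK > 4; silent needs zero promoter density and RPK <= 1.  Mouse
#' rule: active needs RPK > 1; silent needs zero RPK.  Genes matching
#' neither rule are labelled intermediate.
#'
#' @param genes `GRanges` with metadata columns `promoter_density` and
#'   `body_rpk`.
#' @param species `"human"` or `"mouse"`.
#' @return `genes` with an added `activity` column.
#' @export
classifyGenes <- function(genes, species = c("human", "mouse")) {
  species <- match.arg(species)
  mc <- S4Vectors::mcols(genes)
  if (!all(c("promoter_density", "body_rpk") %in% names(mc)))
    stop("genes need 'promoter_density' and 'body_rpk' columns")
  pd <- mc$promoter_density; rpk <- mc$body_rpk
  act <- switch(species, human = pd > 0 & rpk > 4, mouse = rpk > 1)
  sil <- switch(species, human = pd == 0 & rpk <= 1, mouse = rpk == 0)
  S4Vectors::mcols(genes)$activity <-
    ifelse(act, "active", ifelse(sil, "silent", "intermediate"))
  genes
}

#' Define non-transcribed regions between active genes
#'
#' Subtracts the merged active-gene footprint from the A compartments
#' and keeps the gaps flanked on both sides by active genes (gaps
#' touching a compartment boundary are discarded).  Optional filters
#' restrict to a width range (20-100 kb by default, inclusive) and to
#' gaps overlapping ERIZs.
#'
#' @param genes Gene `GRanges` with an `activity` column (see
#'   [classifyGenes()]); `gene_id` is used to record the flanks.
#' @param compartmentsA `GRanges` of A compartments.
#' @param widthRange Length-2 numeric, inclusive width filter in bp;
#'   `NULL` disables it.
#' @param erizs Optional `GRanges`; keep only gaps overlapping it.
#' @return `GRanges` of non-TRs with metadata `upstreamGene`,
#'   `downstreamGene` (flanking active genes by coordinate) and
#'   `midpoint`.
#' @export
defineNonTR <- function(genes, compartmentsA,
                        widthRange = c(20000, 100000), erizs = NULL) {
  mc <- S4Vectors::mcols(genes)
  if (is.null(mc$activity)) stop("run classifyGenes() first")
  active <- genes[mc$activity == "active"]
  comps <- GenomicRanges::reduce(compartmentsA, ignore.strand = TRUE)
  if (length(active) == 0L)
    return(GenomicRanges::GRanges())
  foot <- GenomicRanges::reduce(GenomicRanges::granges(active),
                                ignore.strand = TRUE)
  gaps <- subtractRegions(comps, foot)
  if (length(gaps) == 0L) return(gaps)
  ## flanked both sides: the gap must not touch its compartment edge
  hitComp <- GenomicRanges::findOverlaps(gaps, comps, ignore.strand = TRUE)
  compOf <- comps[S4Vectors::subjectHits(hitComp)]
  inner <- BiocGenerics::start(gaps) > BiocGenerics::start(compOf) &
    BiocGenerics::end(gaps) < BiocGenerics::end(compOf)
  gaps <- gaps[inner]
  if (length(gaps) == 0L) return(gaps)
  ## name the flanking active genes (footprint adjacency guarantees one)
  edge <- function(pos, chrom) {
    p <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    h <- GenomicRanges::findOverlaps(p, active, ignore.strand = TRUE)
    ifelse(lengths(as(h, "List"))[seq_along(p)] > 0,
           S4Vectors::mcols(active)$gene_id[
             S4Vectors::subjectHits(h)[!duplicated(S4Vectors::queryHits(h))]],
           NA_character_)
  }
  chrom <- as.character(GenomeInfoDb::seqnames(gaps))
  S4Vectors::mcols(gaps)$upstreamGene <-
    edge(BiocGenerics::start(gaps) - 1L, chrom)
  S4Vectors::mcols(gaps)$downstreamGene <-
    edge(BiocGenerics::end(gaps) + 1L, chrom)
  keep <- !is.na(S4Vectors::mcols(gaps)$upstreamGene) &
    !is.na(S4Vectors::mcols(gaps)$downstreamGene)
  gaps <- gaps[keep]
  if (!is.null(widthRange))
    gaps <- gaps[BiocGenerics::width(gaps) >= widthRange[1] &
                   BiocGenerics::width(gaps) <= widthRange[2]]
  if (!is.null(erizs))
    gaps <- gaps[IRanges::overlapsAny(gaps, erizs,
                                            ignore.strand = TRUE)]
  S4Vectors::mcols(gaps)$midpoint <-
    (BiocGenerics::start(gaps) - 1L + BiocGenerics::end(gaps)) %/% 2L
  gaps
}

#' Log2 density ratio between non-TRs and their flanking genes
#'
#' For each non-transcribed region, read density is computed over the
#' region trimmed by `trim` bp at head and tail; the flank density
#' pools the reads of both flanking active-gene bodies (each trimmed
#' by `trim` bp at both ends) over their summed length.  The statistic
#' is `log2((dNonTR + eps) / (dTR + eps))`.
#'
#' @param reads `GRanges` of reads (e.g. EdU/HU, or ChIP signal).
#' @param nontrs Non-TRs from [defineNonTR()].
#' @param genes The gene `GRanges` the non-TR flank identifiers refer
#'   to.
#' @param trim Head/tail trim in bp (default 200).
#' @param pseudocount Density stabilizer; default half a read over the
#'   trimmed non-TR length.
#' @return `data.frame` with per-region densities and `log2_ratio`.
#' @export
densityLog2Ratio <- function(reads, nontrs, genes, trim = 200,
                             pseudocount = NULL) {
  mc <- S4Vectors::mcols(nontrs)
  if (is.null(mc$upstreamGene)) stop("'nontrs' must come from defineNonTR()")
  ids <- S4Vectors::mcols(genes)$gene_id
  trimmed <- function(g) {
    s <- BiocGenerics::start(g) + trim; e <- BiocGenerics::end(g) - trim
    if (e <= s) return(NULL)
    GenomicRanges::GRanges(GenomeInfoDb::seqnames(g), IRanges::IRanges(s, e))
  }
  rows <- lapply(seq_along(nontrs), function(i) {
    reg <- trimmed(nontrs[i])
    up <- trimmed(genes[match(mc$upstreamGene[i], ids)])
    dn <- trimmed(genes[match(mc$downstreamGene[i], ids)])
    if (is.null(reg) || is.null(up) || is.null(dn)) {
      warning("region ", i, " skipped: trimmed length <= 0")
      return(NULL)
    }
    wN <- as.numeric(BiocGenerics::width(reg))
    dN <- countMidpointsIn(reads, reg) / wN
    wT <- as.numeric(BiocGenerics::width(up)) +
      as.numeric(BiocGenerics::width(dn))
    dT <- (countMidpointsIn(reads, up) + countMidpointsIn(reads, dn)) / wT
    eps <- if (is.null(pseudocount)) 0.5 / wN else pseudocount
    data.frame(region = i, d_nontr = dN, d_tr = dT,
               log2_ratio = log2((dN + eps) / (dT + eps)))
  })
  do.call(rbind, rows)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two samples: exact enumeration
#' when both groups have at most `exactMax` observations and no ties,
#' otherwise the tie-corrected normal approximation with continuity
#' correction.  Degenerate input (all values identical) returns p = 1.
#'
#' @param x,y Numeric samples.
#' @param exactMax Largest per-group size for the exact branch
#'   (default 25).
#' @return List with `statistic` (Mann-Whitney W for `x`) and
#'   `p.value`.
#' @export
rankSumTest <- function(x, y, exactMax = 25L) {
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p.value = 1))
  hasTies <- anyDuplicated(c(x, y)) > 0
  exact <- !hasTies && max(length(x), length(y)) <= exactMax
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                     correct = TRUE, conf.int = FALSE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Signal heatmap matrices around regions
#'
#' `mode = "midpoint"`: each region contributes one row of mean track
#' values in `binWidth` columns across `center +/- flank`; rows are
#' ordered by increasing region width.  `mode = "scaled"`: regions
#' (gene bodies) are scaled to `bodyBins` columns aligned at TSS and
#' TTS, flanked by `flank / binWidth` unscaled columns each side;
#' minus-strand rows are flipped so transcription runs left to right;
#' rows are ordered by increasing width, smallest on top.  Columns off
#' the chromosome ends are `NA`.
#'
#' @param track A [BinnedTrack-class].
#' @param regions `GRanges` (non-TRs for midpoint mode, gene bodies
#'   for scaled mode).
#' @param mode `"midpoint"` or `"scaled"`.
#' @param flank Flank in bp (default 100 kb midpoint / 50 kb scaled).
#' @param binWidth Column width in bp (default 1 kb).
#' @param bodyBins Scaled-mode body column count (default 100).
#' @return Numeric matrix, one row per region in display order, with
#'   attribute `"order"` giving the original region indices.
#' @export
heatmapMatrix <- function(track, regions, mode = c("midpoint", "scaled"),
                          flank = NULL, binWidth = 1000L, bodyBins = 100L) {
  mode <- match.arg(mode)
  if (length(regions) == 0L) stop("no regions")
  if (is.null(flank)) flank <- if (mode == "midpoint") 100000L else 50000L
  sl <- GenomeInfoDb::seqlengths(track@genome)
  colMean <- function(chr, s, e) {      # mean track value on [s,e], NA off-end
    if (s < 1 || e > sl[[chr]] || e < s) return(NA_real_)
    meanOver(track, GenomicRanges::GRanges(chr, IRanges::IRanges(s, e)))
  }
  ord <- order(BiocGenerics::width(regions))
  rows <- lapply(ord, function(i) {
    r <- regions[i]
    chr <- as.character(GenomeInfoDb::seqnames(r))
    if (mode == "midpoint") {
      mid0 <- (BiocGenerics::start(r) - 1L + BiocGenerics::end(r)) %/% 2L
      nCol <- as.integer(2 * flank / binWidth)
      starts <- mid0 - flank + (seq_len(nCol) - 1L) * binWidth + 1L
      vapply(starts, function(s) colMean(chr, s, s + binWidth - 1L),
             numeric(1))
    } else {
      nF <- as.integer(flank / binWidth)
      w <- as.numeric(BiocGenerics::width(r))
      s <- BiocGenerics::start(r); e <- BiocGenerics::end(r)
      upS <- s - flank + (seq_len(nF) - 1L) * binWidth
      up <- vapply(upS, function(z) colMean(chr, z, z + binWidth - 1L),
                   numeric(1))
      bodyEdges <- round(s - 1 + (0:bodyBins) * w / bodyBins)
      body <- vapply(seq_len(bodyBins), function(k)
        colMean(chr, bodyEdges[k] + 1, max(bodyEdges[k + 1], bodyEdges[k] + 1)),
        numeric(1))
      dnS <- e + 1L + (seq_len(nF) - 1L) * binWidth
      dn <- vapply(dnS, function(z) colMean(chr, z, z + binWidth - 1L),
                   numeric(1))
      row <- c(up, body, dn)
      if (as.character(GenomicRanges::strand(r)) == "-") row <- rev(row)
      row
    }
  })
  m <- do.call(rbind, rows)
  attr(m, "order") <- ord
  m
}
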