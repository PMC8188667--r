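## File-format plumbing: chrom.sizes, BED3/BED6 and bedGraph, gene
## tables, and the deposited-ERIZ-table schema.  rtracklayer handles
## the BED-family formats; coordinates are half-open on disk and
## 1-based GRanges in memory.

#' Read a two-column chrom.sizes file as a genome layout
#'
#' @param path Tab-separated file with columns chromosome, length.
#' @return A [GenomeInfoDb::Seqinfo].
#' @export
readChromSizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  if (anyDuplicated(df$chrom)) stop("duplicated chromosome names")
  if (any(df$length <= 0)) stop("chromosome lengths must be positive")
  GenomeInfoDb::Seqinfo(seqnames = df$chrom, seqlengths = df$length)
}

#' @rdname readChromSizes
#' @param genome A `Seqinfo`.
#' @export
writeChromSizes <- function(genome, path) {
  write.table(data.frame(names(GenomeInfoDb::seqlengths(genome)),
                         GenomeInfoDb::seqlengths(genome)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' BED and bedGraph input/output
#'
#' Thin wrappers over [rtracklayer::import()]/[rtracklayer::export()]
#' that attach a genome layout on read.  `readBedGraph()` additionally
#' maps the values onto a fixed bin grid, returning a
#' [BinnedTrack-class]; `writeBedGraph()` writes one line per bin.
#'
#' @param path File path.
#' @param genome Optional (`readBed`) or required `Seqinfo`.
#' @return `readBed()` a `GRanges`; `readBedGraph()` a `BinnedTrack`.
#' @export
readBed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::strand(gr) <- GenomicRanges::strand(gr)  # keep as read
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  gr
}

#' @rdname readBed
#' @param gr A `GRanges` to write (BED3, plus name/score when present).
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname readBed
#' @param binWidth Bin width of the target grid in bp.
#' @param units Units tag for the resulting track.
#' @export
readBedGraph <- function(path, genome, binWidth, units = "score") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
  GenomeInfoDb::seqinfo(gr) <- genome
  track <- BinnedTrack(genome, binWidth, units = units)
  vals <- track@values
  bw <- as.integer(binWidth)
  for (chr in names(vals)) {
    sub <- gr[GenomeInfoDb::seqnames(gr) == chr]
    if (!length(sub)) next
    ## assign each record's value to the bins it covers (records are
    ## expected to be bin-aligned; partial cover takes the record value)
    from <- (BiocGenerics::start(sub) - 1L) %/% bw + 1L
    to <- (BiocGenerics::end(sub) - 1L) %/% bw + 1L
    for (i in seq_along(sub))
      vals[[chr]][from[i]:to[i]] <- S4Vectors::mcols(sub)$score[i]
  }
  methods::initialize(track, values = vals)
}

#' @rdname readBed
#' @param track A `BinnedTrack`.
#' @export
writeBedGraph <- function(track, path) {
  gr <- binRanges(track)
  S4Vectors::mcols(gr)$score <- S4Vectors::mcols(gr)$value
  S4Vectors::mcols(gr)$value <- NULL
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a gene table with nascent-transcription densities
#'
#' Expected columns: `chrom`, `start`, `end` (BED half-open),
#' `strand`, `gene_id`, `promoter_density`, `body_rpk`.
#'
#' @param path Tab-separated file with header.
#' @param genome Optional `Seqinfo`.
#' @return `GRanges` with the density metadata columns.
#' @export
readGeneTable <- function(path, genome = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "gene_id",
            "promoter_density", "body_rpk")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  gr <- bedRanges(df$chrom, df$start, df$end, genome = genome,
                  gene_id = df$gene_id,
                  promoter_density = df$promoter_density,
                  body_rpk = df$body_rpk)
  GenomicRanges::strand(gr) <- df$strand
  gr
}

#' @rdname readGeneTable
#' @param genes A gene `GRanges` as returned by `readGeneTable()` or
#'   [truthGenes()].
#' @export
writeGeneTable <- function(genes, path) {
  df <- cbind(bedFrame(genes),
              strand = as.character(GenomicRanges::strand(genes)),
              as.data.frame(S4Vectors::mcols(genes)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a deposited ERIZ interval table
#'
#' The deposited zone tables are three-column interval lists
#' (chromosome, start, end).  Both headerless BED-style files and
#' files with a header line are accepted.
#'
#' @param path File path.
#' @return `GRanges` of the listed intervals.
#' @export
readErizTable <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- !grepl("^\\S+\t[0-9]+\t[0-9]+", first)
  df <- read.table(path, sep = "\t", header = hasHeader,
                   stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  bedRanges(df$chrom, df$start, df$end)
}
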