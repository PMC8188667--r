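#' BinnedTrack: fixed-width binned genomic signal
#'
#' A per-chromosome numeric signal on a fixed-width bin grid, the
#' substrate of every caller in the package.  Each chromosome holds
#' `ceiling(length / binWidth)` bins; the last bin may be shorter than
#' `binWidth` and is length-weighted wherever bases are averaged.
#'
#' @slot genome A [GenomeInfoDb::Seqinfo] describing the bin grid.
#' @slot binWidth Bin width in bp.
#' @slot values Named list, one numeric vector per chromosome.
#' @slot units One of `"count"`, `"RPM"`, `"RPK"`, `"RPKM"`,
#'   `"fold_change"`, `"zscore"`, `"timing"`, `"score"`.
#' @export
setClass("BinnedTrack",
  representation(genome = "Seqinfo", binWidth = "integer",
                 values = "list", units = "character"))

.trackUnits <- c("count", "RPM", "RPK", "RPKM", "fold_change", "zscore",
                 "timing", "score")

setValidity("BinnedTrack", function(object) {
  sl <- GenomeInfoDb::seqlengths(object@genome)
  if (object@binWidth <= 0L) return("binWidth must be positive")
  if (!identical(sort(names(object@values)), sort(names(sl))))
    return("values must hold exactly one vector per chromosome")
  for (chr in names(sl)) {
    n <- as.integer(ceiling(sl[[chr]] / object@binWidth))
    v <- object@values[[chr]]
    if (length(v) != n)
      return(sprintf("chromosome %s: expected %d bins, got %d",
                     chr, n, length(v)))
    if (any(!is.finite(v)) && object@units != "timing")
      return(sprintf("chromosome %s: non-finite values", chr))
    if (object@units == "count" && any(v < 0))
      return("count track has negative values")
  }
  if (!object@units %in% .trackUnits)
    return(sprintf("unknown units '%s'", object@units))
  TRUE
})

#' Construct a BinnedTrack
#'
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param binWidth Bin width in bp.
#' @param values Named list of per-chromosome numeric vectors; omitted
#'   chromosomes are zero-filled.
#' @param units Signal units tag.
#' @return A [BinnedTrack-class] object.
#' @export
BinnedTrack <- function(genome, binWidth, values = NULL, units = "count") {
  sl <- GenomeInfoDb::seqlengths(genome)
  binWidth <- as.integer(binWidth)
  full <- lapply(sl, function(len) numeric(ceiling(len / binWidth)))
  if (!is.null(values))
    for (chr in names(values)) full[[chr]] <- as.numeric(values[[chr]])
  methods::new("BinnedTrack", genome = genome, binWidth = binWidth,
               values = full, units = units)
}

#' @describeIn BinnedTrack Bin width in bp.
#' @param x,object A `BinnedTrack`.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
#' @rdname BinnedTrack-class
#' @export
setMethod("binWidth", "BinnedTrack", function(x) x@binWidth)

#' @describeIn BinnedTrack Named list of per-chromosome bin values.
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @rdname BinnedTrack-class
#' @export
setMethod("trackValues", "BinnedTrack", function(x) x@values)

#' @describeIn BinnedTrack Units tag of the signal.
#' @export
setGeneric("trackUnits", function(x) standardGeneric("trackUnits"))
#' @rdname BinnedTrack-class
#' @export
setMethod("trackUnits", "BinnedTrack", function(x) x@units)

#' @describeIn BinnedTrack Genome layout (`Seqinfo`) of the grid.
#' @export
setGeneric("genomeLayout", function(x) standardGeneric("genomeLayout"))
#' @rdname BinnedTrack-class
#' @export
setMethod("genomeLayout", "BinnedTrack", function(x) x@genome)

setMethod("show", "BinnedTrack", function(object) {
  v <- unlist(object@values, use.names = FALSE)
  cat(sprintf("BinnedTrack: %d chromosome(s), %d bp bins, units = %s\n",
              length(object@values), object@binWidth, object@units))
  cat(sprintf("  %d bins; mean = %.4g, max = %.4g\n",
              length(v), mean(v), max(v)))
})

#' Ranges of every bin of a BinnedTrack
#'
#' @param track A [BinnedTrack-class].
#' @param chrom Optional single chromosome to restrict to.
#' @return `GRanges` with metadata column `value`, clipped to
#'   chromosome ends.
#' @export
binRanges <- function(track, chrom = NULL) {
  sl <- GenomeInfoDb::seqlengths(track@genome)
  chroms <- if (is.null(chrom)) names(sl) else chrom
  grl <- lapply(chroms, function(chr) {
    n <- length(track@values[[chr]])
    bw <- track@binWidth
    starts <- seq.int(1L, by = bw, length.out = n)
    ends <- pmin(starts + bw - 1L, sl[[chr]])
    GenomicRanges::GRanges(chr, IRanges::IRanges(starts, ends),
                           value = track@values[[chr]],
                           seqinfo = track@genome)
  })
  sort(do.call(c, grl))
}

#' ErizResult: EdU/HU peaks partitioned into ERIZs and non-ERIZs
#'
#' The result of [defineErizs()].  ERIZs are EdU/HU peaks overlapping
#' at least one dual-label E-B peak; all other EdU/HU peaks are
#' non-ERIZs.  Both sets carry per-peak replication timing (mean of the
#' timing track over the peak) and a timing class: `"early"` when the
#' mean timing value exceeds the early cutoff, `"late"` otherwise,
#' `"unknown"` when the peak has no timing coverage.
#'
#' @slot erizs `GRanges` of ERIZs with `timing` and `timingClass`.
#' @slot nonErizs `GRanges` of non-ERIZs, same metadata.
#' @export
setClass("ErizResult",
  representation(erizs = "GRanges", nonErizs = "GRanges"))

setValidity("ErizResult", function(object) {
  need <- c("timing", "timingClass")
  for (s in list(object@erizs, object@nonErizs))
    if (length(s) && !all(need %in% names(S4Vectors::mcols(s))))
      return("peaks must carry 'timing' and 'timingClass' metadata")
  TRUE
})

#' @describeIn ErizResult The ERIZ intervals.
#' @param x,object An `ErizResult`.
#' @export
setGeneric("erizs", function(x) standardGeneric("erizs"))
#' @rdname ErizResult-class
#' @export
setMethod("erizs", "ErizResult", function(x) x@erizs)

#' @describeIn ErizResult The non-ERIZ intervals.
#' @export
setGeneric("nonErizs", function(x) standardGeneric("nonErizs"))
#' @rdname ErizResult-class
#' @export
setMethod("nonErizs", "ErizResult", function(x) x@nonErizs)

setMethod("show", "ErizResult", function(object) {
  fmtW <- function(g) if (length(g)) sprintf("median width %.0f bp",
                                             median(BiocGenerics::width(g)))
                      else "empty"
  pe <- S4Vectors::mcols(object@erizs)$timingClass
  cat(sprintf("ErizResult: %d ERIZs (%s), %d non-ERIZs (%s)\n",
              length(object@erizs), fmtW(object@erizs),
              length(object@nonErizs), fmtW(object@nonErizs)))
  if (length(pe) && any(pe != "unknown"))
    cat(sprintf("  ERIZs early: %.1f%% of timed peaks\n",
                100 * mean(pe[pe != "unknown"] == "early")))
})

#' ErizModel: logistic-regression predictor of ERIZ occupancy
#'
#' Fitted by [fitErizModel()] on 50-kb window enrichment scores.
#'
#' @slot coefficients Named coefficient vector (incl. intercept).
#' @slot se Standard errors from the information matrix.
#' @slot zvalue Wald z statistics.
#' @slot converged Whether IRLS converged.
#' @slot iterations Number of IRLS iterations used.
#' @slot separable Whether (quasi-)separation was detected.
#' @slot fit The underlying `glm` object.
#' @export
setClass("ErizModel",
  representation(coefficients = "numeric", se = "numeric",
                 zvalue = "numeric", converged = "logical",
                 iterations = "integer", separable = "logical",
                 fit = "ANY"))

#' @rdname ErizModel-class
#' @param object An `ErizModel`.
#' @param ... Unused.
#' @export
setMethod("coef", "ErizModel", function(object, ...) object@coefficients)

setMethod("show", "ErizModel", function(object) {
  cat(sprintf("ErizModel: %d predictors, %s after %d IRLS iterations%s\n",
              length(object@coefficients) - 1L,
              if (object@converged) "converged" else "NOT converged",
              object@iterations,
              if (object@separable) " (separation detected)" else ""))
  print(round(data.frame(coefficient = object@coefficients,
                         se = object@se, z = object@zvalue), 4))
})

#' SyntheticTruth: planted ground truth for the synthetic assays
#'
#' Produced by [generateTruth()]: a toy genome with A/B compartments,
#' genes carrying nascent-transcription densities, and planted early
#' replication initiation zones confined to non-transcribed gaps
#' between active genes inside A compartments.
#'
#' @slot genome `Seqinfo` of the synthetic genome.
#' @slot compartmentsA,compartmentsB Compartment segmentation.
#' @slot genes `GRanges` with `gene_id`, `strand`, `promoter_density`,
#'   `body_rpk`, `activity`.
#' @slot zones Planted initiation zones (`GRanges`).
#' @slot config The [simConfig()] list used.
#' @export
setClass("SyntheticTruth",
  representation(genome = "Seqinfo", compartmentsA = "GRanges",
                 compartmentsB = "GRanges", genes = "GRanges",
                 zones = "GRanges", config = "list"))

setValidity("SyntheticTruth", function(object) {
  act <- object@genes[S4Vectors::mcols(object@genes)$activity == "active"]
  moved <- S4Vectors::mcols(object@zones)$relocated
  fixed <- if (is.null(moved)) object@zones else object@zones[!moved]
  if (length(fixed) && any(GenomicRanges::countOverlaps(
        fixed, act, ignore.strand = TRUE) > 0))
    return("non-relocated zones must not overlap active gene bodies")
  if (length(object@zones) > 1 &&
      !GenomicRanges::isDisjoint(object@zones, ignore.strand = TRUE))
    return("planted zones must be pairwise disjoint")
  TRUE
})

#' @describeIn SyntheticTruth Planted initiation zones.
#' @param x,object A `SyntheticTruth`.
#' @export
setGeneric("plantedZones", function(x) standardGeneric("plantedZones"))
#' @rdname SyntheticTruth-class
#' @export
setMethod("plantedZones", "SyntheticTruth", function(x) x@zones)

#' @describeIn SyntheticTruth Gene annotation with activity labels.
#' @export
setGeneric("truthGenes", function(x) standardGeneric("truthGenes"))
#' @rdname SyntheticTruth-class
#' @export
setMethod("truthGenes", "SyntheticTruth", function(x) x@genes)

#' @describeIn SyntheticTruth A or B compartment segmentation.
#' @param which `"A"` or `"B"`.
#' @export
setGeneric("compartments", function(x, which = "A")
  standardGeneric("compartments"))
#' @rdname SyntheticTruth-class
#' @export
setMethod("compartments", "SyntheticTruth", function(x, which = "A") {
  if (match.arg(which, c("A", "B")) == "A") x@compartmentsA
  else x@compartmentsB
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(paste0("SyntheticTruth: %d chromosome(s) (%.1f Mb), ",
                     "%d genes (%d active), %d planted zones\n"),
              length(GenomeInfoDb::seqlengths(object@genome)),
              sum(GenomeInfoDb::seqlengths(object@genome)) / 1e6,
              length(object@genes),
              sum(S4Vectors::mcols(object@genes)$activity == "active"),
              length(object@zones)))
})
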