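## The epigenetic-feature predictor of ERIZ occupancy: 50-kb window
## binarization inside A compartments, shuffle-based expected marker
## occupancy, log-odds enrichment scores, class balancing, and the
## logistic fit whose coefficients rank marker contributions.

#' Tile A compartments into labelled 50-kb windows
#'
#' Each reduced A compartment is tiled from its start in `window`
#' steps; a final partial window is kept when it is at least half the
#' window width.  A window is labelled 1 when it overlaps an ERIZ by
#' at least one base, else 0.
#'
#' @param erizs `GRanges` of ERIZs.
#' @param compartmentsA `GRanges` of A compartments (non-empty).
#' @param genome `Seqinfo`.
#' @param window Window width in bp (default 50 kb).
#' @return `GRanges` of windows with integer metadata column `label`.
#' @export
binarizeWindows <- function(erizs, compartmentsA, genome,
                            window = 50000L) {
  comps <- GenomicRanges::reduce(compartmentsA, ignore.strand = TRUE)
  if (length(comps) == 0L) stop("empty A compartments")
  win <- lapply(seq_along(comps), function(i) {
    s <- BiocGenerics::start(comps[i]); e <- BiocGenerics::end(comps[i])
    starts <- seq.int(s, e, by = window)
    ends <- pmin(starts + window - 1L, e)
    keep <- (ends - starts + 1L) >= window / 2
    if (!any(keep)) return(GenomicRanges::GRanges(seqinfo = genome))
    GenomicRanges::GRanges(
      rep(as.character(GenomeInfoDb::seqnames(comps[i])), sum(keep)),
      IRanges::IRanges(starts[keep], ends[keep]), seqinfo = genome)
  })
  win <- sort(do.call(c, win))
  S4Vectors::mcols(win)$label <-
    as.integer(IRanges::overlapsAny(win, erizs, ignore.strand = TRUE))
  win
}

#' Log-odds enrichment score of marker peaks per window
#'
#' Observed occupancy of a window is the fraction of its 1-kb bins
#' overlapping at least one marker peak.  Expected occupancy is
#' estimated per chromosome as the mean, over `nShuffle` within-
#' chromosome shuffles of the marker peaks, of the same fraction
#' across all window bins of that chromosome.  The score is the
#' difference of natural-log odds,
#' `log((pObs + eps)/(1 - pObs + eps)) - log((pExp + eps)/(1 - pExp + eps))`.
#'
#' @param windows Windows from [binarizeWindows()].
#' @param markerPeaks Non-empty `GRanges` of marker (ChIP-like) peaks.
#' @param genome `Seqinfo`.
#' @param nShuffle Number of shuffles for the expectation (default 10).
#' @param seed Optional seed; fixes the shuffle null.
#' @param eps Haldane-style stabilizer on both odds (default 0.01).
#' @param subBin Occupancy bin width in bp (default 1 kb).
#' @return Numeric score vector, one per window.
#' @export
enrichmentScores <- function(windows, markerPeaks, genome, nShuffle = 10L,
                             seed = NULL, eps = 0.01, subBin = 1000L) {
  if (length(markerPeaks) == 0L) stop("no marker peaks")
  if (nShuffle < 1L) stop("'nShuffle' must be >= 1")
  if (any(BiocGenerics::width(windows) < subBin))
    stop("window smaller than the occupancy bin")
  ## fixed 1-kb sub-bin lattice over the windows, built once
  sub <- lapply(seq_along(windows), function(i) {
    s <- BiocGenerics::start(windows[i]); e <- BiocGenerics::end(windows[i])
    starts <- seq.int(s, e, by = subBin)
    GenomicRanges::GRanges(GenomeInfoDb::seqnames(windows[i]),
      IRanges::IRanges(starts, pmin(starts + subBin - 1L, e)),
      window = i)
  })
  sub <- do.call(c, sub)
  winOf <- S4Vectors::mcols(sub)$window
  chromOfSub <- as.character(GenomeInfoDb::seqnames(sub))
  occ <- function(peaks)
    IRanges::overlapsAny(sub, peaks, ignore.strand = TRUE)
  pObs <- as.numeric(tapply(occ(markerPeaks), winOf, mean))
  expFrac <- withSeed(seed, {
    reps <- vapply(seq_len(nShuffle), function(k) {
      shuf <- shuffleWithinChrom(markerPeaks, genome,
                                 seed = NULL)  # stream already fixed
      tapply(occ(shuf), chromOfSub, mean)
    }, numeric(length(unique(chromOfSub))))
    rowMeans(matrix(reps, ncol = nShuffle))
  })
  names(expFrac) <- sort(unique(chromOfSub))
  chromOfWin <- as.character(GenomeInfoDb::seqnames(windows))
  pExp <- expFrac[chromOfWin]
  lo <- function(p) log((p + eps) / (1 - p + eps))
  unname(lo(pObs) - lo(pExp))
}

#' Balance classes by subsampling the majority label
#'
#' Keeps every label-1 row and a uniform without-replacement sample of
#' label-0 rows of the same count (and vice versa when 1 is the
#' majority).
#'
#' @param labels Integer/logical vector of 0/1 labels.
#' @param seed Optional seed for a deterministic subsample.
#' @return Sorted integer vector of retained row indices.
#' @export
balanceSubsample <- function(labels, seed = NULL) {
  ones <- which(labels == 1); zeros <- which(labels == 0)
  if (!length(ones) || !length(zeros))
    stop("both classes must be non-empty")
  withSeed(seed, {
    if (length(zeros) >= length(ones))
      sort(c(ones, sample(zeros, length(ones))))
    else sort(c(sample(ones, length(zeros)), zeros))
  })
}

#' Fit the ERIZ logistic-regression model
#'
#' Maximum-likelihood logit fit by iteratively reweighted least
#' squares (`glm` with a binomial family, the same fitter the
#' original analysis used), reporting Wald standard errors and a
#' truthful convergence flag.  Perfect or quasi-separation is detected
#' from the fitted probabilities and flagged with a warning rather
#' than hidden.
#'
#' @param X Numeric matrix or data.frame of enrichment scores
#'   (columns = markers).
#' @param y 0/1 labels, one per row of `X`.
#' @param maxIter IRLS iteration cap (default 100).
#' @param tol Convergence tolerance on deviance (default 1e-8).
#' @return An [ErizModel-class].
#' @export
fitErizModel <- function(X, y, maxIter = 100L, tol = 1e-8) {
  X <- as.data.frame(X)
  if (nrow(X) <= ncol(X)) stop("need more rows than predictors")
  if (any(apply(X, 2, function(v) sd(v) == 0)))
    stop("constant predictor column")
  df <- cbind(.y = as.numeric(y), X)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., family = binomial(), data = df,
        control = glm.control(epsilon = tol, maxit = maxIter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep)
    warning("separation detected: coefficients reported but unstable")
  sm <- summary(fit)$coefficients
  methods::new("ErizModel",
               coefficients = sm[, "Estimate"],
               se = sm[, "Std. Error"],
               zvalue = sm[, "z value"],
               converged = fit$converged,
               iterations = as.integer(fit$iter),
               separable = sep, fit = fit)
}

#' Rank marker contributions of a fitted ERIZ model
#'
#' @param model An [ErizModel-class] from [fitErizModel()].
#' @return `data.frame` (marker, coefficient, se, z, sign) sorted by
#'   decreasing coefficient; the intercept is omitted.
#' @export
rankContributions <- function(model) {
  if (!methods::is(model, "ErizModel")) stop("not a fitted ErizModel")
  keep <- names(model@coefficients) != "(Intercept)"
  df <- data.frame(marker = names(model@coefficients)[keep],
                   coefficient = unname(model@coefficients[keep]),
                   se = unname(model@se[keep]),
                   z = unname(model@zvalue[keep]))
  df$sign <- ifelse(df$coefficient >= 0, "positive", "negative")
  df[order(df$coefficient, decreasing = TRUE), , drop = FALSE]
}
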