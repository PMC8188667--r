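## Independent per-base oracles for the interval engine, plus small
## fixture builders.  The oracles work on explicit base-coverage
## vectors and never call the package's interval code.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(GenomeInfoDb)
})

makeGenome <- function(lengths) {
  Seqinfo(seqnames = names(lengths), seqlengths = unname(lengths))
}

## coverage vector (TRUE = covered) per chromosome, BED coords
bfCoverage <- function(df, sl) {
  lapply(sl, function(len) {
    v <- logical(len)
    v
  }) -> cov
  names(cov) <- names(sl)
  if (nrow(df)) for (i in seq_len(nrow(df))) {
    idx <- (df$start[i] + 1):df$end[i]
    cov[[df$chrom[i]]][idx] <- TRUE
  }
  cov
}

## runs of TRUE -> BED data.frame
bfRuns <- function(cov) {
  out <- lapply(names(cov), function(chr) {
    r <- rle(cov[[chr]])
    e <- cumsum(r$lengths); s <- e - r$lengths
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(chrom = chr, start = s[keep], end = e[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(chrom = character(), start = numeric(),
                               end = numeric()) else out
}

## merge with gap < maxGap: fill FALSE runs shorter than maxGap that
## sit between TRUE runs, then read off the runs
bfMerge <- function(df, sl, maxGap) {
  cov <- bfCoverage(df, sl)
  for (chr in names(cov)) {
    v <- cov[[chr]]
    r <- rle(v)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k] && k > 1 && k < length(r$values) &&
          r$lengths[k] < maxGap)
        v[s[k]:e[k]] <- TRUE
    }
    cov[[chr]] <- v
  }
  bfRuns(cov)
}

bfSubtract <- function(dfa, dfb, sl) {
  ca <- bfCoverage(dfa, sl); cb <- bfCoverage(dfb, sl)
  bfRuns(mapply(function(a, b) a & !b, ca, cb, SIMPLIFY = FALSE))
}

bfIntersectSelect <- function(dfa, dfb, sl) {
  cb <- bfCoverage(dfb, sl)
  hit <- vapply(seq_len(nrow(dfa)), function(i)
    any(cb[[dfa$chrom[i]]][(dfa$start[i] + 1):dfa$end[i]]), logical(1))
  list(hits = dfa[hit, , drop = FALSE],
       misses = dfa[!hit, , drop = FALSE])
}

## edge-to-edge distance between two BED intervals (0 if overlapping)
bfDist <- function(a, b) {
  if (a["chrom"] != b["chrom"]) return(Inf)
  max(0, as.numeric(b["start"]) - as.numeric(a["end"]),
      as.numeric(a["start"]) - as.numeric(b["end"]))
}

bfProximity <- function(dfa, dfb, maxDist) {
  if (!nrow(dfa) || !nrow(dfb)) return(dfa[integer(0), , drop = FALSE])
  keep <- vapply(seq_len(nrow(dfa)), function(i) {
    d <- vapply(seq_len(nrow(dfb)), function(j)
      bfDist(c(chrom = dfa$chrom[i], start = dfa$start[i],
               end = dfa$end[i]),
             c(chrom = dfb$chrom[j], start = dfb$start[j],
               end = dfb$end[j])), numeric(1))
    min(d) <= maxDist
  }, logical(1))
  dfa[keep, , drop = FALSE]
}

bfFractionIn <- function(dfa, dfb, sl) {
  ca <- bfCoverage(dfa, sl); cb <- bfCoverage(dfb, sl)
  num <- sum(mapply(function(a, b) sum(a & b), ca, cb))
  num / sum(vapply(ca, sum, numeric(1)))
}

## random interval set on a small genome, as a BED data.frame
randomIntervalFrame <- function(sl, n) {
  if (n == 0) return(data.frame(chrom = character(), start = numeric(),
                                end = numeric()))
  chrom <- sample(names(sl), n, replace = TRUE)
  w <- sample.int(5000, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(sl[[chrom[i]]] - w[i] + 1, 1) - 1, numeric(1))
  data.frame(chrom = chrom, start = start, end = start + w)
}

frameToGr <- function(df, genome) {
  if (!nrow(df)) return(GRanges(seqinfo = genome))
  bedRanges(df$chrom, df$start, df$end, genome = genome)
}

grToFrame <- function(gr) {
  df <- bedFrame(gr)
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

sortFrame <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), c("chrom", "start", "end"),
           drop = FALSE]
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  rownames(df) <- NULL
  df
}

## exact Wilcoxon rank-sum two-sided p by full enumeration (no ties)
bfWilcoxExact <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  wObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
}
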