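## Distance-decay analytics: expected profiles, observed/expected matrices
## and P(s) curves with scaling-exponent fits.

# Mean balanced contact per genomic-separation (in bins) for one
# chromosome block; returns vector indexed by separation + 1 (0..n-1) and
# matching pair counts.
chromDecay <- function(w, mask) {
  n <- nrow(w)
  vals <- numeric(n)
  cnts <- numeric(n)
  for (s in 0:(n - 1)) {
    i <- seq_len(n - s)
    v <- w[cbind(i, i + s)]
    ok <- !is.na(v)
    vals[s + 1] <- sum(v[ok])
    cnts[s + 1] <- sum(ok)
  }
  list(sum = vals, n = cnts)
}

#' Expected contact frequency per genomic separation
#'
#' Mean balanced contact over unmasked intra-chromosomal pairs at each
#' separation, pooled across chromosomes (separations in bins).
#'
#' @param map balanced [ContactMap-class]
#' @return numeric vector; element k = expected value at separation k-1 bins
#' @export
expectedProfile <- function(map) {
  w <- balancedOrCounts(map)
  chrom <- binChrom(map)
  maxn <- max(table(chrom))
  tot <- numeric(maxn); cnt <- numeric(maxn)
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    d <- chromDecay(w[ix, ix, drop = FALSE], binMask(map)[ix])
    k <- seq_along(d$sum)
    tot[k] <- tot[k] + d$sum
    cnt[k] <- cnt[k] + d$n
  }
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Observed/expected matrix
#'
#' Balanced contacts divided by the distance-expected value; defined for
#' intra-chromosomal entries only (inter-chromosomal entries NA).
#'
#' @param map balanced [ContactMap-class]
#' @param expected optional profile from [expectedProfile()]
#' @return matrix of O/E values
#' @export
oeMatrix <- function(map, expected = expectedProfile(map)) {
  w <- balancedOrCounts(map)
  chrom <- binChrom(map)
  out <- matrix(NA_real_, nrow(w), ncol(w))
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    sep <- abs(outer(seq_along(ix), seq_along(ix), "-"))
    e <- matrix(expected[sep + 1], length(ix), length(ix))
    out[ix, ix] <- w[ix, ix] / e
  }
  out
}

#' Contact-probability decay curve P(s) and scaling exponent
#'
#' Mean balanced contact over all unmasked intra-chromosomal pairs per
#' log-spaced separation bin, normalized so the curve integrates to 1 over
#' separation; the scaling exponent is the least-squares slope of
#' log10 P versus log10 s within \code{fitRange}.
#'
#' Bins belonging to a supplied annotation (e.g. pericentromeric
#' heterochromatin) are excluded so that the Rabl-associated signal does
#' not distort arm scaling.
#'
#' @param map balanced [ContactMap-class]
#' @param binsPerDecade log-bin density
#' @param fitRange numeric(2) separation range in bp for the exponent fit
#' @param exclude optional GRanges; overlapping bins are dropped
#' @return [DecayCurve-class]
#' @export
decayCurve <- function(map, binsPerDecade = 8,
                       fitRange = c(1e5, 1e7), exclude = NULL) {
  w <- balancedOrCounts(map)
  keep <- binMask(map)
  if (!is.null(exclude))
    keep <- keep & !overlapsAny(binRanges(map), exclude)
  res <- mapResolution(map)
  chrom <- binChrom(map)
  maxn <- max(table(chrom))
  tot <- numeric(maxn); cnt <- numeric(maxn)
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch & keep)
    if (length(ix) < 2) next
    sub <- w[ix, ix, drop = FALSE]
    # separations must reflect genomic distance of the retained bins
    pos <- round((start(binRanges(map))[ix] - 1) / res)
    n <- length(ix)
    for (a in seq_len(n - 1)) {
      b <- (a + 1):n
      s <- pos[b] - pos[a]
      v <- sub[a, b]
      ok <- !is.na(v) & s >= 1
      if (any(ok)) {
        tsep <- s[ok]
        agg <- rowsum(cbind(v[ok], 1), tsep)
        k <- as.integer(rownames(agg))
        kk <- k[k <= maxn - 1]
        tot[kk + 1] <- tot[kk + 1] + agg[k <= maxn - 1, 1]
        cnt[kk + 1] <- cnt[kk + 1] + agg[k <= maxn - 1, 2]
      }
    }
  }
  sepBins <- which(cnt > 0) - 1
  sepBins <- sepBins[sepBins >= 1]
  if (!length(sepBins)) stopf("no intra-chromosomal pairs available")
  sepBp <- sepBins * res
  p <- tot[sepBins + 1] / cnt[sepBins + 1]
  # pool into log-spaced bins
  lo <- floor(log10(min(sepBp)) * binsPerDecade)
  hi <- ceiling(log10(max(sepBp)) * binsPerDecade)
  edges <- 10^(seq(lo, hi) / binsPerDecade)
  bin <- findInterval(sepBp, edges, rightmost.closed = TRUE)
  pooled <- vapply(split(seq_along(p), bin), function(ix) {
    c(sum(p[ix] * cnt[sepBins[ix] + 1]) / sum(cnt[sepBins[ix] + 1]),
      exp(mean(log(sepBp[ix]))))
  }, numeric(2))
  prob <- pooled[1, ]
  sepc <- pooled[2, ]
  ord <- order(sepc)
  prob <- prob[ord]; sepc <- sepc[ord]
  # unit-area normalization: sum P * bin width = 1
  bw <- diff(edges)[findInterval(sepc, edges, rightmost.closed = TRUE)]
  area <- sum(prob * bw)
  if (area > 0) prob <- prob / area
  inFit <- sepc >= fitRange[1] & sepc <= fitRange[2] & prob > 0
  if (sum(inFit) < 3)
    stopf("fewer than 3 populated log-bins in fit range; exponent undefined")
  fit <- lm(log10(prob[inFit]) ~ log10(sepc[inFit]))
  new("DecayCurve", separations = sepc, probabilities = prob,
      fitRange = fitRange, exponent = unname(coef(fit)[2]))
}
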