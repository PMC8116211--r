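## Compartment score (first eigenvector), saddle analysis and compartment
## strength, switching, and insulation/TAD boundaries.

#' Compartment score: first eigenvector of the O/E correlation matrix
#'
#' Per chromosome, the balanced map is converted to observed/expected, then
#' to a Pearson correlation matrix; the leading eigenvector gives the
#' per-bin score. The eigenvector sign is arbitrary, so it is oriented so
#' that the score correlates positively with \code{orientation} (e.g. gene
#' density, active-mark coverage, or the synthetic ground truth). Labels:
#' A for score > 0, B for score < 0, NA for masked bins.
#'
#' @param map balanced [ContactMap-class]
#' @param orientation numeric per-bin reference vector, or NULL to leave
#'   the sign convention at "first defined loading positive"
#' @return [CompartmentTrack-class]
#' @export
compartmentScore <- function(map, orientation = NULL) {
  w <- balancedOrCounts(map)
  chrom <- binChrom(map)
  n <- nrow(w)
  if (!is.null(orientation) && length(orientation) != n)
    stopf("orientation track must have one value per bin")
  oe <- oeMatrix(map)
  score <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch & binMask(map))
    if (length(ix) < 3) next
    sub <- oe[ix, ix, drop = FALSE]
    sds <- apply(sub, 2, sd, na.rm = TRUE)
    if (all(!is.finite(sds)) || all(sds < 1e-12)) {
      warnf("degenerate (constant) O/E on %s; scores undefined", ch)
      next
    }
    cc <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 0
    eg <- eigen(cc, symmetric = TRUE)
    v <- eg$vectors[, 1]
    if (eg$values[1] < 1e-10) {
      warnf("degenerate correlation matrix on %s; scores undefined", ch)
      next
    }
    score[ix] <- v
  }
  if (!is.null(orientation)) {
    ok <- !is.na(score) & !is.na(orientation)
    if (sum(ok) >= 2 && sd(score[ok]) > 0 && sd(orientation[ok]) > 0 &&
        cor(score[ok], orientation[ok]) < 0)
      score <- -score
  } else {
    first <- which(!is.na(score) & score != 0)
    if (length(first) && score[first[1]] < 0) score <- -score
  }
  lab <- ifelse(is.na(score) | score == 0, NA_character_,
                ifelse(score > 0, "A", "B"))
  bins <- binRanges(map)
  mcols(bins)$score <- score
  mcols(bins)$label <- lab
  new("CompartmentTrack", bins = bins, resolution = mapResolution(map))
}

#' Construct a CompartmentTrack from explicit scores
#'
#' @param chrom chromosome per bin
#' @param start bin start (1-based) per bin
#' @param score per-bin score; 0/NA = undefined
#' @param resolution bin size in bp
#' @return [CompartmentTrack-class]
#' @export
compartmentTrack <- function(chrom, start, score, resolution) {
  lab <- ifelse(is.na(score) | score == 0, NA_character_,
                ifelse(score > 0, "A", "B"))
  bins <- GRanges(chrom, IRanges(start, width = resolution))
  mcols(bins)$score <- score
  mcols(bins)$label <- lab
  new("CompartmentTrack", bins = bins, resolution = resolution)
}

#' Read a compartment-score table (tsv1: chrom, start, end, score)
#'
#' @param path tab-separated file, 1-based inclusive coordinates, with or
#'   without header
#' @return [CompartmentTrack-class]
#' @export
readCompartmentTrack <- function(path) {
  gr <- readBed(path, dialect = "tsv1")
  res <- if (length(gr)) round(median(width(gr))) else 1
  compartmentTrack(as.character(seqnames(gr)), start(gr),
                   mcols(gr)$score, res)
}

#' Write a per-bin track as bedGraph
#'
#' @param track [CompartmentTrack-class] or [InsulationTrack-class]
#' @param path output path
#' @export
writeBedGraph <- function(track, path) {
  bins <- binRanges(track)
  v <- if (is(track, "CompartmentTrack")) scores(track) else scores(track)
  df <- data.frame(chrom = as.character(seqnames(bins)),
                   start = start(bins) - 1, end = end(bins),
                   value = ifelse(is.na(v), "NA", format(v, digits = 6)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# pool O/E entries by quantile pair; shared by saddle and strength
saddlePool <- function(map, track, nQuantiles, minSeparation,
                       cornerFraction) {
  oe <- oeMatrix(map)
  sc <- scores(track)
  n <- nrow(oe)
  if (length(sc) != n) stopf("track and map must share bins")
  defined <- !is.na(sc) & binMask(map)
  idx <- which(defined)
  if (length(idx) < 2 * nQuantiles)
    nQuantiles <- max(2, floor(length(idx) / 2))
  # ties (e.g. binary ground-truth tracks) are broken by a deterministic
  # pseudo-random permutation, not by genome position, so extreme
  # quantiles do not cluster positionally
  tie <- ((idx * 2654435761) %% 1000003) / 1000003
  scale <- diff(range(sc[idx]))
  if (!is.finite(scale) || scale == 0) scale <- 1
  rk <- rank(sc[idx] + tie * scale * 1e-9, ties.method = "first")
  q <- ceiling(rk * nQuantiles / length(idx))
  chrom <- binChrom(map)
  pos <- start(binRanges(map))
  # intra-chromosomal, unmasked, defined, i < j, separation filter
  pairs <- which(upper.tri(oe) & !is.na(oe), arr.ind = TRUE)
  keep <- defined[pairs[, 1]] & defined[pairs[, 2]] &
    abs(pos[pairs[, 1]] - pos[pairs[, 2]]) >= minSeparation
  pairs <- pairs[keep, , drop = FALSE]
  qi <- q[match(pairs[, 1], idx)]
  qj <- q[match(pairs[, 2], idx)]
  v <- oe[pairs]
  sep <- abs(pos[pairs[, 1]] - pos[pairs[, 2]])
  lo <- pmin(qi, qj); hi <- pmax(qi, qj)
  nc <- max(1, round(cornerFraction * nQuantiles))
  corner <- ifelse(hi <= nc, "BB",
            ifelse(lo > nQuantiles - nc, "AA",
            ifelse(lo <= nc & hi > nQuantiles - nc, "AB", NA)))
  list(qi = qi, qj = qj, v = v, sep = sep, corner = corner,
       nQuantiles = nQuantiles)
}

# Distance-matched corner means: per-separation corner means combined
# with common weights (the AB corner's pair counts), so the distance
# expectation cancels exactly between corners and the strength ratios are
# free of distance-decay confounding. Falls back to plain pooling when no
# separation is shared by all three corners.
cornerStrength <- function(p) {
  pool <- function(k) {
    sel <- which(p$corner %in% k)
    if (!length(sel)) return(NULL)
    agg <- rowsum(cbind(p$v[sel], 1), p$sep[sel])
    data.frame(sep = as.numeric(rownames(agg)), mean = agg[, 1] / agg[, 2],
               n = agg[, 2])
  }
  aa <- pool("AA"); bb <- pool("BB"); ab <- pool("AB")
  if (is.null(aa) || is.null(bb) || is.null(ab))
    return(list(AA = NA_real_, BB = NA_real_, AB = NA_real_))
  common <- Reduce(intersect, list(aa$sep, bb$sep, ab$sep))
  if (length(common) < 3) {
    m <- function(k) mean(p$v[p$corner %in% k])
    return(list(AA = m("AA"), BB = m("BB"), AB = m("AB")))
  }
  w <- ab$n[match(common, ab$sep)]
  wm <- function(df) sum(df$mean[match(common, df$sep)] * w) / sum(w)
  list(AA = wm(aa), BB = wm(bb), AB = wm(ab))
}

#' Saddle analysis: O/E enrichment sorted by compartment score
#'
#' Intra-chromosomal O/E values are pooled by pairs of compartment-score
#' quantiles (ascending, so the B-most bins come first); pairs closer than
#' \code{minSeparation} bp are excluded. Corner means over the extreme
#' \code{cornerFraction} quantiles give the compartment-strength report:
#' strength_A = AA/AB, strength_B = BB/AB, overall = sqrt(AA*BB)/AB.
#' Corner means are distance-matched: per-separation means combined with
#' common weights across corners, so the distance expectation cancels in
#' the strength ratios.
#'
#' @param map balanced [ContactMap-class]
#' @param track [CompartmentTrack-class] on the same bins
#' @param nQuantiles number of score quantiles
#' @param minSeparation minimum pair separation in bp
#' @param cornerFraction fraction of extreme quantiles per corner
#' @return [SaddleMatrix-class]
#' @export
saddle <- function(map, track, nQuantiles = 50, minSeparation = 0,
                   cornerFraction = 0.2) {
  p <- saddlePool(map, track, nQuantiles, minSeparation, cornerFraction)
  nq <- p$nQuantiles
  vals <- matrix(NA_real_, nq, nq)
  cnts <- matrix(0, nq, nq)
  lo <- pmin(p$qi, p$qj); hi <- pmax(p$qi, p$qj)
  agg <- rowsum(cbind(p$v, 1), lo + (hi - 1) * nq)
  key <- as.integer(rownames(agg))
  li <- (key - 1) %% nq + 1
  hj <- (key - 1) %/% nq + 1
  vals[cbind(li, hj)] <- agg[, 1] / agg[, 2]
  vals[cbind(hj, li)] <- agg[, 1] / agg[, 2]
  cnts[cbind(li, hj)] <- agg[, 2]
  cnts[cbind(hj, li)] <- agg[, 2]
  cs <- cornerStrength(p)
  AA <- cs$AA; BB <- cs$BB; AB <- cs$AB
  strength <- list(AA = AA, BB = BB, AB = AB,
                   strengthA = AA / AB, strengthB = BB / AB,
                   strengthOverall = sqrt(AA * BB) / AB)
  new("SaddleMatrix", values = vals, counts = cnts, nQuantiles = nq,
      cornerFraction = cornerFraction, strength = strength)
}

#' log2 differential saddle
#'
#' @param a,b [SaddleMatrix-class] with equal nQuantiles
#' @return matrix log2(a/b); undefined cells propagate as NA
#' @export
differentialSaddle <- function(a, b) {
  if (a@nQuantiles != b@nQuantiles) stopf("nQuantiles mismatch")
  log2(a@values / b@values)
}

#' Fraction of bins switching compartment sign
#'
#' @param a,b [CompartmentTrack-class] on the same bins
#' @return fraction of bins with opposite score sign among bins defined in
#'   both tracks
#' @export
compartmentSwitching <- function(a, b) {
  sa <- scores(a); sb <- scores(b)
  if (length(sa) != length(sb)) stopf("tracks must share bins")
  ok <- !is.na(sa) & !is.na(sb) & sa != 0 & sb != 0
  if (!any(ok)) return(NA_real_)
  mean(sign(sa[ok]) != sign(sb[ok]))
}

#' Insulation score and TAD boundaries
#'
#' Per bin, the mean balanced signal in the window x window square crossing
#' the diagonal at that bin, as log2 versus the chromosome median;
#' boundaries are local minima whose prominence (depth below the lower of
#' the two flanking maxima) exceeds \code{prominence}.
#'
#' @param map balanced [ContactMap-class]
#' @param window window in bp on each side of the diagonal
#' @param prominence minimum boundary prominence in log2 units
#' @return [InsulationTrack-class]
#' @export
insulation <- function(map, window = 1e5, prominence = 0.1) {
  w <- balancedOrCounts(map)
  res <- mapResolution(map)
  k <- max(2, round(window / res))
  chrom <- binChrom(map)
  n <- nrow(w)
  raw <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    m <- w[ix, ix, drop = FALSE]
    nn <- length(ix)
    for (i in seq_len(nn)) {
      if (i - k < 1 || i + k > nn) next
      sq <- m[(i - k):(i - 1), (i + 1):(i + k), drop = FALSE]
      if (all(is.na(sq))) next
      raw[ix[i]] <- mean(sq, na.rm = TRUE)
    }
    med <- median(raw[ix], na.rm = TRUE)
    if (is.finite(med) && med > 0)
      raw[ix] <- log2(raw[ix] / med)
  }
  boundaries <- integer(0)
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    v <- raw[ix]
    for (i in seq_along(v)) {
      if (is.na(v[i])) next
      l <- i - 1; r <- i + 1
      if (l < 1 || r > length(v) || is.na(v[l]) || is.na(v[r])) next
      # local minimum; one-sided ties allowed so flat-bottomed (two-bin)
      # minima at symmetric boundaries are still detected
      strictL <- v[i] < v[l]; strictR <- v[i] < v[r]
      if (!((strictL && v[i] <= v[r]) || (v[i] <= v[l] && strictR))) next
      # prominence: rise to the nearest flanking maximum on each side
      leftMax <- max(v[seq_len(i - 1)], na.rm = TRUE)
      rightMax <- max(v[seq(i + 1, length(v))], na.rm = TRUE)
      if (min(leftMax, rightMax) - v[i] >= prominence)
        boundaries <- c(boundaries, ix[i])
    }
  }
  bins <- binRanges(map)
  mcols(bins)$insulation <- raw
  new("InsulationTrack", bins = bins, resolution = res,
      window = k * res, boundaries = as.integer(boundaries))
}
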