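## Contact-map data model and I/O, iterative-correction balancing,
## differential maps and coarsening.

#' Construct a ContactMap
#'
#' @param counts symmetric non-negative matrix; an asymmetric input is
#'   symmetrized as (M + t(M))/2 with a warning
#' @param resolution bin size in bp
#' @param chrom chromosome per bin (recycled scalar allowed)
#' @param start bin start (1-based) per bin; default consecutive bins
#' @return [ContactMap-class]
#' @export
contactMap <- function(counts, resolution, chrom = "chr1", start = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (ncol(counts) != n) stopf("counts must be square")
  if (any(counts < 0, na.rm = TRUE)) stopf("negative count in matrix")
  if (max(abs(counts - t(counts)), na.rm = TRUE) > 1e-8) {
    warnf("asymmetric input symmetrized as (M + t(M))/2")
    counts <- (counts + t(counts)) / 2
  }
  chrom <- rep_len(chrom, n)
  if (is.null(start)) {
    pos <- stats::ave(seq_len(n), chrom, FUN = seq_along)
    start <- (pos - 1) * resolution + 1
  }
  bins <- GRanges(chrom, IRanges(start, width = resolution))
  new("ContactMap", bins = bins, resolution = resolution, counts = counts,
      mask = rep(TRUE, n))
}

#' Load a contact map from disk
#'
#' Formats: \code{"dense"}, a whitespace-separated symmetric matrix (one
#' chromosome); \code{"triplet"}, the package's tab-separated sparse format
#' with \code{#resolution} and \code{#bin} header comments followed by
#' \code{bin_i bin_j count} rows (0-based bin indices, upper triangle
#' sufficient).
#'
#' @param path file path
#' @param format "dense" or "triplet"
#' @param resolution bin size in bp (dense format; triplet carries its own)
#' @param chrom chromosome name for dense input
#' @return [ContactMap-class]
#' @export
loadContactMap <- function(path, format = c("dense", "triplet"),
                           resolution = NULL, chrom = "chr1") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "dense") {
    rows <- strsplit(trimws(readLines(path)), "\\s+")
    rows <- rows[lengths(rows) > 0]
    n <- length(rows)
    if (length(unique(lengths(rows))) != 1 || lengths(rows)[1] != n)
      stopf("ragged or non-square dense matrix in %s", path)
    m <- matrix(as.numeric(unlist(rows)), n, n, byrow = TRUE)
    if (any(is.na(m))) stopf("non-numeric entry in dense matrix %s", path)
    if (any(m < 0)) stopf("negative count in %s", path)
    if (is.null(resolution)) stopf("dense format requires a resolution")
    contactMap(m, resolution, chrom)
  } else {
    lines <- readLines(path)
    resLine <- grep("^#resolution\\t", lines, value = TRUE)
    binLines <- grep("^#bin\\t", lines, value = TRUE)
    if (!length(resLine) || !length(binLines))
      stopf("triplet file %s lacks #resolution/#bin headers", path)
    resolution <- as.numeric(sub("^#resolution\\t", "", resLine[1]))
    binF <- strsplit(sub("^#bin\\t", "", binLines), "\t", fixed = TRUE)
    chromv <- vapply(binF, `[`, "", 1)
    startv <- as.numeric(vapply(binF, `[`, "", 2))
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    n <- length(binLines)
    m <- matrix(0, n, n)
    if (length(body)) {
      tf <- strsplit(body, "\t", fixed = TRUE)
      i <- as.integer(vapply(tf, `[`, "", 1)) + 1L
      j <- as.integer(vapply(tf, `[`, "", 2)) + 1L
      v <- as.numeric(vapply(tf, `[`, "", 3))
      if (any(is.na(i) | is.na(j) | is.na(v)))
        stopf("malformed triplet row in %s", path)
      if (any(v < 0)) stopf("negative count in %s", path)
      m[cbind(i, j)] <- v
      m[cbind(j, i)] <- v
    }
    map <- contactMap(m, resolution, chromv, startv)
    map
  }
}

#' Write a contact map
#'
#' @param map [ContactMap-class]
#' @param path output path
#' @param format "dense" (counts matrix, whitespace-separated) or
#'   "triplet" (sparse upper triangle with bin headers)
#' @param layer "counts" or "balanced"
#' @export
writeContactMap <- function(map, path, format = c("triplet", "dense"),
                            layer = c("counts", "balanced")) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  m <- if (layer == "counts") contactCounts(map) else balancedCounts(map)
  if (is.null(m)) stopf("map has no balanced layer")
  if (format == "dense") {
    write.table(m, path, sep = " ", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    bins <- binRanges(map)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#resolution\t%d", as.integer(mapResolution(map))), con)
    writeLines(sprintf("#bin\t%s\t%d", as.character(seqnames(bins)),
                       start(bins)), con)
    idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    if (nrow(idx))
      writeLines(sprintf("%d\t%d\t%s", idx[, 1] - 1L, idx[, 2] - 1L,
                         format(m[idx], scientific = FALSE, trim = TRUE)),
                 con)
  }
  invisible(path)
}

#' Balance a contact map by iterative correction (ICE)
#'
#' Equalizes per-bin coverage by iteratively dividing the matrix by its
#' row-sum deviations. Bins with fewer than \code{minNnz} nonzero entries
#' (or zero total) are masked and excluded from the convergence criterion.
#' The balanced layer is scaled so unmasked row sums equal 1.
#'
#' @param map [ContactMap-class]
#' @param maxIter maximum iterations
#' @param tol relative row-sum tolerance for convergence
#' @param minNnz minimum nonzero entries per kept bin
#' @return map with balanced layer, mask and convergence flag set
#' @export
balanceICE <- function(map, maxIter = 200, tol = 1e-5, minNnz = 10) {
  m <- contactCounts(map)
  n <- nrow(m)
  nnz <- rowSums(m > 0)
  mask <- nnz >= min(minNnz, max(1, n - 1)) & rowSums(m) > 0
  w <- m
  w[!mask, ] <- 0
  w[, !mask] <- 0
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    s <- rowSums(w)
    su <- s[mask]
    if (!length(su)) break
    dev <- su / mean(su)
    if (max(abs(dev - 1)) < tol) { converged <- TRUE; break }
    b <- rep(1, n)
    b[mask] <- dev
    w <- w / outer(b, b)
  }
  if (!converged && length(su))
    warnf("ICE did not converge in %d iterations (max dev %.2g)",
          maxIter, max(abs(dev - 1)))
  s <- rowSums(w)
  scale <- mean(s[mask])
  if (is.finite(scale) && scale > 0) w <- w / scale
  w[!mask, ] <- NA_real_
  w[, !mask] <- NA_real_
  map@balanced <- w
  map@mask <- mask
  map@converged <- converged
  validObject(map)
  map
}

#' log2 differential contact map
#'
#' \code{log2((a + pc) / (b + pc))} entry-wise on balanced layers scaled to
#' equal total signal; entries involving a bin masked in either map are NA.
#'
#' @param a,b [ContactMap-class] with identical bins, both balanced
#' @param pseudocount added to both layers, in units of the mean
#'   off-diagonal balanced value (default 0.01)
#' @return matrix of log2 ratios
#' @export
differentialMap <- function(a, b, pseudocount = 0.01) {
  if (!identical(dim(contactCounts(a)), dim(contactCounts(b))) ||
      length(binRanges(a)) != length(binRanges(b)) ||
      any(as.character(seqnames(binRanges(a))) !=
          as.character(seqnames(binRanges(b)))) ||
      any(start(binRanges(a)) != start(binRanges(b))))
    stopf("bin mismatch between maps")
  ma <- balancedCounts(a); mb <- balancedCounts(b)
  if (is.null(ma) || is.null(mb)) stopf("both maps must be balanced")
  # symmetric rescaling to the geometric mean of the totals, so
  # differentialMap(a, b) == -differentialMap(b, a) exactly
  ok <- !is.na(ma) & !is.na(mb)
  s <- sqrt(sum(mb[ok]) / sum(ma[ok]))
  ma <- ma * s
  mb <- mb / s
  pc <- pseudocount * mean(c(ma[ok & upper.tri(ma)], mb[ok & upper.tri(mb)]))
  out <- log2((ma + pc) / (mb + pc))
  out[!ok] <- NA_real_
  out
}

#' Coarsen a map by an integer factor
#'
#' Counts are summed over factor x factor blocks within each chromosome;
#' the total count is conserved exactly.
#'
#' @param map [ContactMap-class]
#' @param factor integer >= 2 (1 returns the map unchanged)
#' @return coarsened [ContactMap-class] (unbalanced)
#' @export
coarsenMap <- function(map, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stopf("factor must be >= 1")
  if (factor == 1) return(map)
  chrom <- binChrom(map)
  # per-chromosome consecutive-bin grouping
  grp <- integer(length(chrom))
  newChrom <- character(0)
  off <- 0L
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    g <- (seq_along(ix) - 1L) %/% factor + 1L
    grp[ix] <- g + off
    newChrom <- c(newChrom, rep(ch, max(g)))
    off <- off + max(g)
  }
  m <- contactCounts(map)
  agg <- rowsum(m, grp)
  agg <- t(rowsum(t(agg), grp))
  res <- mapResolution(map) * factor
  starts <- unlist(lapply(unique(newChrom), function(ch)
    (seq_len(sum(newChrom == ch)) - 1) * res + 1), use.names = FALSE)
  contactMap(agg, res, newChrom, starts)
}
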