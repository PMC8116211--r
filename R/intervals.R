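## Genomic interval I/O and the peak/compartment/pericentromere statistics.
## Intervals are GRanges internally (1-based closed, the Bioconductor
## convention); BED (0-based half-open) and tsv1 (1-based inclusive) are
## converted at the I/O boundary.

#' Read a BED-like interval file
#'
#' Supports two dialects: \code{"bed0"}, classic BED with 0-based half-open
#' coordinates, and \code{"tsv1"}, a tab-separated table with 1-based
#' inclusive coordinates (the convention of many supplementary tables). A
#' fourth column, if present and numeric, is kept as \code{score}. With
#' \code{dialect = "auto"} the file is sniffed: a header line or any
#' start equal to 1 selects tsv1.
#'
#' @param path file path
#' @param dialect "bed0", "tsv1" or "auto"
#' @param assembly optional [GenomeAssembly-class] used to validate
#'   chromosome names and interval bounds
#' @return GRanges (possibly empty), sorted by (chrom, start)
#' @export
readBed <- function(path, dialect = c("auto", "bed0", "tsv1"),
                    assembly = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  header <- FALSE
  if (length(lines)) {
    f1 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(f1) >= 3 && is.na(suppressWarnings(as.numeric(f1[2]))))
      header <- TRUE
  }
  if (dialect == "auto") {
    body <- if (header) lines[-1] else lines
    starts <- suppressWarnings(as.numeric(
      vapply(strsplit(body, "\t", fixed = TRUE), function(x)
        if (length(x) >= 2) x[2] else NA_character_, "")))
    dialect <- if (header || any(starts == 1, na.rm = TRUE)) "tsv1" else "bed0"
  }
  if (header) { lines <- lines[-1]; lineno <- lineno[-1] }
  if (!length(lines)) {
    gr <- GRanges()
    mcols(gr)$score <- numeric(0)
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stopf("malformed line %d: fewer than 3 fields", lineno[which(nf < 3)[1]])
  chrom <- vapply(fields, `[`, "", 1)
  s <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stopf("malformed line %d: non-numeric coordinates", lineno[bad[1]])
  if (dialect == "bed0") s <- s + 1  # to 1-based closed
  bad <- which(e < s)
  if (length(bad))
    stopf("validation error at line %d: start >= end", lineno[bad[1]])
  score <- rep(NA_real_, length(s))
  has4 <- nf >= 4
  score[has4] <- suppressWarnings(as.numeric(
    vapply(fields[has4], `[`, "", 4)))
  gr <- GRanges(chrom, IRanges(s, e), score = score)
  if (!is.null(assembly)) validateIntervals(gr, assembly)
  sort(gr)
}

#' Write intervals as BED (0-based half-open) or tsv1 (1-based inclusive)
#'
#' @param gr GRanges
#' @param path output path
#' @param dialect "bed0" or "tsv1"
#' @export
writeBed <- function(gr, path, dialect = c("bed0", "tsv1")) {
  dialect <- match.arg(dialect)
  s <- start(gr); e <- end(gr)
  if (dialect == "bed0") s <- s - 1
  df <- data.frame(chrom = as.character(seqnames(gr)), start = s, end = e)
  if (!is.null(mcols(gr)$score) && any(!is.na(mcols(gr)$score)))
    df$score <- mcols(gr)$score
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validateIntervals <- function(gr, assembly) {
  chroms <- as.character(seqnames(gr))
  unknown <- setdiff(unique(chroms), names(assembly@seqlengths))
  if (length(unknown))
    stopf("chromosome absent from assembly: %s", unknown[1])
  lens <- assembly@seqlengths[chroms]
  if (any(end(gr) > lens))
    stopf("interval exceeds chromosome length on %s",
          chroms[which(end(gr) > lens)[1]])
  invisible(TRUE)
}

#' Partition peaks by overlap with an annotation
#'
#' A peak is "inside" iff it overlaps the annotation by at least
#' \code{minOverlap} bp (\code{mode = "any"}), or iff its midpoint falls in
#' the annotation (\code{mode = "midpoint"}). Inside and outside partition
#' the input exactly.
#'
#' @param peaks GRanges of peaks
#' @param annotation GRanges of annotation intervals (e.g. pericentromeric
#'   heterochromatin)
#' @param minOverlap minimum overlap in bp (mode "any")
#' @param mode overlap mode
#' @param assembly optional [GenomeAssembly-class]; chromosomes in
#'   \code{peaks} absent from it raise an error
#' @return list(inside = GRanges, outside = GRanges)
#' @export
classifyByAnnotation <- function(peaks, annotation, minOverlap = 1,
                                 mode = c("any", "midpoint"),
                                 assembly = NULL) {
  mode <- match.arg(mode)
  if (!is.null(assembly)) validateIntervals(peaks, assembly)
  if (length(peaks) == 0)
    return(list(inside = peaks, outside = peaks))
  query <- if (mode == "midpoint") {
    GRanges(seqnames(peaks), IRanges(mid(ranges(peaks)), width = 1))
  } else peaks
  inside <- overlapsAny(query, annotation,
                        minoverlap = if (mode == "any") minOverlap else 1L)
  list(inside = peaks[inside], outside = peaks[!inside])
}

#' Box-plot summary of interval widths
#'
#' Median, quartiles (linear-interpolation quantiles, R type 7), IQR
#' whiskers at Q1 - 1.5 IQR and Q3 + 1.5 IQR, and outliers beyond the
#' whiskers.
#'
#' @param gr non-empty GRanges
#' @return list with median, q1, q3, iqr, whiskerLow, whiskerHigh,
#'   outliers, n
#' @export
widthStats <- function(gr) {
  if (length(gr) == 0) stopf("width statistics of an empty interval set")
  w <- width(gr)
  q <- quantile(w, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whiskerLow = lo, whiskerHigh = hi,
       outliers = w[w < lo | w > hi], n = length(w))
}

#' Assign peaks to A/B compartments
#'
#' Each peak is labelled by the compartment of the bin containing its
#' midpoint (default) or by the compartment overlapping the majority of its
#' length. Peaks in bins with undefined score, or on chromosomes absent
#' from the track, are labelled \code{"unassigned"}.
#'
#' @param peaks GRanges
#' @param track [CompartmentTrack-class]
#' @param mode "midpoint" or "majority"
#' @return \code{peaks} with a \code{compartment} metadata column
#'   ("A", "B" or "unassigned")
#' @export
assignToCompartments <- function(peaks, track,
                                 mode = c("midpoint", "majority")) {
  mode <- match.arg(mode)
  bins <- binRanges(track)
  lab <- compartmentLabels(track)
  out <- rep("unassigned", length(peaks))
  if (length(peaks)) {
    if (mode == "midpoint") {
      pts <- GRanges(seqnames(peaks), IRanges(mid(ranges(peaks)), width = 1))
      hits <- findOverlaps(pts, bins, select = "first")
      ok <- !is.na(hits)
      hl <- lab[hits[ok]]
      out[ok][!is.na(hl)] <- hl[!is.na(hl)]
    } else {
      hits <- findOverlaps(peaks, bins)
      if (length(hits)) {
        ov <- width(GenomicRanges::pintersect(
          peaks[queryHits(hits)], bins[subjectHits(hits)]))
        hl <- lab[subjectHits(hits)]
        keep <- !is.na(hl)
        if (any(keep)) {
          df <- data.frame(peak = queryHits(hits)[keep], lab = hl[keep],
                           ov = ov[keep])
          agg <- aggregate(ov ~ peak + lab, df, sum)
          agg <- agg[order(agg$peak, -agg$ov), ]
          best <- agg[!duplicated(agg$peak), ]
          out[best$peak] <- best$lab
        }
      }
    }
  }
  mcols(peaks)$compartment <- out
  peaks
}

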