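# Fixtures built in code; no binary files.

suppressPackageStartupMessages(library(GenomicRanges))

# brute-force O(n*m) overlap oracle on plain data.frames
bruteOverlap <- function(peaks, annot, minOverlap = 1) {
  inside <- logical(length(peaks))
  for (i in seq_along(peaks)) {
    for (j in seq_along(annot)) {
      if (as.character(seqnames(peaks)[i]) !=
          as.character(seqnames(annot)[j])) next
      ov <- min(end(peaks)[i], end(annot)[j]) -
        max(start(peaks)[i], start(annot)[j]) + 1
      if (ov >= minOverlap) { inside[i] <- TRUE; break }
    }
  }
  inside
}

randomIntervals <- function(n, chroms = c("c1", "c2"), maxPos = 1e5,
                            maxWidth = 500) {
  s <- sample.int(maxPos, n, replace = TRUE)
  w <- sample.int(maxWidth, n, replace = TRUE)
  GRanges(sample(chroms, n, replace = TRUE), IRanges(s, s + w))
}

# small deterministic contact map with planted two-block checkerboard
checkerMap <- function(nBins = 60, blocks = 2, contrast = 2, gamma = -1,
                       depth = 5e5, noise = FALSE, seed = 1) {
  profile <- rep(rep_len(c("A", "B"), blocks),
                 each = ceiling(nBins / blocks))[seq_len(nBins)]
  makeSyntheticMap(nBins = nBins, profile = profile, contrast = contrast,
                   gamma = gamma, depth = depth, noise = noise, seed = seed)
}

quietBalance <- function(map, ...) suppressWarnings(balanceICE(map, ...))
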