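## Seed-deterministic synthetic data: contact maps with power-law decay,
## checkerboard compartments, optional pericentromeric block, TAD
## boundaries and Poisson noise; and BED-like peak/annotation/compartment
## tables with planted fractions. Ground truth is always returned.

#' Synthetic assembly: two 20-Mb chromosomes
#'
#' The first \code{pericentromereBp} of each chromosome is annotated as
#' pericentromeric heterochromatin (the apical, centromere-proximal side).
#'
#' @param nChromosomes number of chromosomes
#' @param chromLength chromosome length in bp
#' @return [GenomeAssembly-class]
#' @export
syntheticAssembly <- function(nChromosomes = 2, chromLength = 2e7) {
  GenomeAssembly("synthetic",
                 setNames(rep(chromLength, nChromosomes),
                          paste0("chrS", seq_len(nChromosomes))))
}

#' Synthetic Hi-C map with planted compartments
#'
#' Expected counts: \code{E_ij = depthScale * s^gamma * m_ij} with s the
#' bin separation, where \code{m_ij = contrast} for same-compartment
#' pairs (additionally multiplied by \code{bWeakening} when both bins are
#' B), 1 for A/B pairs. Optional TAD boundaries deplete crossing contacts
#' at short range. Counts are Poisson draws around the expectation
#' (\code{noise = FALSE} returns the expectation itself for exact
#' checks). The planted compartment track is returned alongside.
#'
#' @param nBins number of bins (one chromosome)
#' @param resolution bin size in bp
#' @param gamma decay exponent (< 0)
#' @param blockBins compartment block length in bins
#' @param profile optional explicit A/B label vector (overrides blockBins)
#' @param contrast within-compartment enrichment factor c (>= 1)
#' @param bWeakening multiplier beta on B-B enrichment only (0 < beta <= 1)
#' @param boundaries optional bin indices of TAD boundaries
#' @param boundaryDepletion factor on short-range boundary-crossing pairs
#' @param boundaryRange range (bins) of the depletion
#' @param depth total expected count over the upper triangle
#' @param noise Poisson noise (TRUE) or exact expectations (FALSE)
#' @param seed RNG seed
#' @param chrom chromosome name
#' @return list(map = [ContactMap-class], track = [CompartmentTrack-class],
#'   expected = matrix)
#' @export
makeSyntheticMap <- function(nBins = 200, resolution = 1e4, gamma = -1,
                             blockBins = 20, profile = NULL, contrast = 2,
                             bWeakening = 1, boundaries = NULL,
                             boundaryDepletion = 0.5, boundaryRange = 20,
                             depth = 1e6, noise = TRUE, seed = 1,
                             chrom = "chrS1") {
  if (gamma >= 0) stopf("gamma must be < 0")
  if (contrast < 1) stopf("contrast must be >= 1")
  if (bWeakening <= 0 || bWeakening > 1)
    stopf("bWeakening must be in (0, 1]")
  if (depth <= 0) stopf("depth must be > 0")
  set.seed(as.integer(seed %% 2147483647))
  if (is.null(profile)) {
    # randomized block lengths (geometric around blockBins, min half) so
    # the same-compartment fraction decorrelates with separation, as in
    # real maps, instead of oscillating with a fixed period
    lens <- integer(0)
    while (sum(lens) < nBins)
      lens <- c(lens, max(ceiling(blockBins / 2),
                          rpois(1, blockBins)))
    profile <- rep(rep_len(c("A", "B"), length(lens)), lens)[seq_len(nBins)]
  }
  stopifnot(length(profile) == nBins)
  s <- abs(outer(seq_len(nBins), seq_len(nBins), "-"))
  sfac <- pmax(s, 1)^gamma
  same <- outer(profile, profile, "==")
  bothB <- outer(profile == "B", profile == "B", "&")
  m <- ifelse(same, contrast, 1) * ifelse(bothB, bWeakening, 1)
  if (!is.null(boundaries)) {
    for (b in boundaries) {
      cross <- outer(seq_len(nBins) <= b, seq_len(nBins) > b, "&")
      cross <- (cross | t(cross)) & s <= boundaryRange
      m[cross] <- m[cross] * boundaryDepletion
    }
  }
  expect <- sfac * m
  expect <- expect * (depth / sum(expect[upper.tri(expect, diag = TRUE)]))
  if (noise) {
    up <- upper.tri(expect, diag = TRUE)
    counts <- matrix(0, nBins, nBins)
    counts[up] <- rpois(sum(up), expect[up])
    counts <- counts + t(counts) - diag(diag(counts))
  } else counts <- expect
  map <- contactMap(counts, resolution, chrom)
  score <- ifelse(profile == "A", 1, -1)
  track <- compartmentTrack(rep(chrom, nBins),
                            (seq_len(nBins) - 1) * resolution + 1,
                            score, resolution)
  list(map = map, track = track, expected = expect)
}

#' Paired control / knockdown-like synthetic maps
#'
#' Two maps sharing the compartment profile and a seed-split RNG: the
#' perturbed ("kd") map has decay exponent \code{gamma + gammaShift}
#' (milder decay for positive shift) and B-B enrichment multiplied by
#' \code{beta}.
#'
#' @param nBins,resolution,gamma,blockBins,contrast,depth,noise,seed as in
#'   [makeSyntheticMap()]
#' @param gammaShift added to gamma for the kd map (gamma + shift < 0)
#' @param beta B-B weakening of the kd map
#' @return list(control, kd, track) where control/kd are
#'   [ContactMap-class]
#' @export
pairedConditionMaps <- function(nBins = 300, resolution = 1e4, gamma = -1,
                                blockBins = 20, contrast = 2,
                                gammaShift = 0, beta = 0.8, depth = 1e6,
                                noise = TRUE, seed = 1) {
  if (gamma + gammaShift >= 0) stopf("gamma + gammaShift must be < 0")
  # both conditions share one compartment profile; only the RNG is split
  probe <- makeSyntheticMap(nBins, resolution, gamma, blockBins,
                            depth = 1, noise = FALSE, seed = seed)
  profile <- ifelse(compartmentLabels(probe$track) %in% "A", "A", "B")
  ctrl <- makeSyntheticMap(nBins, resolution, gamma, profile = profile,
                           contrast = contrast, bWeakening = 1,
                           depth = depth, noise = noise,
                           seed = childSeed(seed, 1))
  kd <- makeSyntheticMap(nBins, resolution, gamma + gammaShift,
                         profile = profile,
                         contrast = contrast, bWeakening = beta,
                         depth = depth, noise = noise,
                         seed = childSeed(seed, 2))
  list(control = ctrl$map, kd = kd$map, track = ctrl$track)
}

#' Synthetic peak / annotation / compartment tables
#'
#' Emulates the supplementary-table inputs: a pericentromeric annotation
#' (the first \code{pericentromereBp} of each chromosome), a compartment
#' score table of alternating A/B blocks along the arms, and a peak table
#' with a planted pericentromeric fraction. Peak widths are drawn from a
#' log-normal via a seed-permuted quantile grid (stratified sampling), per
#' destination class, so planted medians are reproduced essentially
#' exactly: \code{widthMedianPeri} for pericentromeric peaks (broader),
#' \code{widthMedianB} for arm peaks in B bins, \code{widthMedianA} for
#' arm peaks in A bins.
#'
#' @param nPeaks total number of peaks
#' @param fractionPericentromeric planted fraction of peaks inside the
#'   pericentromeric annotation; the planted count is
#'   \code{round(nPeaks * fraction)}
#' @param widthMedianPeri,widthMedianB,widthMedianA median widths (bp)
#' @param widthSigma log-normal sigma (log scale)
#' @param assembly [GenomeAssembly-class]
#' @param pericentromereBp pericentromeric span per chromosome
#' @param compartmentResolution compartment bin size (bp)
#' @param compartmentBlockBp A/B block length along arms (bp)
#' @param armBFraction fraction of arm peaks directed to B bins
#' @param seed RNG seed
#' @param dir optional directory: writes peaks.bed, pericentromere.bed,
#'   compartments.tsv
#' @return list(peaks, pericentromere (GRanges), compartments
#'   ([CompartmentTrack-class]), assembly, files)
#' @export
makeSyntheticTables <- function(nPeaks = 6607,
                                fractionPericentromeric = 4394 / 6607,
                                widthMedianPeri = 2000, widthMedianB = 730,
                                widthMedianA = 500, widthSigma = 0.5,
                                assembly = syntheticAssembly(),
                                pericentromereBp = 4e6,
                                compartmentResolution = 1e4,
                                compartmentBlockBp = 2e5,
                                armBFraction = 0.5, seed = 1,
                                dir = NULL) {
  if (fractionPericentromeric < 0 || fractionPericentromeric > 1)
    stopf("fraction must be in [0, 1]")
  set.seed(as.integer(seed %% 2147483647))
  chroms <- names(assembly@seqlengths)
  lens <- assembly@seqlengths
  peri <- GRanges(chroms, IRanges(1, pmin(pericentromereBp, lens)))
  # compartment track: pericentromeric bins undefined, arms alternate A/B
  binList <- lapply(chroms, function(ch) {
    starts <- seq(1, lens[[ch]], by = compartmentResolution)
    block <- ((starts - 1) %/% compartmentBlockBp) %% 2
    score <- ifelse(block == 0, 1, -1)
    score[starts <= pericentromereBp] <- NA_real_
    data.frame(chrom = ch, start = starts, score = score)
  })
  binDf <- do.call(rbind, binList)
  compTrack <- compartmentTrack(binDf$chrom, binDf$start, binDf$score,
                                compartmentResolution)
  nIn <- round(nPeaks * fractionPericentromeric)
  nOut <- nPeaks - nIn
  qgrid <- function(n, medianW) {
    if (n == 0) return(numeric(0))
    w <- exp(log(medianW) + widthSigma * qnorm((seq_len(n) - 0.5) / n))
    round(pmax(w[sample.int(n)], 50))
  }
  place <- function(n, where) {
    if (n == 0) return(GRanges())
    w <- width(where)
    pick <- sample.int(length(where), n, replace = TRUE, prob = w)
    off <- floor(runif(n) * (w[pick] - 1))
    GRanges(seqnames(where)[pick],
            IRanges(start(where)[pick] + off, width = 1))
  }
  inMid <- place(nIn, peri)
  arms <- GRanges(chroms, IRanges(pericentromereBp + 1, lens))
  # direct arm peaks to A or B bins so per-class width medians are planted
  bins <- binRanges(compTrack)
  lab <- compartmentLabels(compTrack)
  # margin keeps arm peaks clear of the pericentromere boundary so the
  # planted inside/outside counts are recovered exactly by any-overlap
  margin <- 4 * max(widthMedianPeri, widthMedianB, widthMedianA)
  clear <- start(bins) > pericentromereBp + margin
  armB <- bins[lab %in% "B" & clear]
  armA <- bins[lab %in% "A" & clear]
  nB <- round(nOut * armBFraction); nA <- nOut - nB
  outMid <- c(place(nB, armB), place(nA, armA))
  widths <- c(qgrid(nIn, widthMedianPeri), qgrid(nB, widthMedianB),
              qgrid(nA, widthMedianA))
  mids <- c(inMid, outMid)
  half <- floor((widths - 1) / 2)
  s <- pmax(start(mids) - half, 1)
  e <- pmin(s + widths - 1, lens[as.character(seqnames(mids))])
  peaks <- GRanges(seqnames(mids), IRanges(s, e))
  # keep midpoints where they were planted: clipping at chromosome edges
  # is negligible by construction (pericentromere is interior)
  mcols(peaks)$score <- widths
  peaks <- sort(peaks)
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(peaks = file.path(dir, "peaks.bed"),
                  pericentromere = file.path(dir, "pericentromere.bed"),
                  compartments = file.path(dir, "compartments.tsv"))
    writeBed(peaks, files$peaks, "bed0")
    writeBed(peri, files$pericentromere, "bed0")
    tb <- binRanges(compTrack)
    df <- data.frame(chrom = as.character(seqnames(tb)), start = start(tb),
                     end = end(tb), score = mcols(tb)$score)
    write.table(df, files$compartments, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = c("chrom", "start", "end",
                                                 "score"))
  }
  list(peaks = peaks, pericentromere = peri, compartments = compTrack,
       assembly = assembly, files = files)
}
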