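## Block-copolymer Monte-Carlo simulator: chromosomes as chains of A/B/C
## beads with square-well attractions, soft-core repulsion and harmonic
## bonds inside a hard extensibility window, optionally confined in a
## cylindrical nucleus whose apical cap attracts C (pericentromeric /
## telomeric) beads -- the Rabl configuration.

#' Type-pair interaction energy table
#'
#' Attraction depths in kT (depth convention: values >= 0, 0 = purely
#' repulsive). Defaults are the whole-genome control parameterization
#' selected by the shipped grid-search utility to give arm-like scaling
#' and compartment strength.
#'
#' @param AA,AB,BB,AC,BC,CC square-well depths in kT
#' @param surfC apical-surface attraction of C beads in kT
#' @return [TypeEnergyTable-class]
#' @export
typeEnergyTable <- function(AA = 0.2, AB = 0.05, BB = 0.35, AC = 0.05,
                            BC = 0.05, CC = 1.5, surfC = 4.0) {
  new("TypeEnergyTable",
      eps = c(AA = AA, AB = AB, BB = BB, AC = AC, BC = BC, CC = CC),
      epsSurfC = surfC)
}

#' Region-model base energies
#'
#' Default attraction depths for the two-type (A/B) region chain used in
#' the copolymer phase sweeps: globally attractive with a same-type
#' preference, placed so that halving all depths swells the chain and
#' strengthens relative compartmentalization while increasing them
#' compacts and mixes it. Selected with [energyGridSearch()].
#'
#' @return [TypeEnergyTable-class]
#' @export
regionBaseEnergies <- function() {
  typeEnergyTable(AA = 0.75, AB = 0.5, BB = 0.9,
                  AC = 0, BC = 0, CC = 0, surfC = 0)
}

#' Grid search over candidate energy tables
#'
#' Small utility used to select default energy tables: runs
#' [sweepEnergies()] for each candidate and reports the summary table,
#' letting the caller pick the candidate whose sweep shows the desired
#' scaling/strength behavior.
#'
#' @param seq [BeadTypeSequence-class]
#' @param candidates list of [TypeEnergyTable-class]
#' @param multipliers sweep multipliers
#' @param confinement [ConfinementSpec-class]
#' @param config [SimulationConfig-class]
#' @param seeds replicate seeds per point
#' @return data.frame with one row per (candidate, multiplier, seed)
#' @export
energyGridSearch <- function(seq, candidates, multipliers, confinement,
                             config, seeds = 2) {
  out <- lapply(seq_along(candidates), function(i) {
    sw <- sweepEnergies(seq, candidates[[i]], multipliers, confinement,
                        config, seeds = seeds)
    sw$candidate <- i
    sw
  })
  do.call(rbind, out)
}

#' Heterochromatin-loss ("mutant") energy transform
#'
#' Multiplies the C-C attraction and the C-bead surface attraction by
#' \code{cFactor}, leaving all other entries unchanged. \code{cFactor = 1}
#' is the identity; 0 removes heterochromatic interactions entirely.
#'
#' @param energies [TypeEnergyTable-class]
#' @param cFactor multiplier in [0, 1]
#' @return transformed [TypeEnergyTable-class]
#' @export
mutantTransform <- function(energies, cFactor) {
  if (cFactor < 0 || cFactor > 1) stopf("cFactor must be in [0, 1]")
  energies@eps["CC"] <- energies@eps["CC"] * cFactor
  energies@epsSurfC <- energies@epsSurfC * cFactor
  validObject(energies)
  energies
}

#' Scale attraction depths by a multiplier
#'
#' @param energies [TypeEnergyTable-class]
#' @param m multiplier > 0
#' @param pairs which entries to scale (default all six type pairs)
#' @return scaled table (surface attraction untouched)
#' @export
scaleEnergies <- function(energies, m,
                          pairs = c("AA", "AB", "BB", "AC", "BC", "CC")) {
  if (m < 0) stopf("multiplier must be >= 0")
  energies@eps[pairs] <- energies@eps[pairs] * m
  validObject(energies)
  energies
}

#' Simulation configuration
#'
#' @param nSweeps production sweeps
#' @param equilibrationSweeps discarded sweeps
#' @param sampleInterval sweeps between samples
#' @param seed mandatory RNG seed
#' @param bondLength bond rest length (sigma)
#' @param excludedVolume soft-core cap (kT)
#' @param attractionRange square-well range (sigma)
#' @return [SimulationConfig-class]
#' @export
simulationConfig <- function(nSweeps = 2000, equilibrationSweeps = 1000,
                             sampleInterval = 10, seed,
                             bondLength = 1, excludedVolume = 4,
                             attractionRange = 1.5) {
  if (missing(seed)) stopf("seed is mandatory")
  new("SimulationConfig", bondLength = bondLength,
      excludedVolume = excludedVolume, attractionRange = attractionRange,
      nSweeps = nSweeps, equilibrationSweeps = equilibrationSweeps,
      sampleInterval = sampleInterval, seed = seed)
}

#' Cylindrical confinement sized to a packing fraction
#'
#' The cylinder volume is set so that nBeads spheres of diameter sigma
#' occupy \code{packingFraction} of it, with height = aspect * radius. The
#' apical cap is the top disc (z = height).
#'
#' @param nBeads number of beads
#' @param packingFraction bead volume fraction (default 0.1)
#' @param aspect height / radius (default 2: a squat nucleus that leaves
#'   lateral room for chromosome territories)
#' @return [ConfinementSpec-class]
#' @export
autoConfinement <- function(nBeads, packingFraction = 0.1, aspect = 2) {
  vol <- nBeads * pi / 6 / packingFraction
  r <- (vol / (pi * aspect))^(1 / 3)
  new("ConfinementSpec", shape = "cylinder", radius = r, height = aspect * r)
}

#' No confinement (region models)
#' @return [ConfinementSpec-class] with shape "none"
#' @export
noConfinement <- function() new("ConfinementSpec", shape = "none")

#' Box confinement
#' @param box numeric(3) edge lengths
#' @return [ConfinementSpec-class]
#' @export
boxConfinement <- function(box) {
  new("ConfinementSpec", shape = "box", box = box)
}

#' Whole-genome bead-type template
#'
#' Each chromosome is telomere (C) - arm (A/B) - centromere (C) - arm -
#' telomere (C). Arm patterns come from \code{pattern} (a character vector
#' of A/B recycled per arm, e.g. from a compartment track's labels) or
#' default to alternating A/B blocks of \code{blockBeads}.
#'
#' @param nChromosomes number of chains
#' @param armBeads beads per arm
#' @param centromereBeads C beads in the central block
#' @param telomereBeads C beads at each end
#' @param pattern optional A/B vector for the arms (length <= armBeads
#'   prefix is tiled; longer than armBeads is an error)
#' @param blockBeads A/B block length for the synthetic alternation
#' @param beadSize bead size in bp
#' @return [BeadTypeSequence-class] with segment annotation
#' @export
buildGenomeTemplate <- function(nChromosomes = 4, armBeads = 130,
                                centromereBeads = 10, telomereBeads = 5,
                                pattern = NULL, blockBeads = 10,
                                beadSize = 1e4) {
  if (min(nChromosomes, armBeads, centromereBeads, telomereBeads) < 1)
    stopf("all counts must be >= 1")
  if (!is.null(pattern)) {
    if (length(pattern) > armBeads)
      stopf("arm pattern longer than armBeads")
    if (!all(pattern %in% c("A", "B"))) stopf("pattern must be A/B")
  }
  armPattern <- function() {
    if (!is.null(pattern)) rep_len(pattern, armBeads)
    else rep(rep(c("A", "B"), length.out = ceiling(armBeads / blockBeads)),
             each = blockBeads)[seq_len(armBeads)]
  }
  chains <- list(); segments <- list()
  for (k in seq_len(nChromosomes)) {
    ch <- c(rep("C", telomereBeads), armPattern(),
            rep("C", centromereBeads), armPattern(),
            rep("C", telomereBeads))
    sg <- c(rep("tel", telomereBeads), rep("arm", armBeads),
            rep("cen", centromereBeads), rep("arm", armBeads),
            rep("tel", telomereBeads))
    chains[[k]] <- ch; segments[[k]] <- sg
  }
  new("BeadTypeSequence", chains = chains, segments = segments,
      beadSize = beadSize)
}

#' Single-chain A/B region template
#'
#' @param types character vector over {A,B} (or {A,B,C})
#' @param beadSize bead size in bp (region models use 40 kb)
#' @return [BeadTypeSequence-class]
#' @export
regionChain <- function(types, beadSize = 4e4) {
  new("BeadTypeSequence", chains = list(types), beadSize = beadSize)
}

#' Alternating A/B block pattern
#' @param nBeads chain length
#' @param blockBeads block length
#' @return character vector
#' @export
alternatingBlocks <- function(nBeads, blockBeads = 15) {
  rep(rep(c("A", "B"), length.out = ceiling(nBeads / blockBeads)),
      each = blockBeads)[seq_len(nBeads)]
}

# Rabl-like initial conformation: centromeric block apical (high z), arms
# extended toward the basal cap, each chain in its own angular sector.
# Bonds are exactly bondLength; all beads strictly inside the volume.
rablInit <- function(seq, conf, bondLength, seed) {
  chains <- beadChains(seq)
  nc <- length(chains)
  rng <- function(k) ((seed * 2654435761 + k * 40503) %% 1e6) / 1e6
  height <- conf@height; radius <- conf@radius
  margin <- min(1, radius * 0.2)
  out <- matrix(0, sum(lengths(chains)), 3)
  row <- 1
  for (c in seq_len(nc)) {
    ch <- chains[[c]]
    n <- length(ch)
    ang <- 2 * pi * (c - 1) / nc
    rad <- radius * 0.55
    cx <- rad * cos(ang); cy <- rad * sin(ang)
    # target z path: rise to the apical cap at the chain centre, descend;
    # laterally the path converges on the cylinder axis near the apex so
    # all centromeric blocks seed one apical chromocenter
    half <- ceiling(n / 2)
    zhi <- height - 0.6; zlo <- 0.6
    ztar <- c(seq(zlo, zhi, length.out = half),
              seq(zhi, zlo, length.out = n - half + 1)[-1])
    if (n == 1) ztar <- (zlo + zhi) / 2
    pull <- (ztar - zlo) / (zhi - zlo)  # 1 at the apex
    cxs <- cx * (1 - 0.9 * pull)
    cys <- cy * (1 - 0.9 * pull)
    pos <- matrix(0, n, 3)
    pos[1, ] <- c(cxs[1], cys[1], ztar[1])
    for (i in seq_len(n - 1)) {
      jit <- 0.4 * c(rng(row + 2 * i) - 0.5, rng(row + 2 * i + 1) - 0.5, 0)
      w <- c(cxs[i + 1], cys[i + 1], ztar[i + 1]) + jit
      d <- w - pos[i, ]
      nrm <- sqrt(sum(d^2))
      if (nrm < 1e-9) d <- c(0, 0, bondLength) else d <- d / nrm * bondLength
      cand <- pos[i, ] + d
      cand[3] <- max(min(cand[3], height - 0.1), 0.1)
      r2 <- cand[1]^2 + cand[2]^2
      if (r2 > (radius - margin)^2) {
        s <- (radius - margin) / sqrt(r2)
        cand[1] <- cand[1] * s; cand[2] <- cand[2] * s
      }
      # exact bond after clamping
      d <- cand - pos[i, ]
      cand <- pos[i, ] + d / sqrt(sum(d^2)) * bondLength
      pos[i + 1, ] <- cand
    }
    out[row:(row + n - 1), ] <- pos
    row <- row + n
  }
  out
}

# free-space initial conformation: seeded random-direction growth with
# overlap avoidance (retries directions landing within 0.9 sigma of any
# earlier bead), giving a swollen-coil start close to equilibrium
walkInit <- function(seq, bondLength, seed) {
  chains <- beadChains(seq)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  out <- matrix(0, sum(lengths(chains)), 3)
  row <- 1
  for (c in seq_along(chains)) {
    n <- length(chains[[c]])
    pos <- matrix(0, n, 3)
    pos[1, ] <- c(10 * c, 0, 0)
    for (i in seq_len(n - 1)) {
      for (try in 1:30) {
        d <- rnorm(3)
        cand <- pos[i, ] + bondLength * d / sqrt(sum(d^2))
        prev <- pos[seq_len(max(1, i - 1)), , drop = FALSE]
        mind <- min(sqrt(rowSums((prev - matrix(cand, nrow(prev), 3,
                                                byrow = TRUE))^2)))
        if (mind > 0.9 * bondLength) break
      }
      pos[i + 1, ] <- cand
    }
    out[row:(row + n - 1), ] <- pos
    row <- row + n
  }
  out
}

#' Run the Metropolis Monte-Carlo simulation
#'
#' Single-bead displacement Metropolis MC. Pair energy: soft-core
#' repulsion capped at \code{excludedVolume} kT for r < sigma plus a
#' square-well attraction for r < attractionRange (depth from the type
#' table, or per-pair energies if \code{pairEnergies} is given, where
#' negative values are attractive). C beads gain the apical-surface
#' attraction within one sigma of the top cap. Bonds are harmonic
#' (k = 50 kT/sigma^2) inside a hard window [0.7, 1.3] x bond length.
#' Identical (seed, config) give bit-identical ensembles.
#'
#' @param seq [BeadTypeSequence-class]
#' @param energies [TypeEnergyTable-class]
#' @param confinement [ConfinementSpec-class]
#' @param config [SimulationConfig-class]
#' @param pairEnergies optional nBeads x nBeads contact-energy matrix in kT
#'   (negative = attractive) overriding the type table
#' @param init optional nBeads x 3 initial coordinates; default Rabl-like
#'   when confined in a cylinder, random walk otherwise
#' @param bondK harmonic bond constant (kT/sigma^2)
#' @param useCells neighbor cell lists: NA = automatic (systems above 48
#'   beads), TRUE/FALSE force the choice (results are identical; only
#'   speed differs)
#' @return [Ensemble-class]
#' @export
runMC <- function(seq, energies, confinement, config, pairEnergies = NULL,
                  init = NULL, bondK = 50, useCells = NA) {
  chains <- beadChains(seq)
  types <- unlist(chains)
  n <- length(types)
  chainId <- rep(seq_along(chains), lengths(chains))
  typeId <- match(types, c("A", "B", "C")) - 1L
  eps <- energies@eps
  typeE <- -matrix(c(eps["AA"], eps["AB"], eps["AC"],
                     eps["AB"], eps["BB"], eps["BC"],
                     eps["AC"], eps["BC"], eps["CC"]), 3, 3)
  shape <- match(confinement@shape, c("none", "cylinder", "box")) - 1L
  if (is.na(shape)) stopf("unknown confinement shape")
  if (is.null(init)) {
    init <- if (confinement@shape == "cylinder")
      rablInit(seq, confinement, config@bondLength, config@seed)
    else walkInit(seq, config@bondLength, config@seed)
  }
  if (nrow(init) != n) stopf("init must have one row per bead")
  res <- .mc_run(init, chainId - 1L, typeId, typeE,
                 if (is.null(pairEnergies)) NULL else as.matrix(pairEnergies),
                 energies@epsSurfC, 2L,
                 bondK, config@bondLength, config@excludedVolume,
                 config@bondLength, config@attractionRange * config@bondLength,
                 shape, confinement@radius, confinement@height,
                 confinement@box[1], confinement@box[2], confinement@box[3],
                 as.integer(config@nSweeps),
                 as.integer(config@equilibrationSweeps),
                 as.integer(config@sampleInterval),
                 0.3, as.numeric(config@seed),
                 if (is.na(useCells)) -1L else as.integer(isTRUE(useCells)))
  if (res$acceptance < 0.2 || res$acceptance > 0.8)
    warnf("acceptance rate %.2f outside [0.2, 0.8] after auto-tuning",
          res$acceptance)
  prov <- list(seed = config@seed,
               configHash = hashConfig(list(
                 eps = eps, surf = energies@epsSurfC, shape = confinement@shape,
                 r = confinement@radius, h = confinement@height,
                 sweeps = config@nSweeps, equil = config@equilibrationSweeps,
                 interval = config@sampleInterval, bondK = bondK,
                 perPair = !is.null(pairEnergies))),
               acceptanceStep = res$step)
  new("Ensemble", coords = res$samples, chains = as.integer(chainId),
      types = types, acceptance = res$acceptance, provenance = prov)
}

#' Contact map of a conformational ensemble
#'
#' Contact frequency = fraction of sampled configurations with pairwise
#' distance below \code{contactRadius}; diagonal = 1. Bins are laid out
#' one pseudo-chromosome per chain.
#'
#' @param e [Ensemble-class]
#' @param contactRadius contact threshold in sigma (default 2)
#' @param beadSize bead size in bp for the bin coordinates
#' @param minSamples required number of sampled configurations
#' @return [ContactMap-class]; the balanced layer holds the frequencies
#' @export
ensembleContactMap <- function(e, contactRadius = 2, beadSize = 1e4,
                               minSamples = 50) {
  m <- dim(ensembleCoords(e))[3]
  if (m < minSamples)
    stopf("ensemble has %d samples; %d required", m, minSamples)
  freq <- .mc_contact_map(ensembleCoords(e), contactRadius)
  chrom <- paste0("chain", beadChains(e))
  map <- contactMap(freq, beadSize, chrom)
  map@balanced <- freq
  map@mask <- rep(TRUE, nrow(freq))
  map
}

#' Mean pairwise distance map of an ensemble
#'
#' @param e [Ensemble-class]
#' @param minSamples required number of sampled configurations
#' @return symmetric matrix of mean Euclidean distances (diagonal 0)
#' @export
ensembleDistanceMap <- function(e, minSamples = 50) {
  m <- dim(ensembleCoords(e))[3]
  if (m < minSamples)
    stopf("ensemble has %d samples; %d required", m, minSamples)
  .mc_distance_map(ensembleCoords(e))
}

#' Ground-truth compartment track from bead types
#'
#' Scores +1 for A beads, -1 for B beads, NA for C beads; used to measure
#' compartment strength of simulated maps against the known sequence.
#'
#' @param seq [BeadTypeSequence-class]
#' @return [CompartmentTrack-class] on the ensemble-map bins
#' @export
trackFromTypes <- function(seq) {
  chains <- beadChains(seq)
  types <- unlist(chains)
  score <- ifelse(types == "A", 1, ifelse(types == "B", -1, NA_real_))
  chrom <- paste0("chain", rep(seq_along(chains), lengths(chains)))
  pos <- unlist(lapply(lengths(chains), function(n)
    (seq_len(n) - 1) * seq@beadSize + 1), use.names = FALSE)
  compartmentTrack(chrom, pos, score, seq@beadSize)
}

#' Energy sweep: scaling exponent and compartment strength versus
#' attraction multiplier
#'
#' For each multiplier m the attraction depths (all pairs, or B-B only in
#' \code{mode = "BB"}) are scaled by m, the chain simulated, and the
#' simulated contact map summarized by its P(s) scaling exponent and
#' saddle compartment strength against the known bead-type track.
#'
#' @param seq [BeadTypeSequence-class]
#' @param base [TypeEnergyTable-class] base energies
#' @param multipliers positive multipliers
#' @param confinement [ConfinementSpec-class]
#' @param config [SimulationConfig-class]; seeds are derived per run
#' @param seeds number of replicate seeds per multiplier
#' @param mode "all" or "BB"
#' @param contactRadius contact threshold (sigma)
#' @param nQuantiles,cornerFraction saddle parameters
#' @param fitRange P(s) fit range in bp
#' @return data.frame(multiplier, seed, exponent, strengthA, strengthB,
#'   strengthOverall)
#' @export
sweepEnergies <- function(seq, base, multipliers, confinement, config,
                          seeds = 3, mode = c("all", "BB"),
                          contactRadius = 2, nQuantiles = 10,
                          cornerFraction = 0.2, fitRange = NULL) {
  mode <- match.arg(mode)
  if (any(multipliers <= 0)) stopf("multipliers must be > 0")
  track <- trackFromTypes(seq)
  n <- sum(lengths(beadChains(seq)))
  # short-to-intermediate separations discriminate between collapsed
  # states whose long-range P(s) is flat; 3 beads ~ above 100 kb at 40 kb
  if (is.null(fitRange))
    fitRange <- c(3, min(20, floor(0.8 * n))) * seq@beadSize
  rows <- list()
  for (m in multipliers) {
    en <- if (mode == "all") scaleEnergies(base, m)
          else scaleEnergies(base, m, pairs = "BB")
    for (s in seq_len(seeds)) {
      cfg <- config
      cfg@seed <- childSeed(config@seed, round(1000 * m) + s)
      ens <- runMC(seq, en, confinement, cfg)
      map <- ensembleContactMap(ens, contactRadius, seq@beadSize,
                                minSamples = 10)
      dc <- decayCurve(map, fitRange = fitRange)
      sad <- saddle(map, track, nQuantiles = nQuantiles,
                    cornerFraction = cornerFraction)
      st <- strengthReport(sad)
      rows[[length(rows) + 1]] <- data.frame(
        multiplier = m, seed = s, exponent = scalingExponent(dc),
        strengthA = st$strengthA, strengthB = st$strengthB,
        strengthOverall = st$strengthOverall)
    }
  }
  do.call(rbind, rows)
}

#' Pooled intra-arm compartment strength over replicate ensembles
#'
#' Averages the contact-frequency maps of replicate ensembles (as pooling
#' biological replicates) and computes the within-arm compartment
#' strength of the pooled map; pooling suppresses the slow
#' droplet-position fluctuations of individual runs.
#'
#' @param ensembles list of [Ensemble-class] from the same sequence
#' @param seq [BeadTypeSequence-class] with segment annotation
#' @param contactRadius contact threshold (sigma)
#' @return strength report list (as in [saddle()])
#' @export
pooledIntraArmStrength <- function(ensembles, seq, contactRadius = 2) {
  maps <- lapply(ensembles, function(e)
    .mc_contact_map(ensembleCoords(e), contactRadius))
  avg <- Reduce(`+`, maps) / length(maps)
  seg <- unlist(seq@segments)
  chain <- rep(seq_along(beadChains(seq)), lengths(beadChains(seq)))
  armRun <- cumsum(c(1, diff(as.integer(factor(paste(chain, seg)))) != 0))
  armChrom <- paste0("seg", armRun)
  map <- contactMap(avg, seq@beadSize, armChrom)
  map@balanced <- avg
  map@mask <- rep(TRUE, nrow(avg))
  types <- unlist(beadChains(seq))
  score <- ifelse(types == "A", 1, ifelse(types == "B", -1, NA_real_))
  track <- compartmentTrack(armChrom, start(binRanges(map)), score,
                            seq@beadSize)
  strengthReport(saddle(map, track, nQuantiles = 10))
}

#' Architecture summary of a whole-genome ensemble
#'
#' Summaries used to compare control and mutant simulations: mean
#' inter-chromosomal distance between centromeric (pericentromeric C)
#' beads; arm alignment, measured as the mean distance between beads at
#' matched arm coordinates on different chromosomes (parallel, aligned
#' arms give small values); mean centromere-to-arm contact frequency
#' (same-chain pairs within 10 beads of the block excluded); and
#' intra-arm compartment strength (each arm treated as its own
#' chromosome, so only within-arm pairs contribute).
#'
#' @param e [Ensemble-class]
#' @param seq [BeadTypeSequence-class] with segment annotation (from
#'   [buildGenomeTemplate()])
#' @param contactRadius contact threshold (sigma)
#' @param excludeWithin same-chain pairs within this many beads are left
#'   out of the centromere-arm contact statistic (the proximal arm is in
#'   contact with its own block by connectivity alone)
#' @return list of summaries
#' @export
architectureStats <- function(e, seq, contactRadius = 2,
                              excludeWithin = 30) {
  if (!length(seq@segments)) stopf("sequence lacks segment annotation")
  seg <- unlist(seq@segments)
  types <- beadTypes(e)
  chain <- beadChains(e)
  dmap <- ensembleDistanceMap(e, minSamples = 10)
  cmap <- .mc_contact_map(ensembleCoords(e), contactRadius)
  isCen <- seg == "cen"
  isArm <- seg == "arm"
  diffChain <- outer(chain, chain, "!=")
  up <- upper.tri(dmap)
  sel <- function(rowSel, colSel, M, mask = diffChain) {
    pick <- outer(rowSel, colSel, "&") & mask & up
    pick <- pick | (outer(colSel, rowSel, "&") & mask & up)
    mean(M[pick])
  }
  interC <- sel(isCen, isCen, dmap)
  # arm alignment: matched positions along chains (chains share a
  # layout), restricted to the centromere-proximal arm halves where the
  # apical anchoring has leverage; distal arms are territorial with or
  # without anchoring and only dilute the signal
  nc <- length(beadChains(seq))
  len1 <- lengths(beadChains(seq))[1]
  seg1 <- seg[seq_len(len1)]
  cen1 <- which(seg1 == "cen")
  armIdx <- which(seg1 == "arm")
  distToCen <- vapply(armIdx, function(i) min(abs(i - cen1)), numeric(1))
  armIdx <- armIdx[distToCen <= ceiling(length(armIdx) / 4)]
  alignD <- c()
  for (a in seq_len(nc - 1)) for (b in (a + 1):nc) {
    ia <- (a - 1) * len1 + armIdx
    ib <- (b - 1) * len1 + armIdx
    alignD <- c(alignD, mean(dmap[cbind(ia, ib)]))
  }
  interArm <- mean(alignD)
  # centromere-to-arm contact share: fraction of centromeric contacts
  # made with arm beads (contact maps are coverage-normalized, so
  # declustering redistributes the pericentromeric contact budget toward
  # arms); near-block same-chain pairs excluded throughout
  idx <- seq_along(types)
  sameNear <- outer(chain, chain, "==") &
    abs(outer(idx, idx, "-")) <= excludeWithin
  pickArm <- (outer(isCen, isArm, "&") | outer(isArm, isCen, "&")) &
    !sameNear & up
  pickAll <- (outer(isCen, rep(TRUE, length(isCen)), "&") |
              outer(rep(TRUE, length(isCen)), isCen, "&")) & !sameNear & up
  cArm <- sum(cmap[pickArm]) / sum(cmap[pickAll])
  # intra-arm strength: one pseudo-chromosome per (chain, arm run)
  armRun <- cumsum(c(1, diff(as.integer(factor(paste(chain, seg)))) != 0))
  armChrom <- paste0("seg", armRun)
  map <- contactMap(cmap, seq@beadSize, armChrom)
  map@balanced <- cmap
  map@mask <- rep(TRUE, nrow(cmap))
  score <- ifelse(types == "A", 1, ifelse(types == "B", -1, NA_real_))
  track <- compartmentTrack(armChrom, start(binRanges(map)), score,
                            seq@beadSize)
  st <- strengthReport(saddle(map, track, nQuantiles = 10))
  list(interCentromereDistance = interC,
       interArmDistance = interArm,
       cToArmContact = cArm,
       intraArmStrength = st$strengthOverall,
       intraArmStrengthA = st$strengthA,
       intraArmStrengthB = st$strengthB)
}
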