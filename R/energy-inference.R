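## Inverse problem: infer per-bead-pair interaction energies of a region
## chain so that its simulated contact map reproduces a target map, by
## damped iterative Boltzmann inversion.

usedPairs <- function(n) {
  # diagonal and bonded neighbours are excluded from inference
  which(outer(seq_len(n), seq_len(n), function(i, j) j - i >= 2),
        arr.ind = TRUE)
}

#' Infer bead-pair interaction energies from a contact map
#'
#' Damped iterative Boltzmann inversion in two stages. Stage one fits a
#' single uniform contact energy by bisection so the simulated overall
#' contact level matches the target (this scalar captures the global
#' attractiveness of the map). Stage two refines per-pair energies:
#' each round simulates the chain with the current energies and applies
#' the soft-capped update
#' \code{E_ij <- E_ij + cap_k * tanh(alpha_k * log((p_sim + delta)/(p_exp +
#' delta)) / cap_k)}, with gain \code{alpha_k = alpha / (1 + k/gainDecay)}
#' decreasing over rounds (stochastic approximation) and the reported
#' matrix averaged over the post-burn-in iterates, which suppresses the
#' sampling-noise random walk of the iteration. Because contact support
#' varies enormously between near and distant pairs, the reported
#' energies are partially pooled: each pair is shrunk toward its
#' class-pair mean with weight growing with its target contact
#' probability (pairs with almost no contacts are weakly identified and
#' borrow strength from their class).
#'
#' Iteration stops when the Spearman correlation of the log maps reaches
#' \code{rStop}, when \code{maxRounds} is exhausted, or (with a warning)
#' after \code{abortAfter} rounds without improvement of the running best
#' correlation.
#'
#' Targets on the probability scale (unit diagonal, values in [0, 1], as
#' produced by [ensembleContactMap()]) are used as-is; other targets are
#' scaled once so their mean at bead separation 2 matches the initial
#' simulation.
#'
#' @param target [ContactMap-class] (balanced layer used if present) or a
#'   plain matrix of contact frequencies; one bin per bead
#' @param seq [BeadTypeSequence-class]; chain length must equal bin count
#' @param config [SimulationConfig-class]; per-round seeds derive from it
#' @param alpha initial damping factor of the update
#' @param gainDecay rounds over which the gain halves
#' @param maxRounds maximum update rounds
#' @param rStop Spearman correlation target on log maps
#' @param cap per-round update cap in kT (applied smoothly via tanh)
#' @param delta probability floor; default half the smallest nonzero
#'   target probability, but at least the sampling resolution 0.5/m of
#'   an m-sample simulated map
#' @param contactRadius contact threshold (sigma)
#' @param abortAfter abort after this many non-improving rounds
#' @param uniformInit run the stage-one scalar fit (FALSE starts the
#'   iteration from E = 0, e.g. for fixed-point checks)
#' @param uniformRange search interval (kT) for the stage-one scalar
#' @param shrink probability scale of the identifiability weight
#'   \code{w = p/(p + shrink)} used in the class shrinkage
#' @return list(energies = [EnergyMatrix-class], report = list with
#'   iterations, finalCorrelation, correlations, aborted, uniformFit,
#'   classMeans, overallMean, pairCounts)
#' @export
inferEnergies <- function(target, seq, config, alpha = 0.5, gainDecay = 10,
                          maxRounds = 30, rStop = 0.9, cap = 0.5,
                          delta = NULL, contactRadius = 2, abortAfter = 5,
                          uniformInit = TRUE, uniformRange = c(-0.6, 0.1),
                          shrink = 0.02) {
  pExp <- if (is(target, "ContactMap")) {
    b <- balancedCounts(target)
    if (is.null(b)) contactCounts(target) else b
  } else as.matrix(target)
  n <- nrow(pExp)
  types <- unlist(beadChains(seq))
  if (length(types) != n)
    stopf("chain length (%d) must equal target bin count (%d)",
          length(types), n)
  pairs <- usedPairs(n)
  nSamples <- max(1, floor(config@nSweeps / config@sampleInterval))
  if (is.null(delta)) {
    nz <- pExp[pairs][pExp[pairs] > 0]
    delta <- max(if (length(nz)) min(nz) / 2 else 1e-6, 0.5 / nSamples)
  }
  conf <- noConfinement()
  eps0 <- typeEnergyTable(0, 0, 0, 0, 0, 0, 0)
  simulate <- function(E, k, sweepFactor = 1) {
    cfg <- config
    cfg@seed <- childSeed(config@seed, k)
    cfg@nSweeps <- ceiling(config@nSweeps * sweepFactor)
    ens <- runMC(seq, eps0, conf, cfg, pairEnergies = E)
    .mc_contact_map(ensembleCoords(ens), contactRadius)
  }
  # target scale: probability maps are used as-is, others anchored at
  # separation 2 against the initial simulation
  offdiag <- pExp[pairs]
  probScale <- all(abs(diag(pExp) - 1) < 1e-6) && max(offdiag) <= 1 + 1e-9
  E <- matrix(0, n, n)
  if (!probScale) {
    p0 <- simulate(E, 0)
    sep2 <- pairs[pairs[, 2] - pairs[, 1] == 2, , drop = FALSE]
    pExp <- pmin(pExp * mean(p0[sep2]) / mean(pExp[sep2]), 1)
  }
  # stage one: uniform contact energy by bisection on the mean
  # (tanh-transformed) log discrepancy
  u <- 0
  if (uniformInit) {
    lo <- uniformRange[1]; hi <- uniformRange[2]
    for (it in seq_len(7)) {
      u <- (lo + hi) / 2
      E[pairs] <- u
      E[pairs[, c(2, 1)]] <- E[pairs]
      ps <- simulate(E, 100 + it, sweepFactor = 0.6)
      d <- mean(tanh(0.5 * (log(ps[pairs] + delta) -
                            log(pExp[pairs] + delta))))
      if (d > 0) lo <- u else hi <- u
    }
    u <- (lo + hi) / 2
    E[pairs] <- u
    E[pairs[, c(2, 1)]] <- E[pairs]
  }
  corOf <- function(p) {
    suppressWarnings(cor(log(p[pairs] + delta), log(pExp[pairs] + delta),
                         method = "spearman"))
  }
  pSim <- simulate(E, 1000)
  cors <- corOf(pSim)
  best <- cors[1]
  stall <- 0L
  aborted <- FALSE
  iterations <- 0L
  burn <- ceiling(maxRounds / 3)
  Esum <- matrix(0, n, n)
  navg <- 0L
  while (iterations < maxRounds && cors[length(cors)] < rStop) {
    k <- iterations + 1L
    aK <- alpha / (1 + k / gainDecay)
    capK <- min(cap, 2 * aK)
    lr <- log((pSim[pairs] + delta) / (pExp[pairs] + delta))
    upd <- capK * tanh(aK * lr / capK)
    E[pairs] <- E[pairs] + upd
    E[pairs[, c(2, 1)]] <- E[pairs]
    iterations <- k
    pSim <- simulate(E, 1000 + k)
    if (k > burn) { Esum <- Esum + E; navg <- navg + 1L }
    r <- corOf(pSim)
    cors <- c(cors, r)
    if (r > best + 2e-3) { best <- r; stall <- 0L }
    else stall <- stall + 1L
    if (stall >= abortAfter) {
      warnf(paste0("inference aborted: correlation not improving for %d ",
                   "rounds (best %.3f)"), abortAfter, best)
      aborted <- TRUE
      break
    }
  }
  if (navg > 0) E <- Esum / navg
  labels <- ifelse(types == "C", "B", types)  # region chains are A/B
  # identifiability-weighted partial pooling toward class means
  cls <- paste0(pmin(labels[pairs[, 1]], labels[pairs[, 2]]),
                pmax(labels[pairs[, 1]], labels[pairs[, 2]]))
  v <- E[pairs]
  cm <- tapply(v, cls, mean)
  w <- pExp[pairs] / (pExp[pairs] + shrink)
  E[pairs] <- w * v + (1 - w) * cm[cls]
  E[pairs[, c(2, 1)]] <- E[pairs]
  em <- new("EnergyMatrix", E = E, classLabels = labels,
            beadSize = seq@beadSize)
  report <- c(list(iterations = iterations,
                   finalCorrelation = cors[length(cors)],
                   correlations = cors, aborted = aborted,
                   uniformFit = u,
                   pairCounts = classPairCounts(labels)),
              classEnergyMeans(em))
  list(energies = em, report = report)
}

#' Class-wise energy means with standard errors
#'
#' Mean and s.e.m. of the inferred energies pooled per unordered class
#' pair (A-A, A-B, B-B), raw and mean-centred (the overall mean over used
#' pairs subtracted, absorbing the additive gauge freedom of the
#' inference).
#'
#' @param em [EnergyMatrix-class]
#' @return list(classMeans = data.frame, overallMean)
#' @export
classEnergyMeans <- function(em) {
  E <- energyValues(em)
  lab <- em@classLabels
  n <- nrow(E)
  pairs <- usedPairs(n)
  cls <- paste0(pmin(lab[pairs[, 1]], lab[pairs[, 2]]),
                pmax(lab[pairs[, 1]], lab[pairs[, 2]]))
  v <- E[pairs]
  overall <- mean(v)
  df <- do.call(rbind, lapply(c("AA", "AB", "BB"), function(k) {
    x <- v[cls == k]
    data.frame(class = k, n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sem = if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_,
               meanCentred = if (length(x)) mean(x) - overall else NA_real_)
  }))
  list(classMeans = df, overallMean = overall)
}

#' Unordered class-pair counts
#'
#' For n_A beads of class A and n_B of class B: n_A(n_A-1)/2 A-A pairs,
#' n_B(n_B-1)/2 B-B pairs and n_A n_B A-B pairs. With
#' \code{excludeBonded}, chain-adjacent pairs are removed from the counts
#' (requires \code{labels} in chain order).
#'
#' @param labels per-bead class vector over {A,B}
#' @param excludeBonded drop bonded-neighbour pairs from the counts
#' @return named numeric: AA, AB, BB
#' @export
classPairCounts <- function(labels, excludeBonded = FALSE) {
  nA <- sum(labels == "A"); nB <- sum(labels == "B")
  out <- c(AA = nA * (nA - 1) / 2, AB = nA * nB, BB = nB * (nB - 1) / 2)
  if (excludeBonded && length(labels) > 1) {
    a <- labels[-length(labels)]; b <- labels[-1]
    bonded <- paste0(pmin(a, b), pmax(a, b))
    out["AA"] <- out["AA"] - sum(bonded == "AA")
    out["AB"] <- out["AB"] - sum(bonded == "AB")
    out["BB"] <- out["BB"] - sum(bonded == "BB")
  }
  out
}

#' Per-class energy differences between two models
#'
#' Element-wise differences a - b pooled per class pair, mean and s.e.m.
#' over pairs; also reported after mean-centring each matrix (gauge-free
#' comparison).
#'
#' @param a,b [EnergyMatrix-class] with identical labels
#' @return data.frame(class, n, deltaMean, deltaSem, deltaMeanCentred)
#' @export
compareEnergySets <- function(a, b) {
  if (!identical(a@classLabels, b@classLabels))
    stopf("label mismatch between energy sets")
  Ea <- energyValues(a); Eb <- energyValues(b)
  n <- nrow(Ea)
  pairs <- usedPairs(n)
  lab <- a@classLabels
  cls <- paste0(pmin(lab[pairs[, 1]], lab[pairs[, 2]]),
                pmax(lab[pairs[, 1]], lab[pairs[, 2]]))
  d <- Ea[pairs] - Eb[pairs]
  dc <- (Ea[pairs] - mean(Ea[pairs])) - (Eb[pairs] - mean(Eb[pairs]))
  do.call(rbind, lapply(c("AA", "AB", "BB"), function(k) {
    x <- d[cls == k]; xc <- dc[cls == k]
    data.frame(class = k, n = length(x),
               deltaMean = mean(x), deltaSem = sd(x) / sqrt(length(x)),
               deltaMeanCentred = mean(xc))
  }))
}

#' Write an energy matrix as TSV (i, j, E_kT) with a labels sidecar
#'
#' @param em [EnergyMatrix-class]
#' @param path output path; labels are written to \code{paste0(path,
#'   ".labels")}
#' @export
writeEnergyMatrix <- function(em, path) {
  E <- energyValues(em)
  pairs <- usedPairs(nrow(E))
  df <- data.frame(i = pairs[, 1] - 1, j = pairs[, 2] - 1, E = E[pairs])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("i", "j", "E_kT"))
  writeLines(em@classLabels, paste0(path, ".labels"))
  invisible(path)
}
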