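# Inverse energy inference: fixed point, recovery, class summaries.

infCfg <- function(seed, nSweeps = 10000, equil = 3000) {
  simulationConfig(nSweeps = nSweeps, equilibrationSweeps = equil,
                   sampleInterval = 5, seed = seed)
}

test_that("class pair counts follow the combinatorics", {
  lab <- c(rep("A", 45), rep("B", 46))
  pc <- classPairCounts(lab)
  expect_equal(pc[["AA"]], 990)
  expect_equal(pc[["BB"]], 1035)
  expect_equal(pc[["AB"]], 45 * 46)
  # degenerate cases
  expect_equal(classPairCounts(rep("B", 5))[["AA"]], 0)
  expect_equal(classPairCounts(rep("B", 5))[["BB"]], 10)
  expect_equal(unname(classPairCounts(c("A", "B"))), c(0, 1, 0))
  # bonded-pair exclusion removes chain-adjacent pairs per class
  lab2 <- c("A", "A", "B", "B")
  pc2 <- classPairCounts(lab2, excludeBonded = TRUE)
  expect_equal(pc2[["AA"]], 0)   # one AA pair, bonded
  expect_equal(pc2[["BB"]], 0)
  expect_equal(pc2[["AB"]], 3)   # 4 total minus the bonded one
})

test_that("self-generated target is a fixed point of the inference", {
  seqt <- regionChain(alternatingBlocks(40, 10))
  # sampling deep enough that the Spearman noise ceiling of two
  # finite-sample maps lies above the stop threshold
  cfg <- infCfg(31, nSweeps = 200000)
  ens <- runMC(seqt, typeEnergyTable(0, 0, 0, 0, 0, 0, 0),
               noConfinement(), cfg)
  target <- ensembleContactMap(ens, contactRadius = 2,
                               beadSize = 4e4, minSamples = 50)
  res <- inferEnergies(target, seqt, infCfg(32, nSweeps = 200000),
                       maxRounds = 10)
  # the stop threshold is reached quickly and energies stay near 0
  E <- energyValues(res$energies)
  used <- abs(row(E) - col(E)) >= 2
  expect_lt(mean(abs(E[used])), 0.1)
  expect_gte(res$report$finalCorrelation, 0.9)
})

test_that("planted class structure is recovered (smoke-scale)", {
  n <- 60
  lab <- alternatingBlocks(n, 10)
  Ep <- matrix(0, n, n)
  pairs <- which(abs(row(Ep) - col(Ep)) >= 2)
  cls <- paste0(pmin(lab[row(Ep)[pairs]], lab[col(Ep)[pairs]]),
                pmax(lab[row(Ep)[pairs]], lab[col(Ep)[pairs]]))
  Ep[pairs] <- c(AA = -0.25, AB = -0.1, BB = -0.4)[cls]
  seqt <- regionChain(lab)
  ens <- runMC(seqt, typeEnergyTable(0, 0, 0, 0, 0, 0, 0),
               noConfinement(), infCfg(41, nSweeps = 50000), pairEnergies = Ep)
  target <- ensembleContactMap(ens, contactRadius = 2, beadSize = 4e4,
                               minSamples = 50)
  res <- inferEnergies(target, seqt, infCfg(141),
                       alpha = 0.15, maxRounds = 30, rStop = 0.98,
                       abortAfter = 100)
  # global attractiveness captured by the uniform stage
  expect_lt(res$report$uniformFit, -0.1)
  # class ordering: B-B most attractive, A-B least
  cm <- res$report$classMeans
  expect_lt(cm$mean[cm$class == "BB"], cm$mean[cm$class == "AA"])
  expect_lt(cm$mean[cm$class == "AA"], cm$mean[cm$class == "AB"])
  E <- energyValues(res$energies)
  expect_gt(cor(Ep[pairs], E[pairs]), 0.4)
})

test_that("stalled correlation triggers the abort path with diagnostics", {
  seqt <- regionChain(alternatingBlocks(40, 10))
  ens <- runMC(seqt, typeEnergyTable(0.3, 0.1, 0.4, 0, 0, 0, 0),
               noConfinement(), infCfg(51))
  target <- ensembleContactMap(ens, contactRadius = 2, beadSize = 4e4,
                               minSamples = 50)
  # unreachable stop threshold with a tight stall window
  expect_warning(
    res <- inferEnergies(target, seqt, infCfg(52, nSweeps = 3000),
                         maxRounds = 40, rStop = 0.999, abortAfter = 3),
    "aborted")
  expect_true(res$report$aborted)
  # the running best is non-decreasing by construction
  cors <- res$report$correlations
  expect_false(any(diff(cummax(cors)) < 0))
})

test_that("gauge shift changes class comparisons only in the raw view", {
  n <- 30
  lab <- alternatingBlocks(n, 10)
  E <- matrix(-0.2, n, n)
  a <- new("EnergyMatrix", E = E, classLabels = lab, beadSize = 4e4)
  b <- new("EnergyMatrix", E = E - 0.2, classLabels = lab, beadSize = 4e4)
  cmp <- compareEnergySets(a, b)
  expect_equal(cmp$deltaMean, rep(0.2, 3), tolerance = 1e-12)
  expect_equal(cmp$deltaMeanCentred, rep(0, 3), tolerance = 1e-12)
  # identical sets: all zero
  cmp0 <- compareEnergySets(a, a)
  expect_true(all(cmp0$deltaMean == 0))
  # label mismatch errors
  d <- new("EnergyMatrix", E = E, classLabels = ifelse(lab == "A", "B", "A"),
           beadSize = 4e4)
  expect_error(compareEnergySets(a, d), "mismatch")
})

test_that("energy matrices round-trip through the TSV writer", {
  n <- 12
  lab <- alternatingBlocks(n, 4)
  E <- matrix(0, n, n)
  pairs <- which(abs(row(E) - col(E)) >= 2)
  set.seed(2)
  E[pairs] <- round(rnorm(length(pairs), -0.2, 0.1), 6)
  E[lower.tri(E)] <- t(E)[lower.tri(E)]
  E[abs(row(E) - col(E)) < 2] <- 0
  E <- (E + t(E)) / 2
  em <- new("EnergyMatrix", E = E, classLabels = lab, beadSize = 4e4)
  f <- withr::local_tempfile()
  writeEnergyMatrix(em, f)
  df <- read.table(f, header = TRUE)
  expect_equal(nrow(df), sum(abs(row(E) - col(E))[upper.tri(E)] >= 2) / 1)
  back <- matrix(0, n, n)
  back[cbind(df$i + 1, df$j + 1)] <- df$E_kT
  expect_equal(back[upper.tri(back)], E[upper.tri(E)])
  expect_equal(readLines(paste0(f, ".labels")), lab)
})
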