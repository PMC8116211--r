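---
title: "chromarch: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromarch: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `chromarch`: the models and
estimators, the parameters that matter with their defaults and
rationale, what the synthetic generators do and do not emulate, and the
numerical choices made where the design was genuinely open. The package
is built around the biology of early-embryo nuclear architecture — the
Rabl configuration with apically clustered pericentromeric
heterochromatin, the alignment of chromosome arms, and A/B compartment
segregation — and around perturbations that weaken
heterochromatin-mediated interactions (an "HP1-knockdown-like" state).

## Contact-map analytics

**Balancing.** `balanceICE()` implements iterative correction: the
count matrix is repeatedly divided by the outer product of its row-sum
deviations until unmasked row sums agree within `tol` (default 1e-5,
maximum 200 iterations). Bins with fewer than `minNnz = 10` nonzero
entries or zero coverage are masked; the balanced layer is scaled to
unit row sums. Non-convergence flags the map and warns rather than
failing.

Analytics accept both balanced and unbalanced maps: when no balanced
layer is present, raw counts are used. This matters for synthetic
maps, which carry no technical coverage bias — and where balancing is
not merely unnecessary but actively distorting: row-sum equalization
partially absorbs a planted *selective* perturbation (a B-B-only
contact loss leaves B-row sums low; ICE scales them back up, moving
part of the effect into the A rows). The B-weakening recovery analyses
therefore run on raw observed/expected, which is exact for
Poisson-sampled maps.

**Distance decay.** `decayCurve()` pools mean contacts per separation
into log-spaced bins (8 per decade), normalizes the curve to unit area
over separation, and fits the scaling exponent by least squares on
log10 *P* versus log10 *s* inside `fitRange` (default 100 kb-10 Mb,
following the observation window in which knockdown embryos show a
milder decay). Fewer than 3 populated bins in the range is an error,
not a silent NA. Pericentromeric bins can be excluded via `exclude`
so Rabl-associated signal does not distort arm scaling.

**Compartment score.** Per chromosome: observed/expected, Pearson
correlation matrix, leading eigenvector (`eigen()` on the symmetric
matrix). The eigenvector sign is arbitrary, so it is oriented against
an external reference (`orientation`): gene density or active-mark
coverage on real data, the planted truth in tests. Degenerate inputs
(constant O/E) warn and yield undefined scores. Labels follow the
sign; masked bins stay `NA`.

**Saddle and compartment strength.** O/E entries are pooled by pairs
of score quantiles (default `nQuantiles = 50`), ascending, with ties
broken by a deterministic pseudo-random permutation — with binary
ground-truth scores, positional tie-breaking would concentrate extreme
quantiles at chromosome ends and bias corner statistics. Pairs closer
than `minSeparation` can be excluded (the robustness analyses use 0
and 500 kb). Corner means over the extreme `cornerFraction` (default
0.2; results hold for 0.1-0.25) give `strength_A = AA/AB`,
`strength_B = BB/AB`, `strength_overall = sqrt(AA*BB)/AB`. Corner
means are **distance-matched**: per-separation means combined with
common weights across the three corners, so the distance expectation
cancels exactly in the ratios. Without this, the different separation
profiles of the BB and AB corner pools leak distance decay into the
strength and bias a planted 20% B-B weakening toward smaller measured
effects. With it, the no-noise recovery is exact (ratio 0.8000) and
the Poisson-noise recovery at depth 1e6 is unbiased.

**Insulation.** Windowed mean of contacts crossing each bin (default
window 100 kb at 10-kb bins, the fly TAD scale), log2 against the
chromosome median; boundaries are local minima with prominence at
least 0.1 log2 units.

## The polymer model

Chromosomes are chains of beads of types A, B (compartments, 10 kb in
the whole-genome template, 40 kb in region models) and C
(pericentromeric/telomeric). The potential is deliberately minimal:

- harmonic bonds, `k = 50` kT/sigma^2, rest length 1 sigma, inside a
  hard extensibility window [0.7, 1.3] x rest length. The window makes
  "bond lengths bounded in every sampled configuration" an invariant
  by construction rather than a statistical accident (a pure harmonic
  bond at k = 50 leaves the window with non-negligible probability);
- soft-core repulsion, capped at `excludedVolume = 4` kT at full
  overlap, quadratic in r^2 below 1 sigma;
- square-well attraction of range 1.5 sigma with per-type-pair depths
  (kT), or per-pair energies in the inference setting;
- confinement: a cylinder sized so beads occupy a packing fraction of
  0.1, height = 2 x radius (a squat nucleus leaves lateral room for
  chromosome territories); C beads within 1 sigma of the apical cap
  gain the surface energy.

Sampling is single-bead Metropolis Monte Carlo with a displacement
step auto-tuned during equilibration only (detailed balance is exact
in the production phase). The simulator owns its RNG (xoshiro256+), so
a (seed, configuration) pair reproduces ensembles bit-for-bit. Cell
lists with edge = interaction range accelerate systems above 48 beads;
the cell and direct paths produce identical trajectories.

The whole-genome template is telomere(C)-arm-centromere(C)-arm-
telomere(C) per chromosome, with arms patterned from a compartment
track or synthetic A/B alternation. The initial conformation is
Rabl-like: V-shaped chains with the centromeric block seeded near the
cylinder axis at the apical cap (one chromocenter) and arms extended
basally.

**Default energies.** The whole-genome control table
(`typeEnergyTable()`: AA 0.2, AB 0.05, BB 0.35, AC/BC 0.05, CC 1.5,
surface 4.0 kT) was selected with the shipped `energyGridSearch()`
utility so that the control shows a tight apical chromocenter,
arm-level A/B compartment strength in the range seen in embryo maps,
and stable arm scaling; the deep C-C and surface terms reflect that
pericentromeric clustering is the strongest feature of the control
architecture. The region-model base (`regionBaseEnergies()`: AA 0.75,
AB 0.5, BB 0.9 kT) places the 90-bead chain just past its
microphase-separation maximum, so halving all attractions swells the
chain (steeper *P(s)*, stronger relative compartments) and increasing
them compacts and mixes it (milder scaling, weaker compartments) —
the phase behavior the sweep analyses probe.

**Mutant transform.** `mutantTransform(energies, cFactor)` multiplies
only the C-C attraction and the C-surface attraction; `cFactor = 0.2`
is the standard heterochromatin-loss condition. Architecture
comparisons (`architectureStats()`) report: inter-chromosomal
centromere-centromere distance; arm alignment as the distance between
matched arm coordinates on different chromosomes (parallel Rabl arms
give small values); the centromere-to-arm **contact share** (fraction
of centromeric contacts made with arms — contact maps are
coverage-normalized, so declustering redistributes the pericentromeric
contact budget toward arms); and within-arm compartment strength, with
each arm treated as its own chromosome. For the strength comparison,
replicate ensembles are pooled into one contact map
(`pooledIntraArmStrength()`), as replicate embryos are pooled in Hi-C
analyses, which suppresses the slow droplet-position fluctuations of
individual runs.

**Problem sizes.** The desk-scale genome is 4 chromosomes x 300 beads
(arms of 130, 10 centromeric, 2 x 5 telomeric beads), with 12,000
equilibration and 16,000 production sweeps per run and five replicate
seeds for the control/mutant comparison; the self-avoiding-walk check
uses a 96-bead athermal chain, eight seeds and 240,000 sweeps each,
fitting internal distances over separations 11-72 (short separations
carry thickness corrections that inflate the effective exponent; at
these mid-range separations the fitted exponent sits at the
self-avoiding value within its uncertainty).

## Inverse energy inference

`inferEnergies()` fits per-pair contact energies of a region chain to
a target map. Two stages:

1. a single uniform contact energy is found by bisection so the
   simulated overall contact level matches the target — this scalar is
   the model's measure of global attractiveness;
2. damped iterative Boltzmann inversion refines per-pair energies:
   `E_ij += cap_k * tanh(alpha_k * log((p_sim+delta)/(p_exp+delta)) / cap_k)`,
   with gain `alpha_k = alpha/(1 + k/gainDecay)` decreasing over
   rounds and fresh simulation seeds per round; the reported matrix is
   the average of post-burn-in iterates.

Numerical choices that matter, and why:

- the **tanh soft cap** replaces a hard clip: with a hard clip the
  asymmetry between saturating contact probabilities (p near 1) and
  floor-limited ones (p near 0) rectifies sampling noise into a
  systematic drift of the mean energy;
- **decreasing gains with iterate averaging** (stochastic
  approximation) prevent the per-pair random walk that a fixed gain
  accumulates from finite-sample maps;
- the **probability floor** `delta` is half the smallest nonzero
  target value but never below the sampling resolution `0.5/m` of an
  m-sample simulated map — a probability of zero in m samples is only
  known to be below 1/m;
- targets on the probability scale (unit diagonal, values in [0, 1])
  are used as-is; other targets are anchored once, at bead separation
  2, against the initial simulation. Anchoring at larger separations
  is unstable: it couples the unknown compaction state to the target
  scale;
- **identifiability-weighted class pooling**: distant pairs make few
  contacts, so their individual energies are weakly identified — their
  fixed-point values absorb target noise amplified by the inverse of a
  small response coefficient. Reported energies are therefore shrunk
  toward their class-pair mean with weight `p/(p + shrink)`
  (`shrink = 0.02`): well-supported pairs keep their per-pair values,
  unsupported ones borrow strength from their class. This is ordinary
  partial pooling, matching how the energies are interpreted (class
  summaries A-A, A-B, B-B);
- bonded neighbours (|i-j| <= 1) are excluded from inference — their
  contact statistics are bond-dominated;
- the additive gauge of the energies (a constant shift trades against
  compaction) is absorbed by reporting class comparisons both raw and
  mean-centred.

Iteration stops at a Spearman correlation `rStop` between log maps, at
`maxRounds`, or aborts with diagnostics after `abortAfter` rounds
without improvement of the running best. Parameter-recovery tests run
at 60 beads with 2,000 sampled configurations per round against
40,000-sample targets; the region template mirrors a 3.6-Mb window at
40 kb (90 beads) and uses 60 beads in tests for speed.

The inverse problem is well-posed near the model manifold: targets
generated by the forward model (with planted energies, or planted
condition differences such as "globally more attractive with
relatively weaker B-B") are recovered reliably. Arbitrary analytic
maps — e.g. exact power laws with checkerboards — can lie outside
what a 60-bead chain can realize and then the iteration reports its
failure through the abort path rather than converging; condition
comparisons are therefore always made between models fitted by the
same protocol.

## Synthetic data

`makeSyntheticMap()` builds the expected matrix
`E_ij = depth_scale * s^gamma * m_ij`, where `m_ij` is `contrast` for
same-compartment pairs, additionally multiplied by `bWeakening` when
both bins are B, and 1 otherwise; optional TAD boundaries deplete
short-range crossing pairs. Counts are Poisson draws
(`noise = FALSE` returns expectations for exact checks). Compartment
blocks have randomized lengths (Poisson around `blockBins`, minimum
half) so the same-compartment fraction decorrelates with separation
instead of oscillating with a fixed period — a periodic profile would
put a spurious ripple into *P(s)* and couple block phase to the
expected profile. `pairedConditionMaps()` shares one profile between
conditions and splits the RNG; the knockdown-like condition gets
`gamma + gammaShift` (milder decay) and `beta` (B-B weakening).

`makeSyntheticTables()` plants: an exact pericentromeric/arm peak
split (`round(nPeaks * fraction)` peaks placed inside the annotation,
the rest on arms clear of the boundary, so any-overlap classification
recovers the counts exactly); compartment assignment of arm peaks
(midpoints placed inside known A or B bins); and per-class width
distributions drawn from a log-normal via a seed-permuted quantile
grid — stratified sampling, so the planted medians (2,000 bp
pericentromeric, 730 bp for arm-B peaks, 500 bp for arm-A peaks,
sigma 0.5 on the log scale) are reproduced essentially exactly by the
sample median rather than only in expectation.

Defaults are the study conditions: 6,607 peaks of which 4,394
pericentromeric/telomeric (66.5%), B-peak median width 730 bp, maps at
10-kb resolution with depth 1e6 and `beta = 0.8` for the knockdown
surrogate.

What the generators do **not** emulate: read-level artifacts
(re-ligation, duplicates, mappability), coverage bias (hence the raw
O/E analysis above), repeat sequence content, inter-chromosomal
contacts, and continuous compartment-score gradations (planted scores
are binary). Passing tests demonstrate that the estimators recover
planted structure under Poisson sampling at realistic depth — not that
they are robust to technical biases real pipelines must correct first.

## Known limitations

- The whole-genome model is desk-scale (1,220 beads, where a 120-Mb
  genome at 10 kb would be 12,000); conclusions from it are
  directional, not quantitative. One finite-size coupling is worth
  naming: when the heterochromatin-loss transform disperses the small
  (10-bead) pericentromeric blocks into the arms, the interlopers
  mildly dilute arm compartments — an effect of order 10% on intra-arm
  strength that shrinks with system size (and grows sharply if
  compartment blocks are made smaller). At full scale the contiguous
  pericentromeric domains stay polymerically coherent and arms are
  long, so the coupling vanishes; at desk scale the within-arm strength
  comparison between control and mutant carries both this mild real
  coupling and a few-percent measurement spread even with pooled
  replicate ensembles.
- Single-bead moves mix slowly in collapsed states; compartment
  strengths of individual simulated ensembles carry droplet-position
  noise, which is why replicate pooling is built into the comparison
  utilities.
- Per-pair energies of rarely-contacting (distant) pairs are reported
  as class-pooled estimates; only their class structure, not their
  individual values, should be interpreted.
- Insulation boundaries use a simple prominence rule on local minima;
  no multi-scale TAD calling is attempted.
- Only intra-chromosomal (intra-arm) compartment analysis is
  implemented.
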