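## Central S4 data containers. Genomic intervals themselves are plain
## GRanges; the classes below hold the derived objects (binned matrices,
## per-bin tracks, polymer systems) that GRanges does not model.

#' Genome assembly: named chromosomes with lengths
#'
#' Thin wrapper around a named vector of chromosome lengths, used to
#' validate intervals and to lay out synthetic genomes.
#'
#' @slot name assembly identifier, e.g. \code{"dm6"} or \code{"synthetic"}
#' @slot seqlengths named numeric vector of chromosome lengths in bp
#' @export
setClass("GenomeAssembly",
  representation(name = "character", seqlengths = "numeric"),
  validity = function(object) {
    nm <- names(object@seqlengths)
    if (is.null(nm) || anyDuplicated(nm))
      return("chromosome names must be present and unique")
    if (any(object@seqlengths <= 0))
      return("chromosome lengths must be > 0")
    TRUE
  })

#' Binned Hi-C contact map
#'
#' Symmetric binned contact matrix with bin coordinates, an optional
#' balanced (iteratively corrected) layer and a per-bin validity mask.
#' Bins are ordered by (chromosome, start); inter-chromosomal blocks are
#' part of the matrix but most analytics use intra-chromosomal entries only.
#'
#' @slot bins GRanges of bin intervals, one per matrix row
#' @slot resolution bin size in bp
#' @slot counts symmetric non-negative raw count matrix
#' @slot balanced balanced matrix (same dim) or 0x0 matrix if absent
#' @slot mask logical per bin; FALSE = bin excluded (low coverage)
#' @slot converged logical; FALSE if balancing hit max iterations
#' @export
setClass("ContactMap",
  representation(bins = "GRanges", resolution = "numeric",
                 counts = "matrix", balanced = "matrix",
                 mask = "logical", converged = "logical"),
  prototype(balanced = matrix(numeric(0), 0, 0), converged = TRUE),
  validity = function(object) {
    n <- nrow(object@counts)
    if (ncol(object@counts) != n) return("counts must be square")
    if (length(object@bins) != n) return("one bin per matrix row required")
    if (length(object@mask) != n) return("mask length must equal bin count")
    if (any(object@counts < 0, na.rm = TRUE)) return("counts must be >= 0")
    if (max(abs(object@counts - t(object@counts)), na.rm = TRUE) > 1e-8)
      return("counts must be symmetric")
    if (nrow(object@balanced) > 0 && nrow(object@balanced) != n)
      return("balanced layer must match counts dimension")
    TRUE
  })

#' Per-bin compartment score track
#'
#' First eigenvector of the observed/expected correlation matrix with sign
#' oriented by an external reference; labels A (score > 0), B (score < 0)
#' or NA (masked / undefined bin).
#'
#' @slot bins GRanges of bins with metadata columns \code{score} and
#'   \code{label}
#' @slot resolution bin size in bp
#' @export
setClass("CompartmentTrack",
  representation(bins = "GRanges", resolution = "numeric"),
  validity = function(object) {
    mc <- mcols(object@bins)
    if (!all(c("score", "label") %in% colnames(mc)))
      return("bins must carry 'score' and 'label' metadata columns")
    sc <- mc$score; lb <- mc$label
    ok <- is.na(sc) & is.na(lb) |
      (!is.na(sc) & sc > 0 & lb %in% "A") |
      (!is.na(sc) & sc < 0 & lb %in% "B") |
      (!is.na(sc) & sc == 0 & is.na(lb))
    if (!all(ok)) return("labels must follow sign(score): A > 0 > B")
    TRUE
  })

#' Saddle matrix: O/E enrichment sorted by compartment score
#'
#' Mean observed/expected contact enrichment pooled by pairs of
#' compartment-score quantiles (ascending score: B corner top-left, A corner
#' bottom-right), together with corner-based compartment-strength summaries.
#'
#' @slot values nQuantiles x nQuantiles mean O/E matrix (NA = empty cell)
#' @slot counts pair count per cell
#' @slot nQuantiles number of score quantiles
#' @slot cornerFraction fraction of extreme quantiles pooled per corner
#' @slot strength named list: AA, BB, AB corner means and strengthA
#'   (AA/AB), strengthB (BB/AB), strengthOverall (sqrt(AA*BB)/AB)
#' @export
setClass("SaddleMatrix",
  representation(values = "matrix", counts = "matrix",
                 nQuantiles = "numeric", cornerFraction = "numeric",
                 strength = "list"))

#' Insulation score track
#'
#' Windowed mean of contacts crossing each bin's diagonal, log2 relative to
#' the chromosome median; local minima of sufficient prominence are TAD
#' boundary calls.
#'
#' @slot bins GRanges with metadata column \code{insulation}
#' @slot resolution bin size in bp
#' @slot window window size in bp (each side of the diagonal)
#' @slot boundaries integer indices (into bins) of boundary bins
#' @export
setClass("InsulationTrack",
  representation(bins = "GRanges", resolution = "numeric",
                 window = "numeric", boundaries = "integer"))

#' Distance-decay curve P(s)
#'
#' Mean contact probability per log-spaced genomic-separation bin,
#' normalized to unit area, with a least-squares scaling exponent fitted on
#' log10 P versus log10 s within \code{fitRange}.
#'
#' @slot separations representative separation (bp) per log bin
#' @slot probabilities mean contact probability per log bin
#' @slot fitRange numeric(2), separation range (bp) used for the fit
#' @slot exponent fitted scaling exponent (slope)
#' @export
setClass("DecayCurve",
  representation(separations = "numeric", probabilities = "numeric",
                 fitRange = "numeric", exponent = "numeric"))

## ---- polymer model ----

#' Bead-type sequence of a modelled genome
#'
#' One character vector per chain over the alphabet A/B/C (A/B compartment
#' beads, C pericentromeric/telomeric beads), plus optional per-bead segment
#' annotation ("tel", "arm", "cen") for the whole-genome template.
#'
#' @slot chains list of per-chain character vectors over {A,B,C}
#' @slot segments list of per-chain character vectors (may be empty)
#' @slot beadSize bead size in bp (10 kb whole-genome, 40 kb region model)
#' @export
setClass("BeadTypeSequence",
  representation(chains = "list", segments = "list", beadSize = "numeric"),
  prototype(segments = list()),
  validity = function(object) {
    if (length(object@chains) == 0) return("at least one chain required")
    for (ch in object@chains) {
      if (length(ch) == 0) return("empty chain")
      if (!all(ch %in% c("A", "B", "C")))
        return("bead types must be A, B or C")
    }
    if (length(object@segments) &&
        !identical(lengths(object@segments), lengths(object@chains)))
      return("segments must parallel chains")
    TRUE
  })

#' Type-pair interaction energies (kT)
#'
#' Square-well attraction depths for each unordered type pair plus the
#' attraction of C beads to the apical nuclear surface. Depth convention:
#' values are >= 0; 0 means purely repulsive.
#'
#' @slot eps named numeric: AA, AB, BB, AC, BC, CC attraction depths in kT
#' @slot epsSurfC C-bead apical-surface attraction depth in kT
#' @export
setClass("TypeEnergyTable",
  representation(eps = "numeric", epsSurfC = "numeric"),
  validity = function(object) {
    need <- c("AA", "AB", "BB", "AC", "BC", "CC")
    if (!all(need %in% names(object@eps)))
      return("eps must name all pairs AA, AB, BB, AC, BC, CC")
    if (any(object@eps < 0) || object@epsSurfC < 0)
      return("attraction depths must be >= 0")
    TRUE
  })

#' Nuclear confinement geometry
#'
#' @slot shape "cylinder", "box" or "none"
#' @slot radius cylinder radius in sigma units
#' @slot height cylinder height (z in [0, height]; apical cap at the top)
#' @slot box numeric(3) box edge lengths (shape "box")
#' @export
setClass("ConfinementSpec",
  representation(shape = "character", radius = "numeric",
                 height = "numeric", box = "numeric"),
  prototype(radius = 0, height = 0, box = c(0, 0, 0)))

#' Monte-Carlo simulation configuration
#'
#' @slot bondLength bond rest length (sigma)
#' @slot excludedVolume soft-core repulsion cap in kT
#' @slot attractionRange square-well attraction range in sigma
#' @slot nSweeps production sweeps (one sweep = N single-bead moves)
#' @slot equilibrationSweeps sweeps discarded before sampling
#' @slot sampleInterval sweeps between samples
#' @slot seed RNG seed (mandatory; the simulator owns its RNG stream)
#' @export
setClass("SimulationConfig",
  representation(bondLength = "numeric", excludedVolume = "numeric",
                 attractionRange = "numeric", nSweeps = "numeric",
                 equilibrationSweeps = "numeric", sampleInterval = "numeric",
                 seed = "numeric"),
  validity = function(object) {
    vals <- c(object@bondLength, object@excludedVolume,
              object@attractionRange, object@nSweeps,
              object@equilibrationSweeps + 1, object@sampleInterval)
    if (any(!is.finite(vals)) || any(vals <= 0))
      return("all configuration values must be positive and finite")
    if (length(object@seed) != 1 || !is.finite(object@seed))
      return("a finite seed is mandatory")
    TRUE
  })

#' Sampled conformational ensemble
#'
#' @slot coords numeric array (nBeads, 3, nSamples)
#' @slot chains integer chain id per bead
#' @slot types character bead type per bead
#' @slot acceptance overall Metropolis acceptance rate
#' @slot provenance list: config hash, seed, resolved parameters
#' @export
setClass("Ensemble",
  representation(coords = "array", chains = "integer", types = "character",
                 acceptance = "numeric", provenance = "list"),
  validity = function(object) {
    d <- dim(object@coords)
    if (length(d) != 3 || d[2] != 3)
      return("coords must be an (nBeads, 3, nSamples) array")
    if (length(object@chains) != d[1] || length(object@types) != d[1])
      return("chains/types must have one entry per bead")
    TRUE
  })

## ---- energy inference ----

#' Per-bead-pair interaction energy matrix (kT)
#'
#' Inferred contact energies of a region model; negative = attractive.
#' Diagonal and bonded-neighbour entries are excluded from inference and
#' held at zero.
#'
#' @slot E symmetric numeric matrix in kT
#' @slot classLabels per-bead compartment class, "A" or "B"
#' @slot beadSize bead size in bp
#' @slot region optional "chrom:start-end" description
#' @export
setClass("EnergyMatrix",
  representation(E = "matrix", classLabels = "character",
                 beadSize = "numeric", region = "character"),
  prototype(region = NA_character_),
  validity = function(object) {
    n <- nrow(object@E)
    if (ncol(object@E) != n) return("E must be square")
    if (length(object@classLabels) != n)
      return("one class label per bead required")
    if (!all(object@classLabels %in% c("A", "B")))
      return("class labels must be A or B")
    if (max(abs(object@E - t(object@E))) > 1e-8)
      return("E must be symmetric")
    TRUE
  })

#' @describeIn GenomeAssembly constructor
#' @param name assembly name
#' @param seqlengths named numeric chromosome lengths (bp)
#' @export
GenomeAssembly <- function(name, seqlengths) {
  new("GenomeAssembly", name = name, seqlengths = seqlengths)
}

setMethod("show", "GenomeAssembly", function(object) {
  cat("GenomeAssembly '", object@name, "': ",
      length(object@seqlengths), " chromosomes, ",
      format(sum(object@seqlengths), big.mark = ","), " bp\n", sep = "")
})

setMethod("show", "ContactMap", function(object) {
  cat("ContactMap: ", nrow(object@counts), " bins @ ",
      object@resolution, " bp, ",
      length(unique(as.character(seqnames(object@bins)))),
      " chromosome(s); balanced: ",
      if (nrow(object@balanced)) "yes" else "no",
      "; masked bins: ", sum(!object@mask), "\n", sep = "")
})

setMethod("show", "CompartmentTrack", function(object) {
  lb <- mcols(object@bins)$label
  cat("CompartmentTrack: ", length(object@bins), " bins @ ",
      object@resolution, " bp (A: ", sum(lb %in% "A"),
      ", B: ", sum(lb %in% "B"), ", undefined: ", sum(is.na(lb)), ")\n",
      sep = "")
})

setMethod("show", "SaddleMatrix", function(object) {
  s <- object@strength
  cat("SaddleMatrix: ", object@nQuantiles, " quantiles; strength A/B/overall: ",
      sprintf("%.3f/%.3f/%.3f", s$strengthA, s$strengthB, s$strengthOverall),
      "\n", sep = "")
})

setMethod("show", "Ensemble", function(object) {
  d <- dim(object@coords)
  cat("Ensemble: ", d[1], " beads, ", d[3], " samples, acceptance ",
      sprintf("%.2f", object@acceptance), "\n", sep = "")
})

setMethod("show", "BeadTypeSequence", function(object) {
  cat("BeadTypeSequence: ", length(object@chains), " chain(s), ",
      sum(lengths(object@chains)), " beads @ ", object@beadSize, " bp\n",
      sep = "")
})

setMethod("show", "EnergyMatrix", function(object) {
  cat("EnergyMatrix: ", nrow(object@E), " beads @ ", object@beadSize,
      " bp; mean E ", sprintf("%.3f", mean(object@E[upper.tri(object@E)])),
      " kT\n", sep = "")
})
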