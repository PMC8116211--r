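#' @name accessors
#' @title Accessors for chromarch classes
#' @description Slot access goes through these accessors, never through
#'   \code{@}.
#' @param x an object
NULL

#' @rdname accessors
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))
#' @rdname accessors
#' @export
setGeneric("mapResolution", function(x) standardGeneric("mapResolution"))
#' @rdname accessors
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))
#' @rdname accessors
#' @export
setGeneric("balancedCounts", function(x) standardGeneric("balancedCounts"))
#' @rdname accessors
#' @export
setGeneric("binMask", function(x) standardGeneric("binMask"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("compartmentLabels", function(x) standardGeneric("compartmentLabels"))
#' @rdname accessors
#' @export
setGeneric("strengthReport", function(x) standardGeneric("strengthReport"))
#' @rdname accessors
#' @export
setGeneric("scalingExponent", function(x) standardGeneric("scalingExponent"))
#' @rdname accessors
#' @export
setGeneric("beadChains", function(x) standardGeneric("beadChains"))
#' @rdname accessors
#' @export
setGeneric("beadTypes", function(x) standardGeneric("beadTypes"))
#' @rdname accessors
#' @export
setGeneric("ensembleCoords", function(x) standardGeneric("ensembleCoords"))
#' @rdname accessors
#' @export
setGeneric("energyValues", function(x) standardGeneric("energyValues"))

#' @rdname accessors
#' @export
setMethod("binRanges", "ContactMap", function(x) x@bins)
#' @rdname accessors
#' @export
setMethod("binRanges", "CompartmentTrack", function(x) x@bins)
#' @rdname accessors
#' @export
setMethod("binRanges", "InsulationTrack", function(x) x@bins)
#' @rdname accessors
#' @export
setMethod("mapResolution", "ContactMap", function(x) x@resolution)
#' @rdname accessors
#' @export
setMethod("mapResolution", "CompartmentTrack", function(x) x@resolution)
#' @rdname accessors
#' @export
setMethod("contactCounts", "ContactMap", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("balancedCounts", "ContactMap", function(x) {
  if (nrow(x@balanced) == 0) NULL else x@balanced
})
#' @rdname accessors
#' @export
setMethod("binMask", "ContactMap", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("scores", "CompartmentTrack", function(x) mcols(x@bins)$score)
#' @rdname accessors
#' @export
setMethod("compartmentLabels", "CompartmentTrack",
          function(x) mcols(x@bins)$label)
#' @rdname accessors
#' @export
setMethod("scores", "InsulationTrack", function(x) mcols(x@bins)$insulation)
#' @rdname accessors
#' @export
setMethod("strengthReport", "SaddleMatrix", function(x) x@strength)
#' @rdname accessors
#' @export
setMethod("scalingExponent", "DecayCurve", function(x) x@exponent)
#' @rdname accessors
#' @export
setMethod("beadChains", "BeadTypeSequence", function(x) x@chains)
#' @rdname accessors
#' @export
setMethod("beadChains", "Ensemble", function(x) x@chains)
#' @rdname accessors
#' @export
setMethod("beadTypes", "BeadTypeSequence", function(x) unlist(x@chains))
#' @rdname accessors
#' @export
setMethod("beadTypes", "Ensemble", function(x) x@types)
#' @rdname accessors
#' @export
setMethod("ensembleCoords", "Ensemble", function(x) x@coords)
#' @rdname accessors
#' @export
setMethod("energyValues", "EnergyMatrix", function(x) x@E)
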