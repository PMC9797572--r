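#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: `scores()` returns
#' the numeric score matrix of an [InfectionMatrix-class], `cycleCount()`,
#' `etaFinal()` and `etaDiff()` the layers of a [DominanceMap-class],
#' `predictorValues()`/`predictorInfo()` the parts of a
#' [GenotypeMatrix-class], `pValue()`/`observedStat()`/`nullDraws()` the
#' parts of a [PermutationResult-class], and `flaggedGenes()` the genes a
#' [MultiHitResult-class] calls significant.
#'
#' @param x an object of the matching class.
#' @return the slot contents (matrix, numeric or character as documented).
#' @name accessors
#' @aliases scores cycleCount etaFinal etaDiff predictorValues predictorInfo
#'   pValue observedStat nullDraws flaggedGenes selectedCoef
NULL

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("cycleCount", function(x) standardGeneric("cycleCount"))

#' @rdname accessors
#' @export
setGeneric("etaFinal", function(x) standardGeneric("etaFinal"))

#' @rdname accessors
#' @export
setGeneric("etaDiff", function(x) standardGeneric("etaDiff"))

#' @rdname accessors
#' @export
setGeneric("medianCycles", function(x) standardGeneric("medianCycles"))

#' @rdname accessors
#' @export
setGeneric("predictorValues", function(x) standardGeneric("predictorValues"))

#' @rdname accessors
#' @export
setGeneric("predictorInfo", function(x) standardGeneric("predictorInfo"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("observedStat", function(x) standardGeneric("observedStat"))

#' @rdname accessors
#' @export
setGeneric("nullDraws", function(x) standardGeneric("nullDraws"))

#' @rdname accessors
#' @export
setGeneric("flaggedGenes", function(x) standardGeneric("flaggedGenes"))

#' @rdname accessors
#' @export
setGeneric("selectedCoef", function(x) standardGeneric("selectedCoef"))
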