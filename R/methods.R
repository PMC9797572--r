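# Accessor and show methods for the S4 containers.

#' @rdname accessors
setMethod("scores", "InfectionMatrix", function(x) x@scores)

#' @rdname accessors
setMethod("cycleCount", "DominanceMap", function(x) x@cycleCount)

#' @rdname accessors
setMethod("etaFinal", "DominanceMap", function(x) x@etaFinal)

#' @rdname accessors
setMethod("etaDiff", "DominanceMap", function(x) x@etaDiff)

#' @rdname accessors
setMethod("medianCycles", "DominanceMap", function(x) x@medianCycles)

#' @rdname accessors
setMethod("predictorValues", "GenotypeMatrix", function(x) x@values)

#' @rdname accessors
setMethod("predictorInfo", "GenotypeMatrix", function(x) x@predictorInfo)

#' @rdname accessors
setMethod("pValue", "PermutationResult", function(x) x@pValue)

#' @rdname accessors
setMethod("observedStat", "PermutationResult", function(x) x@observed)

#' @rdname accessors
setMethod("nullDraws", "PermutationResult", function(x) x@nullDraws)

#' @rdname accessors
setMethod("flaggedGenes", "MultiHitResult", function(x) x@flagged)

#' @rdname accessors
setMethod("selectedCoef", "LassoFit", function(x) {
  cf <- x@coefficients
  cf[cf != 0]
})

setMethod("show", "IntensityStack", function(object) {
  d <- dim(object@values)
  cat("IntensityStack:", d[1], "frames x", d[2], "x", d[3], "px,",
      object@frameInterval, "min/frame\n")
  cat("  intensity range:", paste(signif(range(object@values), 4), collapse = " - "), "\n")
})

setMethod("show", "DominanceMap", function(object) {
  d <- dim(object@cycleCount)
  cat("DominanceMap:", d[1], "x", d[2], "blocks\n")
  cat("  median cycles (active blocks):", object@medianCycles,
      " [activity floor", object@activityFloor, "]\n")
  cat("  cycle range:", paste(range(object@cycleCount), collapse = " - "), "\n")
})

setMethod("show", "InfectionMatrix", function(object) {
  s <- object@scores
  cat("InfectionMatrix:", nrow(s), "phage x", ncol(s), "bacteria,",
      sum(is.na(s)), "missing\n")
  if (length(object@rowControls) || length(object@colControls))
    cat("  controls:", length(object@rowControls), "phage,",
        length(object@colControls), "bacterial\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@values), "isolates x",
      ncol(object@values), "predictors (",
      sum(object@predictorInfo$amplification), "copy-number )\n")
})

setMethod("show", "BipartiteStats", function(object) {
  cat("BipartiteStats (binary network, fill", signif(object@fill, 3), ")\n")
  cat("  NODF nestedness:", signif(object@nestedness, 4),
      " p =", signif(object@pNestedness, 4), "\n")
  cat("  Barber modularity Q_b:", signif(object@modularity, 4),
      " p =", signif(object@pModularity, 4), "\n")
  cat("  null draws:", object@nNull, " seed:", object@seed, "\n")
})

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult [", object@statistic, "]\n")
  cat("  observed:", object@observed, " p =", signif(object@pValue, 4),
      " (", object@nReps, "draws, seed", object@seed, ")\n")
})

setMethod("show", "MultiHitResult", function(object) {
  cat("MultiHitResult:", length(object@observedCounts), "genes,",
      object@nReps, "replicates, alpha =", object@alpha, "\n")
  cat("  threshold c* =", object@threshold, "; flagged:",
      if (length(object@flagged)) paste(object@flagged, collapse = ", ") else "none", "\n")
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation:", length(object@sequence), "bp,",
      length(object@orfs), "ORFs\n")
})

setMethod("show", "LassoFit", function(object) {
  nz <- selectedCoef(object)
  cat("LassoFit:", length(object@lambda), "penalties, selected lambda =",
      signif(object@lambdaSel, 4), "(1-SE rule)\n")
  cat("  nonzero coefficients:", length(nz), "\n")
})
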