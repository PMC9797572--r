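#' @import methods
#' @importFrom stats median quantile cor dist hclust cutree rbinom rnorm runif setNames sd aggregate
#' @importFrom utils read.delim write.table read.csv write.csv head
NULL

#' IntensityStack: a time-lapse intensity field
#'
#' Container for a T x H x W stack of dark-field intensities (0--255) as
#' produced by [preprocessStack()] or [simTimelapse()]. The first array
#' dimension is time; `frameInterval` records the acquisition spacing in
#' minutes and is carried along so frame indices can be mapped to wall time.
#'
#' @slot values numeric array, `c(T, H, W)`, intensities in \[0, 255\].
#' @slot frameInterval single numeric, minutes between frames.
#' @exportClass IntensityStack
setClass("IntensityStack",
  representation(values = "array", frameInterval = "numeric"),
  prototype(frameInterval = 10)
)

setValidity("IntensityStack", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("'values' must be a 3-d array (frames, rows, cols)")
  if (d[1] < 1L) return("stack needs at least one frame")
  if (anyNA(object@values) || !all(is.finite(object@values)))
    return("intensities must be finite")
  rng <- range(object@values)
  if (rng[1] < 0 || rng[2] > 255) return("intensities must lie in [0, 255]")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    return("'frameInterval' must be a single positive number")
  TRUE
})

#' DominanceMap: per-block cycle counts and dominance summaries
#'
#' Result of [cycleDominanceMap()]: for every spatial block, the final
#' intensity (eta_final, high where bacteria hold the territory), the lost
#' intensity eta_max - eta_final (high where phage cleared a formerly dense
#' population), and the number of growth--lysis cycles counted as intensity
#' peaks. `medianCycles` is the plate-wide median over blocks whose maximal
#' intensity exceeded `activityFloor`.
#'
#' @slot etaFinal,etaDiff,cycleCount matrices of identical dimension (blocks).
#' @slot medianCycles single numeric (NA when no block is active).
#' @slot activityFloor intensity floor used for the median.
#' @exportClass DominanceMap
setClass("DominanceMap",
  representation(etaFinal = "matrix", etaDiff = "matrix", cycleCount = "matrix",
                 medianCycles = "numeric", activityFloor = "numeric")
)

setValidity("DominanceMap", function(object) {
  d <- dim(object@etaFinal)
  if (!identical(d, dim(object@etaDiff)) || !identical(d, dim(object@cycleCount)))
    return("layer dimensions disagree")
  if (any(object@etaDiff < -1e-9)) return("'etaDiff' must be non-negative")
  if (any(object@cycleCount < 0)) return("'cycleCount' must be non-negative")
  TRUE
})

#' InfectionMatrix: phage x bacteria infectivity scores
#'
#' Cross-infection scores in \[0, 1\] with phage isolates as rows and
#' bacterial isolates as columns; `NA` marks unmeasured pairs. Wildtype
#' control isolates on either axis can be flagged so concordance checks know
#' which profiles to compare.
#'
#' @slot scores numeric matrix with dimnames (phage ids, bacterium ids).
#' @slot rowControls,colControls character, isolate ids of wildtype controls.
#' @slot rowReplicate,colReplicate character, evolutionary replicate labels
#'   (may be empty).
#' @exportClass InfectionMatrix
setClass("InfectionMatrix",
  representation(scores = "matrix",
                 rowControls = "character", colControls = "character",
                 rowReplicate = "character", colReplicate = "character"),
  prototype(rowControls = character(), colControls = character(),
            rowReplicate = character(), colReplicate = character())
)

setValidity("InfectionMatrix", function(object) {
  s <- object@scores
  if (is.null(rownames(s)) || is.null(colnames(s)))
    return("'scores' needs row and column isolate ids")
  v <- s[!is.na(s)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    return("scores must lie in [0, 1]")
  if (!all(object@rowControls %in% rownames(s)))
    return("unknown row control id")
  if (!all(object@colControls %in% colnames(s)))
    return("unknown column control id")
  if (length(object@rowReplicate) && length(object@rowReplicate) != nrow(s))
    return("'rowReplicate' length mismatch")
  if (length(object@colReplicate) && length(object@colReplicate) != ncol(s))
    return("'colReplicate' length mismatch")
  TRUE
})

#' GenotypeMatrix: isolates x encoded mutation predictors
#'
#' Predictor encoding of per-isolate mutations: binary columns for SNPs,
#' insertions, deletions and IS elements; integer copy-number columns for
#' amplifications (ancestral state 1). `predictorInfo` carries one metadata
#' row per column (label, gene, type, coordinates, amplification flag).
#'
#' @slot values numeric matrix, isolates as rows.
#' @slot predictorInfo data.frame with one row per predictor column.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(values = "matrix", predictorInfo = "data.frame")
)

setValidity("GenotypeMatrix", function(object) {
  if (nrow(object@predictorInfo) != ncol(object@values))
    return("'predictorInfo' must have one row per predictor")
  if (is.null(rownames(object@values))) return("isolate ids missing")
  if (!all(c("label", "amplification") %in% colnames(object@predictorInfo)))
    return("predictorInfo needs 'label' and 'amplification' columns")
  TRUE
})

#' BipartiteStats: nestedness and modularity of a binary infection network
#'
#' Holds NODF nestedness (0--1 scale), Barber bipartite modularity Q_b with
#' its module assignment, and their permutation p-values under the
#' equiprobable Bernoulli null.
#'
#' @slot nestedness,modularity observed statistics.
#' @slot rowModules,colModules integer module labels.
#' @slot pNestedness,pModularity add-one permutation p-values in (0, 1\].
#' @slot nNull number of null draws; `fill` the observed fill fraction.
#' @slot seed RNG seed used for the null.
#' @exportClass BipartiteStats
setClass("BipartiteStats",
  representation(nestedness = "numeric", modularity = "numeric",
                 rowModules = "integer", colModules = "integer",
                 pNestedness = "numeric", pModularity = "numeric",
                 nNull = "integer", fill = "numeric", seed = "integer")
)

setValidity("BipartiteStats", function(object) {
  for (p in c(object@pNestedness, object@pModularity))
    if (!is.na(p) && (p <= 0 || p > 1)) return("p-values must lie in (0, 1]")
  TRUE
})

#' PermutationResult: observed statistic vs. permutation null
#'
#' @slot statistic name of the statistic.
#' @slot observed observed value.
#' @slot nullDraws numeric vector of null statistics (length `nReps`).
#' @slot pValue add-one empirical p-value, (1 + exceedances) / (1 + nReps).
#' @slot nReps,seed integers.
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(statistic = "character", observed = "numeric",
                 nullDraws = "numeric", pValue = "numeric",
                 nReps = "integer", seed = "integer")
)

setValidity("PermutationResult", function(object) {
  if (length(object@nullDraws) != object@nReps)
    return("null draw count must equal nReps")
  if (object@pValue <= 0 || object@pValue > 1) return("p must lie in (0, 1]")
  TRUE
})

#' MultiHitResult: multiply-mutated-gene simulation outcome
#'
#' Per-gene observed mutation-event counts, the null distribution of the
#' replicate-wise maximal per-gene count under uniform re-placement, the
#' derived significance threshold `threshold` (smallest count attained by at
#' most `alpha` of the replicates) and the flagged genes.
#'
#' @slot observedCounts named numeric, events per gene.
#' @slot nullMax per-replicate maxima under the null.
#' @slot threshold the count threshold c*.
#' @slot flagged character, genes with observed count >= c*.
#' @slot nReps,seed integers; `alpha` the family-wise level.
#' @exportClass MultiHitResult
setClass("MultiHitResult",
  representation(observedCounts = "numeric", nullMax = "numeric",
                 threshold = "numeric", flagged = "character",
                 nReps = "integer", alpha = "numeric", seed = "integer")
)

setValidity("MultiHitResult", function(object) {
  # family-wise (max-based) results carry a finite global threshold; the
  # per-gene variant stores NA and checks thresholds gene by gene
  if (length(object@threshold) == 1L && is.finite(object@threshold)) {
    want <- names(object@observedCounts)[object@observedCounts >= object@threshold]
    if (!setequal(want, object@flagged))
      return("flagged genes must be exactly those reaching the threshold")
  }
  TRUE
})

#' GenomeAnnotation: a nucleotide sequence with ORF annotation
#'
#' @slot sequence a [Biostrings::DNAString] (the full genome).
#' @slot orfs a [GenomicRanges::GRanges] of coding regions; lengths divisible
#'   by 3, names are gene identifiers.
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
  representation(sequence = "ANY", orfs = "ANY")
)

setValidity("GenomeAnnotation", function(object) {
  if (!is(object@sequence, "DNAString")) return("'sequence' must be a DNAString")
  if (!is(object@orfs, "GRanges")) return("'orfs' must be a GRanges")
  w <- GenomicRanges::width(object@orfs)
  if (any(w %% 3L != 0L)) return("ORF lengths must be divisible by 3")
  if (length(object@orfs) &&
      max(GenomicRanges::end(object@orfs)) > length(object@sequence))
    return("ORF beyond sequence end")
  TRUE
})

#' LassoFit: cross-validated Lasso path and one-standard-error selection
#'
#' @slot lambda penalty grid (decreasing).
#' @slot cvm,cvsd cross-validated mean squared error and its standard error.
#' @slot lambdaMin,lambdaSel the CV-minimising and 1-SE-selected penalties.
#' @slot intercept model intercept at `lambdaSel`.
#' @slot coefficients named numeric: all coefficients at `lambdaSel` on the
#'   original predictor scale (zeros included).
#' @slot cvfit the underlying `cv.glmnet` object.
#' @slot seed fold-assignment seed.
#' @exportClass LassoFit
setClass("LassoFit",
  representation(lambda = "numeric", cvm = "numeric", cvsd = "numeric",
                 lambdaMin = "numeric", lambdaSel = "numeric",
                 intercept = "numeric", coefficients = "numeric",
                 cvfit = "ANY", seed = "integer")
)
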