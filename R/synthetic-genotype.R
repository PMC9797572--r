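#' Simulate genotype tables and an infection matrix with planted effects
#'
#' Generates a bacterial and a phage isolate library with random binary
#' mutation predictors, plants a sparse additive effect vector, and renders
#' the infectivity score of every (phage, bacterium) pair as
#' \deqn{clip(baseline + \sum_j \beta_j x_j^{joint} + \epsilon,\ 0,\ 1)}
#' where the joint genotype concatenates the bacterial and phage
#' predictors. This is exactly the structure the Lasso association stage
#' assumes, so planted support and signs are recoverable ground truth.
#'
#' By default the planted effects follow the biology: bacterial effects are
#' resistance-like (negative), phage effects infectivity-like (positive),
#' with magnitudes drawn uniformly from `effectRange`. A full `beta` vector
#' (length `nMutBact + nMutPhage`) can be supplied instead.
#'
#' Every mutation is carried independently with probability `carrierProb`,
#' so isolates can stack several effect mutations; pairs whose additive
#' score leaves \[0, 1\] are clipped, which mimics complete resistance
#' (score 0) and saturated infection (score 1) in the assay.
#'
#' @param nBacteria,nPhage isolate counts.
#' @param nMutBact,nMutPhage predictor counts per organism.
#' @param sparsity fraction of predictors with nonzero effect.
#' @param effectRange magnitude range of nonzero effects.
#' @param carrierProb probability an isolate carries a given mutation.
#' @param baseline infectivity intercept (mid-scale by default, maximising
#'   the unclipped linear range).
#' @param noiseSd Gaussian noise sd on the score scale.
#' @param beta optional explicit effect vector (bacterial then phage).
#' @param seed RNG seed.
#' @return list: `bactGM`, `phageGM` ([GenotypeMatrix-class]), `im`
#'   ([InfectionMatrix-class]), `beta` (named, bacterial then phage),
#'   `support` (names of nonzero effects), `baseline`.
#' @examples
#' sim <- simGenotypePhenotype(nBacteria = 10, nPhage = 8, seed = 1)
#' dim(scores(sim$im))
#' @export
simGenotypePhenotype <- function(nBacteria = 25L, nPhage = 20L,
                                 nMutBact = 25L, nMutPhage = 25L,
                                 sparsity = 0.1, effectRange = c(0.3, 0.5),
                                 carrierProb = 0.35, baseline = 0.5,
                                 noiseSd = 0.05, beta = NULL, seed = 1L) {
  p <- nMutBact + nMutPhage
  withSeed(seed, {
    bact <- matrix(rbinom(nBacteria * nMutBact, 1L, carrierProb),
                   nBacteria, nMutBact,
                   dimnames = list(sprintf("Bac%02d", seq_len(nBacteria)),
                                   sprintf("bmut%02d", seq_len(nMutBact))))
    phage <- matrix(rbinom(nPhage * nMutPhage, 1L, carrierProb),
                    nPhage, nMutPhage,
                    dimnames = list(sprintf("Phi%02d", seq_len(nPhage)),
                                    sprintf("pmut%02d", seq_len(nMutPhage))))
    if (is.null(beta)) {
      beta <- numeric(p)
      nEff <- max(0L, round(sparsity * p))
      supp <- sample.int(p, nEff)
      mag <- runif(nEff, effectRange[1], effectRange[2])
      sign <- ifelse(supp <= nMutBact, -1, 1)   # resistance vs infectivity
      beta[supp] <- sign * mag
    } else {
      if (length(beta) != p) stop("'beta' must have one entry per predictor")
    }
    names(beta) <- c(colnames(bact), colnames(phage))

    lin <- baseline +
      outer(drop(phage %*% beta[-seq_len(nMutBact)]),
            drop(bact %*% beta[seq_len(nMutBact)]), `+`)
    if (noiseSd > 0) lin <- lin + rnorm(length(lin), sd = noiseSd)
    m <- clamp(lin, 0, 1)
    dimnames(m) <- list(rownames(phage), rownames(bact))

    mkInfo <- function(cols) data.frame(
      label = cols, gene = cols, type = "SNP",
      start = seq_along(cols), end = seq_along(cols),
      amplification = FALSE, stringsAsFactors = FALSE)
    list(bactGM = new("GenotypeMatrix", values = bact * 1.0,
                      predictorInfo = mkInfo(colnames(bact))),
         phageGM = new("GenotypeMatrix", values = phage * 1.0,
                       predictorInfo = mkInfo(colnames(phage))),
         im = new("InfectionMatrix", scores = m),
         beta = beta, support = names(beta)[beta != 0], baseline = baseline)
  })
}

#' Emit mutation-table TSVs for a simulated genotype library
#'
#' Renders the binary predictors of [simGenotypePhenotype()] as SNP records
#' in the mutation-table dialect, one file per organism, so the encoding
#' stage can be exercised on files.
#'
#' @param sim result of [simGenotypePhenotype()].
#' @param dir output directory.
#' @return named character vector of the two paths.
#' @export
writeSimMutationTables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  render <- function(gm, organism) {
    v <- predictorValues(gm)
    idx <- which(v != 0, arr.ind = TRUE)
    data.frame(isolate_id = rownames(v)[idx[, 1]],
               replicate_id = "R1", organism = organism, type = "SNP",
               start = idx[, 2], end = idx[, 2], ref = "A", alt = "G",
               copy_number = NA, effect = "nonsynonymous",
               gene = colnames(v)[idx[, 2]])
  }
  paths <- c(bacteria = file.path(dir, "bacteria_mutations.tsv"),
             phage = file.path(dir, "phage_mutations.tsv"))
  writeMutationTable(render(sim$bactGM, "bacterium"), paths["bacteria"])
  writeMutationTable(render(sim$phageGM, "phage"), paths["phage"])
  paths
}
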