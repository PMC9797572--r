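#' Construct a genome annotation
#'
#' @param sequence genome sequence: a [Biostrings::DNAString] or a character
#'   string.
#' @param orfs a [GenomicRanges::GRanges] of coding regions (names = gene
#'   ids, lengths divisible by 3), or a data.frame with columns `start`,
#'   `end`, `strand`, `gene`.
#' @return a [GenomeAnnotation-class].
#' @export
genomeAnnotation <- function(sequence, orfs) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (is.data.frame(orfs)) {
    gr <- GenomicRanges::GRanges("genome",
            IRanges::IRanges(orfs$start, orfs$end),
            strand = if (is.null(orfs$strand)) "+" else orfs$strand)
    names(gr) <- if (is.null(orfs$gene)) paste0("orf", seq_len(nrow(orfs)))
                 else orfs$gene
    orfs <- gr
  }
  if (is.null(names(orfs))) names(orfs) <- paste0("orf", seq_along(orfs))
  new("GenomeAnnotation", sequence = sequence, orfs = orfs)
}

tsPartner <- c(A = "G", G = "A", C = "T", T = "C")

#' Transition or transversion class of a substitution
#'
#' @param ref,alt single nucleotides (character vectors recycle).
#' @return character vector, `"transition"` or `"transversion"`.
#' @export
substitutionClass <- function(ref, alt) {
  if (any(ref == alt)) stop("ref and alt must differ")
  unname(ifelse(tsPartner[toupper(ref)] == toupper(alt),
                "transition", "transversion"))
}

# Per-ORF-position mutation-effect lookup. For every nucleotide position of
# the concatenated ORFs (in reading-frame orientation): whether the
# transition at that site is nonsynonymous (nsTs) and how many of the two
# transversions are (nsTvCount, 0..2). Stop gains/losses count as
# nonsynonymous; stop-to-stop as synonymous.
nonsynLookup <- function(genome) {
  stopifnot(is(genome, "GenomeAnnotation"))
  code <- Biostrings::GENETIC_CODE
  orfs <- genome@orfs
  if (!length(orfs)) stop("genome without ORFs")
  nsTs <- logical(0); nsTv <- integer(0); orfIdx <- integer(0)
  for (g in seq_along(orfs)) {
    sq <- Biostrings::subseq(genome@sequence,
                             GenomicRanges::start(orfs)[g],
                             GenomicRanges::end(orfs)[g])
    if (as.character(GenomicRanges::strand(orfs)[g]) == "-")
      sq <- Biostrings::reverseComplement(sq)
    s <- as.character(sq)
    L <- nchar(s)
    codons <- substring(s, seq(1, L, 3), seq(3, L, 3))
    aa0 <- code[codons]
    refb <- strsplit(s, "")[[1]]
    posInCodon <- rep(1:3, L / 3)
    codonOf <- rep(seq_len(L / 3), each = 3)
    ns <- matrix(FALSE, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    for (b in c("A", "C", "G", "T")) {
      mut <- codons[codonOf]
      substr(mut, posInCodon, posInCodon) <- b
      ns[, b] <- code[mut] != aa0[codonOf]
    }
    tsb <- tsPartner[refb]
    allb <- c("A", "C", "G", "T")
    iTs <- ns[cbind(seq_len(L), match(tsb, allb))]
    iTv <- vapply(seq_len(L), function(i) {
      tv <- setdiff(allb, c(refb[i], tsb[i]))
      sum(ns[i, tv])
    }, integer(1))
    nsTs <- c(nsTs, iTs); nsTv <- c(nsTv, iTv)
    orfIdx <- c(orfIdx, rep(g, L))
  }
  list(nsTs = nsTs, nsTvCount = nsTv, orf = orfIdx)
}

#' Analytic per-placement nonsynonymous probabilities of a genome
#'
#' Enumerates every single-base substitution over all ORF positions against
#' the standard genetic code and returns the probability that a uniformly
#' placed transition (`qTs`) or transversion (`qTv`, alt drawn uniformly
#' between the two partners) is nonsynonymous.
#'
#' @param genome a [GenomeAnnotation-class].
#' @return list: `qTs`, `qTv`, `nPositions`.
#' @export
nonsynProbability <- function(genome) {
  lk <- nonsynLookup(genome)
  list(qTs = mean(lk$nsTs), qTv = mean(lk$nsTvCount) / 2,
       nPositions = length(lk$nsTs))
}

#' Classify a SNP as intergenic, synonymous or nonsynonymous
#'
#' A position outside every ORF is intergenic. Otherwise the containing
#' codon is translated before and after the substitution (on the coding
#' strand: minus-strand ORFs are handled by reverse complement); the SNP is
#' synonymous iff the amino acid is unchanged, with stop gains and losses
#' counted as nonsynonymous. A position inside overlapping ORFs is
#' classified against each and called nonsynonymous if it is nonsynonymous
#' in any of them (with a warning).
#'
#' @param genome a [GenomeAnnotation-class].
#' @param position 1-based genomic position.
#' @param ref,alt nucleotides; `ref` must match the genome.
#' @return `"intergenic"`, `"synonymous"` or `"nonsynonymous"`.
#' @export
classifySnp <- function(genome, position, ref, alt) {
  stopifnot(is(genome, "GenomeAnnotation"))
  ref <- toupper(ref); alt <- toupper(alt)
  if (ref == alt) stop("ref and alt must differ")
  if (position < 1 || position > length(genome@sequence))
    stop("position outside the genome")
  if (as.character(genome@sequence[position]) != ref)
    stop("ref allele mismatch at position ", position)
  orfs <- genome@orfs
  hit <- which(GenomicRanges::start(orfs) <= position &
               GenomicRanges::end(orfs) >= position)
  if (!length(hit)) return("intergenic")
  if (length(hit) > 1) warning("position ", position, " in overlapping ORFs")
  code <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  effects <- vapply(hit, function(g) {
    minus <- as.character(GenomicRanges::strand(orfs)[g]) == "-"
    if (minus) {
      off <- GenomicRanges::end(orfs)[g] - position + 1L
      r <- comp[ref]; a <- comp[alt]
      sq <- Biostrings::reverseComplement(
        Biostrings::subseq(genome@sequence, GenomicRanges::start(orfs)[g],
                           GenomicRanges::end(orfs)[g]))
    } else {
      off <- position - GenomicRanges::start(orfs)[g] + 1L
      r <- ref; a <- alt
      sq <- Biostrings::subseq(genome@sequence, GenomicRanges::start(orfs)[g],
                               GenomicRanges::end(orfs)[g])
    }
    s <- as.character(sq)
    ci <- (off - 1L) %/% 3L
    codon <- substr(s, ci * 3L + 1L, ci * 3L + 3L)
    p <- off - ci * 3L
    stopifnot(substr(codon, p, p) == r)
    mut <- codon
    substr(mut, p, p) <- a
    if (code[codon] == code[mut]) "synonymous" else "nonsynonymous"
  }, character(1))
  if (any(effects == "nonsynonymous")) "nonsynonymous" else "synonymous"
}

#' dN/dS permutation test preserving transition/transversion classes
#'
#' Tests whether the observed excess of nonsynonymous over synonymous SNPs
#' exceeds what uniform placement explains: each unique intragenic SNP
#' event is re-placed uniformly over all ORF nucleotide positions (longer
#' ORFs proportionally more often), its alt allele drawn to preserve its
#' own substitution class -- a transition keeps its unique partner, a
#' transversion picks uniformly between its two -- and the simulated
#' nonsynonymous count is compared with the observed one over `n`
#' replicates. Intergenic SNPs are excluded. Recurrent events (multiplicity
#' > 1) contribute one placement counted once by default; with
#' `weightByMultiplicity = TRUE` they are placed (and counted) once per
#' replicate plate they appeared in.
#'
#' The p-value is the add-one estimator
#' `(1 + #\{sim nonsyn >= observed nonsyn\}) / (1 + n)`.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param snps data.frame with columns `position`, `ref`, `alt` and
#'   optionally `multiplicity`.
#' @param n permutation replicates (default 10000).
#' @param seed RNG seed.
#' @param weightByMultiplicity count recurrent events once per replicate
#'   plate instead of once.
#' @return a [PermutationResult-class] (statistic `"nonsynonymous count"`).
#' @export
dndsPermutation <- function(genome, snps, n = 10000L, seed = 1L,
                            weightByMultiplicity = FALSE) {
  snps <- as.data.frame(snps)
  if (is.null(snps$multiplicity)) snps$multiplicity <- 1L
  eff <- vapply(seq_len(nrow(snps)), function(i)
    classifySnp(genome, snps$position[i], snps$ref[i], snps$alt[i]),
    character(1))
  intra <- snps[eff != "intergenic", , drop = FALSE]
  effIn <- eff[eff != "intergenic"]
  if (!nrow(intra)) stop("no intragenic SNPs")
  cls <- substitutionClass(intra$ref, intra$alt)
  mult <- if (weightByMultiplicity) intra$multiplicity else rep(1L, nrow(intra))
  observed <- sum((effIn == "nonsynonymous") * mult)
  sTs <- sum(mult[cls == "transition"])
  sTv <- sum(mult[cls == "transversion"])

  lk <- nonsynLookup(genome)
  P <- length(lk$nsTs)
  nulls <- withSeed(seed, {
    cTs <- if (sTs > 0) {
      pos <- sample.int(P, n * sTs, replace = TRUE)
      rowSums(matrix(lk$nsTs[pos], nrow = n))
    } else numeric(n)
    cTv <- if (sTv > 0) {
      pos <- sample.int(P, n * sTv, replace = TRUE)
      hitp <- lk$nsTvCount[pos] / 2
      rowSums(matrix(runif(n * sTv) < hitp, nrow = n))
    } else numeric(n)
    cTs + cTv
  })
  newPermutationResult("nonsynonymous count", observed, nulls, seed)
}

#' Multiply-mutated-gene simulation
#'
#' Detects genes accumulating more independent mutation events than a
#' uniform-placement null allows. Every mutation event keeps all its
#' properties except position; per replicate, each event is re-placed
#' uniformly over the genome -- an event seen in `m` parallel replicate
#' plates is drawn `m` times, and an interval event (deletion,
#' amplification) marks every gene it overlaps. The default family-wise
#' criterion records each replicate's maximal per-gene count and sets the
#' significance threshold `c*` to the smallest count attained by at most
#' `alpha` of the replicates; genes whose observed count reaches `c*` are
#' flagged. `mode = "pergene"` instead thresholds each gene against its own
#' null counts.
#'
#' @param mutations data.frame with columns `start`, `end` (1-based
#'   inclusive; equal for point events) and optionally `multiplicity`.
#' @param genome a [GenomeAnnotation-class]; its ORFs are the genes.
#' @param nReps simulation replicates (>= 100).
#' @param alpha significance level.
#' @param seed RNG seed.
#' @param mode `"max"` (family-wise, default) or `"pergene"`.
#' @return a [MultiHitResult-class].
#' @export
multihitSimulation <- function(mutations, genome, nReps = 500L, alpha = 0.05,
                               seed = 1L, mode = c("max", "pergene")) {
  mode <- match.arg(mode)
  stopifnot(is(genome, "GenomeAnnotation"))
  if (nReps < 100L) stop("'nReps' must be at least 100")
  mutations <- as.data.frame(mutations)
  if (!nrow(mutations)) stop("empty mutation set")
  if (is.null(mutations$multiplicity)) mutations$multiplicity <- 1L
  orfs <- genome@orfs
  G <- length(genome@sequence)
  gs <- GenomicRanges::start(orfs); ge <- GenomicRanges::end(orfs)
  ord <- order(gs)
  gs <- gs[ord]; ge <- ge[ord]
  geneNames <- names(orfs)[ord]
  nG <- length(gs)
  if (any(gs[-1] <= ge[-nG]))
    warning("overlapping genes: interval overlap counts may double-count")

  lens <- mutations$end - mutations$start + 1L
  mult <- mutations$multiplicity

  hitRange <- function(p, L) {
    # contiguous index range of genes overlapping [p, p+L-1]; 0-length if none
    g1 <- findInterval(p - 1L, ge) + 1L       # first gene ending at/after p
    g2 <- findInterval(p + L - 1L, gs)        # last gene starting at/before end
    if (g1 > g2 || g1 > nG) integer(0) else g1:g2
  }

  observed <- numeric(nG)
  for (i in seq_len(nrow(mutations))) {
    hits <- hitRange(mutations$start[i], lens[i])
    observed[hits] <- observed[hits] + mult[i]
  }
  names(observed) <- geneNames

  nullMax <- numeric(nReps)
  exceed <- numeric(nG)   # per-gene: replicates reaching the observed count
  drawsPer <- rep(seq_len(nrow(mutations)), times = mult)
  withSeed(seed, {
    for (r in seq_len(nReps)) {
      counts <- numeric(nG)
      pos <- floor(runif(length(drawsPer)) * (G - lens[drawsPer] + 1L)) + 1L
      for (k in seq_along(drawsPer)) {
        hits <- hitRange(pos[k], lens[drawsPer[k]])
        counts[hits] <- counts[hits] + 1
      }
      nullMax[r] <- if (nG) max(counts) else 0
      exceed <- exceed + (counts >= observed)
    }
  })

  if (mode == "max") {
    cstar <- max(nullMax) + 1
    for (c in sort(unique(c(1, nullMax, nullMax + 1)))) {
      if (mean(nullMax >= c) <= alpha) { cstar <- c; break }
    }
    flagged <- geneNames[observed >= cstar]
  } else {
    pg <- (1 + exceed) / (1 + nReps)
    flagged <- geneNames[pg <= alpha & observed > 0]
    cstar <- NA_real_
  }
  new("MultiHitResult", observedCounts = observed, nullMax = nullMax,
      threshold = cstar, flagged = flagged, nReps = as.integer(nReps),
      alpha = alpha, seed = as.integer(seed))
}
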