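# Independent oracles used to validate the package implementations.
# These deliberately re-derive each quantity from its definition with
# different code paths (naive loops, exhaustive enumeration, exact closed
# forms) and are kept free of package internals.

# Naive NODF straight from the definition: loop over all row pairs and all
# column pairs; a pair contributes overlap/min(fill) iff fills differ.
oracleNodf <- function(b) {
  contrib <- function(x, y) {
    fx <- sum(x); fy <- sum(y)
    if (fx == fy) return(0)
    sum(x & y) / min(fx, fy)
  }
  tot <- 0; np <- 0
  for (i in seq_len(nrow(b) - 1)) for (j in (i + 1):nrow(b)) {
    tot <- tot + contrib(b[i, ], b[j, ]); np <- np + 1
  }
  for (i in seq_len(ncol(b) - 1)) for (j in (i + 1):ncol(b)) {
    tot <- tot + contrib(b[, i], b[, j]); np <- np + 1
  }
  tot / np
}

# All set partitions of n elements as restricted-growth strings.
setPartitions <- function(n) {
  out <- vector("list", 0)
  rec <- function(a, k, i) {
    if (i > n) { out[[length(out) + 1L]] <<- a; return(invisible()) }
    for (j in seq_len(k + 1L)) { a[i] <- j; rec(a, max(k, j), i + 1L) }
  }
  rec(integer(n), 0L, 1L)
  out
}

# Exhaustive Barber modularity: maximize Q over every joint partition of
# the r + c nodes. Only feasible for tiny matrices.
oracleBarberQ <- function(b) {
  r <- nrow(b); cc <- ncol(b)
  m <- sum(b)
  k <- rowSums(b); d <- colSums(b)
  best <- -Inf
  for (part in setPartitions(r + cc)) {
    gr <- part[seq_len(r)]; gc <- part[r + seq_len(cc)]
    q <- 0
    for (i in seq_len(r)) for (j in seq_len(cc)) {
      if (gr[i] == gc[j]) q <- q + b[i, j] - k[i] * d[j] / m
    }
    best <- max(best, q / m)
  }
  best
}

# Per-base coverage oracle for interval segmentation: the set of bases an
# isolate's segments cover must equal the bases its original intervals cover.
oracleCoveredBases <- function(starts, ends) {
  sort(unique(unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))))
}

# Independent per-placement nonsynonymous probability of a genome, using
# seqinr's translation instead of the package's lookup machinery.
oracleNonsynProb <- function(genome) {
  orfs <- genome@orfs
  full <- as.character(genome@sequence)
  nTs <- 0; hitTs <- 0; nTv <- 0; hitTv <- 0
  tsOf <- c(A = "G", G = "A", C = "T", T = "C")
  for (g in seq_along(orfs)) {
    s <- substr(full, GenomicRanges::start(orfs)[g], GenomicRanges::end(orfs)[g])
    if (as.character(GenomicRanges::strand(orfs)[g]) == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    ch <- strsplit(s, "")[[1]]
    for (i in seq_along(ch)) {
      ci <- (i - 1) %/% 3
      codon <- ch[(ci * 3 + 1):(ci * 3 + 3)]
      aa0 <- seqinr::translate(codon)
      p <- i - ci * 3
      for (alt in setdiff(c("A", "C", "G", "T"), ch[i])) {
        mut <- codon; mut[p] <- alt
        ns <- seqinr::translate(mut) != aa0
        if (alt == tsOf[ch[i]]) { nTs <- nTs + 1; hitTs <- hitTs + ns }
        else { nTv <- nTv + 1; hitTv <- hitTv + ns }
      }
    }
  }
  list(qTs = hitTs / nTs, qTv = hitTv / nTv)
}

# Independent Monte-Carlo of the multihit null maximum for point events on
# a tiling gene set (different placement and counting code than the package).
oracleMultihitMax <- function(nEvents, geneStarts, geneEnds, genomeLen, nReps,
                              seed) {
  set.seed(seed)
  vapply(seq_len(nReps), function(r) {
    pos <- sample.int(genomeLen, nEvents, replace = TRUE)
    counts <- table(cut(pos, breaks = c(geneStarts - 0.5,
                                        geneEnds[length(geneEnds)] + 0.5)))
    max(as.integer(counts))
  }, numeric(1))
}

dropEmptyLines <- function(b) b[rowSums(b) > 0, colSums(b) > 0, drop = FALSE]

# Small deterministic infection matrix used by several network tests.
toyInfectionMatrix <- function() {
  m <- rbind(c(1.0, 0.8, 0.6, 0.0),
             c(0.9, 0.7, 0.0, 0.0),
             c(0.8, 0.0, 0.0, 0.0))
  dimnames(m) <- list(paste0("P", 1:3), paste0("B", 1:4))
  new("InfectionMatrix", scores = m)
}
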