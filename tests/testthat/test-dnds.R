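test_that("SNP effects classify against the standard code on both strands", {
  g <- genomeAnnotation(paste0("TTTT", "ATGAAATAA", "TTTT"),
                        data.frame(start = 5, end = 13, strand = "+",
                                   gene = "g1"))
  expect_equal(classifySnp(g, 2, "T", "C"), "intergenic")
  expect_equal(classifySnp(g, 10, "A", "G"), "synonymous")     # AAA -> AAG
  expect_equal(classifySnp(g, 8, "A", "G"), "nonsynonymous")   # AAA -> GAA
  expect_error(classifySnp(g, 8, "C", "G"), "mismatch")

  # the same codon on the minus strand agrees after reverse complement
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGAAATAA")))
  g2 <- genomeAnnotation(paste0("TTTT", rc, "TTTT"),
                         data.frame(start = 5, end = 13, strand = "-",
                                    gene = "g1"))
  # genomic position mirroring ORF offset 6 (A->G) is 13 - 6 + 1 = 8, T->C
  expect_equal(classifySnp(g2, 8, "T", "C"), "synonymous")
  expect_equal(classifySnp(g2, 10, "T", "C"), "nonsynonymous")
})

test_that("substitution classes split transitions from transversions", {
  expect_equal(substitutionClass(c("A", "C", "A"), c("G", "T", "T")),
               c("transition", "transition", "transversion"))
  expect_error(substitutionClass("A", "A"), "differ")
})

test_that("toy genome compositions have the advertised nonsynonymous structure", {
  tgg <- simToyGenome(nOrfs = 2, orfCodons = 30, composition = "allTGG",
                      seed = 1)
  expect_equal(tgg$qTs, 1)    # every change of TGG is nonsynonymous
  expect_equal(tgg$qTv, 1)

  ff <- simToyGenome(nOrfs = 2, orfCodons = 40, composition = "fourfold",
                     seed = 2)
  # third positions are all synonymous: probabilities strictly below 1
  expect_lt(ff$qTs, 1)
  lk <- nonsynProbability(ff$genome)
  expect_equal(lk$qTs, ff$qTs)

  # analytic probabilities agree with an independent enumeration
  mx <- simToyGenome(nOrfs = 3, orfCodons = 25, composition = "mixed",
                     seed = 3, minusStrand = 2)
  ind <- oracleNonsynProb(mx$genome)
  expect_equal(mx$qTs, ind$qTs, tolerance = 1e-12)
  expect_equal(mx$qTv, ind$qTv, tolerance = 1e-12)
})

test_that("toy genomes round-trip through FASTA + GFF3", {
  toy <- simToyGenome(nOrfs = 3, orfCodons = 20, seed = 5, minusStrand = 3)
  fa <- withr::local_tempfile(fileext = ".fasta")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeGenomeAnnotation(toy$genome, fa, gff)
  back <- readGenomeAnnotation(fa, gff)
  expect_equal(as.character(back@sequence), as.character(toy$genome@sequence))
  expect_equal(GenomicRanges::start(back@orfs),
               GenomicRanges::start(toy$genome@orfs))
  expect_equal(as.character(GenomicRanges::strand(back@orfs)),
               as.character(GenomicRanges::strand(toy$genome@orfs)))
  expect_equal(names(back@orfs), names(toy$genome@orfs))
})

test_that("the all-TGG genome pins the permutation p-value at 1", {
  toy <- simToyGenome(nOrfs = 2, orfCodons = 30, composition = "allTGG",
                      seed = 1)
  st <- GenomicRanges::start(toy$genome@orfs[1])
  pos <- st + c(1, 7, 12)
  snps <- data.frame(position = pos,
                     ref = vapply(pos, function(p)
                       as.character(toy$genome@sequence[p]), character(1)),
                     alt = NA)
  snps$alt <- ifelse(snps$ref == "T", "C", "A")   # any change works
  pr <- dndsPermutation(toy$genome, snps, n = 400, seed = 2)
  expect_equal(observedStat(pr), 3)
  expect_equal(pValue(pr), 1)
})

test_that("simulated nonsynonymous counts match the exact binomial tail", {
  toy <- simToyGenome(nOrfs = 4, orfCodons = 60, composition = "mixed",
                      seed = 6)
  g <- toy$genome
  # plant transitions at known intragenic positions
  st <- GenomicRanges::start(g@orfs)
  pos <- as.vector(outer(c(2, 20, 40, 55), st, `+`))
  ref <- vapply(pos, function(p) as.character(g@sequence[p]), character(1))
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  snps <- data.frame(position = pos, ref = ref, alt = unname(ts[ref]))
  pr <- dndsPermutation(g, snps, n = 4000, seed = 3)
  s <- length(pos)
  pExact <- 1 - pbinom(observedStat(pr) - 1, s, toy$qTs)
  se <- sqrt(pExact * (1 - pExact) / 4000)
  expect_lt(abs(pValue(pr) - pExact), 3 * se + 1 / 4000)
  # null draw mean matches the binomial mean
  expect_lt(abs(mean(nullDraws(pr)) - s * toy$qTs),
            4 * sqrt(s * toy$qTs * (1 - toy$qTs) / 4000))

  # reproducibility
  pr2 <- dndsPermutation(g, snps, n = 4000, seed = 3)
  expect_identical(pValue(pr), pValue(pr2))
  expect_identical(nullDraws(pr), nullDraws(pr2))
})

test_that("dN/dS p-values are uniform when the data come from the null", {
  toy <- simToyGenome(nOrfs = 4, orfCodons = 60, composition = "mixed",
                      seed = 8)
  g <- toy$genome
  lk <- phagecoev:::nonsynLookup(g)
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  orfStart <- GenomicRanges::start(g@orfs)
  orfPos <- unlist(lapply(seq_along(g@orfs), function(i)
    orfStart[i] + seq_len(GenomicRanges::width(g@orfs)[i]) - 1L))
  # placements drawn with replacement, matching the null's own placement
  # rule; enough SNPs that the count statistic is effectively continuous
  set.seed(99)
  ps <- vapply(1:120, function(r) {
    pos <- sample(orfPos, 100, replace = TRUE)
    ref <- vapply(pos, function(p) as.character(g@sequence[p]), character(1))
    snps <- data.frame(position = pos, ref = ref, alt = unname(ts[ref]))
    pValue(dndsPermutation(g, snps, n = 500, seed = r))
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("multihit nulls behave at both extremes and stay reproducible", {
  # one gene spanning the whole genome: c* = M + 1 and nothing flagged
  g <- genomeAnnotation(paste(rep("ACG", 300), collapse = ""),
                        data.frame(start = 1, end = 900, strand = "+",
                                   gene = "big"))
  mut <- data.frame(start = c(10, 50, 100), end = c(10, 50, 100))
  mh <- multihitSimulation(mut, g, nReps = 300, seed = 1)
  expect_equal(mh@threshold, 4)
  expect_length(flaggedGenes(mh), 0)

  # planted hotspot among 100 tiling genes is flagged
  genes <- data.frame(start = seq(1, 3000, 30), end = seq(30, 3000, 30),
                      strand = "+", gene = sprintf("g%03d", 1:100))
  gt <- genomeAnnotation(paste(rep("A", 3000), collapse = ""), genes)
  hot <- genes$start[50] + 1:6
  mut2 <- data.frame(start = c(hot, 200, 800, 1500, 2500),
                     end = c(hot, 200, 800, 1500, 2500))
  mh2 <- multihitSimulation(mut2, gt, nReps = 1000, seed = 2)
  expect_true("g050" %in% flaggedGenes(mh2))

  mh3 <- multihitSimulation(mut2, gt, nReps = 1000, seed = 2)
  expect_identical(mh2@nullMax, mh3@nullMax)
  expect_identical(flaggedGenes(mh2), flaggedGenes(mh3))
})

test_that("multiplicity, intervals and per-gene mode shape the multihit null", {
  genes <- data.frame(start = seq(1, 901, 100), end = seq(1, 901, 100) + 89,
                      strand = "+", gene = paste0("g", 1:10))
  g <- genomeAnnotation(paste(rep("A", 1000), collapse = ""), genes)

  # an interval event marks every overlapped gene
  mut <- data.frame(start = 150, end = 450)
  mh <- multihitSimulation(mut, g, nReps = 150, seed = 3)
  expect_equal(sum(mh@observedCounts > 0), 4)   # genes 2..5

  # parallel events draw once per replicate plate
  mutM <- data.frame(start = 150, end = 150, multiplicity = 4)
  mhM <- multihitSimulation(mutM, g, nReps = 150, seed = 4)
  expect_equal(max(mhM@observedCounts), 4)

  # adding events to a flagged gene never unflags it
  hot <- data.frame(start = rep(155, 5), end = rep(155, 5))
  base <- rbind(hot, data.frame(start = c(50, 250), end = c(50, 250)))
  mh1 <- multihitSimulation(base, g, nReps = 400, seed = 5)
  more <- rbind(base, data.frame(start = 160, end = 160))
  mh2 <- multihitSimulation(more, g, nReps = 400, seed = 5)
  expect_true(all(flaggedGenes(mh1) %in% c(flaggedGenes(mh2), "")))

  # per-gene mode agrees on a clear hotspot
  mhP <- multihitSimulation(base, g, nReps = 400, seed = 5, mode = "pergene")
  expect_true("g2" %in% flaggedGenes(mhP))
})
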