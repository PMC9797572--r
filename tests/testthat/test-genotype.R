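test_that("coverage normalization is scale-invariant and flags CNV runs", {
  anc <- rep(c(40, 60), each = 500)
  iso <- anc
  r0 <- normalizeCoverage(iso, anc)
  expect_equal(r0$cnorm, rep(1, 1000))
  expect_equal(nrow(r0$candidates), 0)

  # a region at twice the isolate's own median, ancestor flat
  anc2 <- rep(50, 1000)
  iso2 <- rep(30, 1000); iso2[301:500] <- 60
  r1 <- normalizeCoverage(iso2, anc2)
  expect_equal(unique(r1$cnorm[301:500]), 2)
  expect_equal(r1$candidates$start, 301)
  expect_equal(r1$candidates$end, 500)
  expect_equal(r1$candidates$type, "amplification")

  # global sequencing-depth scaling cancels
  r3 <- normalizeCoverage(iso2 * 3, anc2)
  expect_equal(r3$cnorm, r1$cnorm)

  # zero ancestral coverage is masked with a warning
  anc3 <- anc2; anc3[10] <- 0
  expect_warning(r4 <- normalizeCoverage(iso2, anc3), "masked")
  expect_true(is.na(r4$cnorm[10]))
})

test_that("overlapping interval events segment into shared unique events", {
  ev <- data.frame(isolate_id = c("A", "B"), type = "deletion",
                   start = c(1000, 2000), end = c(3000, 4000))
  seg <- segmentEvents(ev)
  expect_equal(length(unique(seg$segment_id)), 3)
  shared <- seg$segment_id[duplicated(seg$segment_id)]
  expect_equal(sort(seg$isolate_id[seg$segment_id == shared]), c("A", "B"))

  # disjoint events unchanged
  ev2 <- data.frame(isolate_id = c("A", "B"), type = "deletion",
                    start = c(100, 900), end = c(200, 950))
  expect_equal(length(unique(segmentEvents(ev2)$segment_id)), 2)

  # nested intervals partition at both endpoints
  ev3 <- data.frame(isolate_id = c("A", "B"), type = "amplification",
                    start = c(100, 200), end = c(500, 300),
                    copy_number = c(2, 3))
  seg3 <- segmentEvents(ev3)
  expect_equal(sum(seg3$isolate_id == "A"), 3)
  expect_equal(sum(seg3$isolate_id == "B"), 1)
})

test_that("segmentation conserves covered bases against a per-base oracle", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    st <- sample(1:500, n)
    ev <- data.frame(isolate_id = sample(LETTERS[1:3], n, replace = TRUE),
                     type = "deletion", start = st,
                     end = st + sample(10:200, n, replace = TRUE))
    seg <- segmentEvents(ev)
    for (iso in unique(ev$isolate_id)) {
      want <- oracleCoveredBases(ev$start[ev$isolate_id == iso],
                                 ev$end[ev$isolate_id == iso])
      got <- oracleCoveredBases(seg$segment_start[seg$isolate_id == iso],
                                seg$segment_end[seg$isolate_id == iso])
      expect_equal(got, want)
    }
    # segments of one event never overlap each other
    for (r in seq_len(nrow(ev))) {
      s <- seg[seg$isolate_id == ev$isolate_id[r] & seg$start == ev$start[r], ]
      s <- s[order(s$segment_start), ]
      if (nrow(s) > 1)
        expect_true(all(s$segment_start[-1] > s$segment_end[-nrow(s)]))
    }
  }
})

test_that("predictor encoding follows the binary / copy-number rules", {
  rec <- data.frame(isolate_id = "i1", type = "SNP", start = 100, end = 100,
                    ref = "A", alt = "G", copy_number = NA,
                    effect = "nonsynonymous", gene = "mlaA")
  gm <- encodePredictors(rec, isolates = c("i1", "i2"))
  expect_equal(unname(predictorValues(gm)[, 1]), c(1, 0))

  amp <- data.frame(isolate_id = "i1", type = "amplification", start = 10,
                    end = 400, ref = NA, alt = NA, copy_number = 3,
                    effect = NA, gene = "opgG")
  gm2 <- encodePredictors(amp, isolates = c("i1", "i2"))
  expect_equal(unname(predictorValues(gm2)[, 1]), c(3, 1))  # ancestral copy 1
  expect_true(predictorInfo(gm2)$amplification)

  syn <- transform(rec, effect = "synonymous")
  expect_equal(ncol(predictorValues(encodePredictors(syn))), 0)

  conflict <- rbind(rec, transform(rec, alt = "T"))
  expect_error(encodePredictors(conflict), "conflicting")
})

test_that("co-occurring predictors join except amplifications", {
  rec <- data.frame(
    isolate_id = c("i1", "i1", "i2"),
    type = c("SNP", "insertion", "SNP"),
    start = c(100, 300, 700), end = c(100, 300, 700),
    ref = c("A", NA, "C"), alt = c("G", "TT", "T"),
    copy_number = NA, effect = c("nonsynonymous", "inframe", "nonsynonymous"),
    gene = c("mlaA", "mlaA", "trxA"))
  gm <- encodePredictors(rec, isolates = c("i1", "i2", "i3"))
  joined <- joinCooccurring(gm)
  expect_equal(ncol(predictorValues(joined)), 2)
  expect_true(any(grepl("\\+", predictorInfo(joined)$label)))
  # idempotent
  expect_equal(predictorValues(joinCooccurring(joined)),
               predictorValues(joined))

  # identical-pattern amplification and SNP stay separate
  rec2 <- data.frame(
    isolate_id = c("i1", "i1"), type = c("SNP", "amplification"),
    start = c(100, 200), end = c(100, 600), ref = c("A", NA),
    alt = c("G", NA), copy_number = c(NA, 4),
    effect = c("nonsynonymous", NA), gene = c("aceE", "lon"))
  gm2 <- joinCooccurring(encodePredictors(rec2, isolates = c("i1", "i2")))
  expect_equal(ncol(predictorValues(gm2)), 2)
})

test_that("pair observations pool identical joint genotypes", {
  # two phage with identical genotypes, one bacterium, scores 0.2 / 0.4
  bact <- new("GenotypeMatrix",
              values = matrix(1, 1, 1, dimnames = list("B1", "bm1")),
              predictorInfo = data.frame(label = "bm1", amplification = FALSE))
  phage <- new("GenotypeMatrix",
               values = matrix(0, 2, 1, dimnames = list(c("P1", "P2"), "pm1")),
               predictorInfo = data.frame(label = "pm1", amplification = FALSE))
  m <- matrix(c(0.2, 0.4), 2, 1, dimnames = list(c("P1", "P2"), "B1"))
  im <- new("InfectionMatrix", scores = m)
  obs <- buildObservations(bact, phage, im)
  expect_equal(nrow(obs$x), 1)
  expect_equal(obs$y, 0.3)
  expect_equal(obs$weight, 2L)

  # unique genotypes: one observation per scored pair; weights sum to pairs
  sim <- simGenotypePhenotype(nBacteria = 6, nPhage = 5, nMutBact = 8,
                              nMutPhage = 8, noiseSd = 0, seed = 4)
  o2 <- buildObservations(sim$bactGM, sim$phageGM, sim$im)
  expect_equal(sum(o2$weight), 30)
  expect_true(all(o2$y >= 0 & o2$y <= 1))
})

test_that("mutation tables round-trip through TSV", {
  rec <- data.frame(isolate_id = c("i1", "i2"), replicate_id = c("R1", "R2"),
                    organism = "bacterium",
                    type = c("SNP", "amplification"),
                    start = c(10L, 100L), end = c(10L, 600L),
                    ref = c("A", NA), alt = c("G", NA),
                    copy_number = c(NA, 3L),
                    effect = c("nonsynonymous", NA),
                    gene = c("mlaA", "opgG"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeMutationTable(rec, path)
  back <- readMutationTable(path)
  expect_equal(back$isolate_id, rec$isolate_id)
  expect_equal(back$copy_number, rec$copy_number)
  bad <- transform(rec, copy_number = c(NA, 1L))
  writeMutationTable(bad, path)
  expect_error(readMutationTable(path), "copy_number")
})
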