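test_that("matrix assembly averages duplicates and leaves unmeasured pairs NA", {
  tab <- data.frame(phage_id = c("P1", "P1", "P2", "P1"),
                    bacterium_id = c("B1", "B2", "B1", "B1"),
                    infectivity = c(0.2, 0.4, 1, 0.4))
  im <- assembleMatrix(tab)
  m <- scores(im)
  expect_equal(m["P1", "B1"], 0.3)           # duplicate averaged
  expect_equal(m["P2", "B1"], 1)
  expect_true(is.na(m["P2", "B2"]))          # unmeasured
  expect_equal(dim(m), c(2, 2))
})

test_that("control concordance matches closed-form correlations", {
  m <- matrix(NA_real_, 3, 10,
              dimnames = list(paste0("P", 1:3), paste0("B", 1:10)))
  x <- seq(0, 0.9, length.out = 10)
  m[1, ] <- x
  m[2, ] <- pmin(1, 2 * x / 3 + 0.1)         # affine in x
  y <- c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1)  # zero covariance with x? no:
  m[3, ] <- (y - min(y)) / 4 + 0.25          # construct orthogonal below
  # make row 3 exactly uncorrelated with row 1
  xc <- x - mean(x)
  v <- rep(c(0.2, 0.6), 5)
  vc <- v - mean(v) - sum((v - mean(v)) * xc) / sum(xc^2) * xc
  m[3, ] <- vc - min(vc)
  m <- m / max(m, na.rm = TRUE)
  im <- new("InfectionMatrix", scores = m, rowControls = paste0("P", 1:3))
  r2 <- concordanceR2(im, axis = "phage")
  expect_equal(r2$r2[r2$id1 == "P1" & r2$id2 == "P2"], 1)
  expect_equal(r2$r2[r2$id1 == "P1" & r2$id2 == "P3"], 0, tolerance = 1e-12)

  # too few shared observations is an error
  m2 <- matrix(c(0.1, 0.2, NA, NA, NA, 0.4, 0.5, 0.3), 2, 4, byrow = TRUE,
               dimnames = list(c("Pa", "Pb"), paste0("B", 1:4)))
  im2 <- new("InfectionMatrix", scores = m2)
  expect_error(concordanceR2(im2, c("Pa", "Pb"), axis = "phage"), "shared")
})

test_that("complete-linkage classes cut at 40% of maximum linkage", {
  m <- matrix(rep(c(0.5, 0.5, 0.5), each = 4), 3, 4, byrow = TRUE,
              dimnames = list(paste0("P", 1:3), paste0("B", 1:4)))
  expect_equal(length(unique(clusterIsolates(m, "phage")$classes)), 1)

  # two tight blocks far apart: the 40% cut separates exactly the blocks
  set.seed(3)
  prof <- rbind(matrix(0, 4, 6), matrix(10, 4, 6)) +
    matrix(runif(48, 0, 0.5), 8, 6)
  rownames(prof) <- paste0("I", 1:8); colnames(prof) <- paste0("B", 1:6)
  ca <- clusterIsolates(prof / max(prof), "phage")
  expect_equal(length(unique(ca$classes)), 2)
  expect_equal(length(unique(ca$classes[1:4])), 1)
  expect_equal(length(unique(ca$classes[5:8])), 1)

  # permuting the input rows leaves the partition unchanged
  perm <- sample(8)
  ca2 <- clusterIsolates(prof[perm, ] / max(prof), "phage")
  expect_true(all(outer(ca$classes, ca$classes, "==") ==
                  outer(ca2$classes[rownames(prof)],
                        ca2$classes[rownames(prof)], "==")))
})

test_that("missing cells take the mean of their 5x5 sorted neighbourhood", {
  m <- matrix(0.5, 6, 6); m[3, 3] <- NA
  expect_equal(imputeMissing(m)[3, 3], 0.5)

  # corner cell: mean of the in-bounds present neighbours
  m2 <- matrix(0.25, 3, 3); m2[1, 1] <- NA
  expect_equal(imputeMissing(m2)[1, 1], 0.25)

  m3 <- matrix(runif(36), 6, 6)
  expect_equal(imputeMissing(m3), m3)        # nothing missing: unchanged

  # present values are never altered and results stay in [0, 1]
  m4 <- matrix(runif(100), 10, 10); m4[c(5, 50, 95)] <- NA
  out <- imputeMissing(m4)
  expect_equal(out[!is.na(m4)], m4[!is.na(m4)])
  expect_true(all(out >= 0 & out <= 1))

  m5 <- matrix(NA_real_, 6, 6); m5[1, 1] <- 0.2
  expect_error(imputeMissing(m5), "neighbourhood")
})

test_that("binarization uses a strict threshold", {
  expect_true(all(binarizeMatrix(matrix(0, 3, 3)) == 0))
  expect_equal(sort(unique(as.vector(binarizeMatrix(matrix(c(0, 0.3), 2, 2))))),
               c(0L, 1L))
  expect_equal(as.vector(binarizeMatrix(matrix(0.5, 1, 2), threshold = 0.5)),
               c(0L, 0L))
})

test_that("NODF matches its definition, the examples and vegan", {
  expect_equal(nodf(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))), 1)
  expect_equal(nodf(matrix(1, 3, 3)), 0)
  expect_equal(nodf(rbind(c(1, 0), c(0, 1))), 0)

  set.seed(7)
  for (i in 1:20) {
    b <- matrix(rbinom(35, 1, 0.5), 5, 7)
    b <- b[rowSums(b) > 0, colSums(b) > 0, drop = FALSE]
    if (nrow(b) < 2 || ncol(b) < 2) next
    expect_equal(nodf(b), oracleNodf(b))
    # permutation invariance
    expect_equal(nodf(b[sample(nrow(b)), sample(ncol(b))]), nodf(b))
    # independent implementation
    veg <- unname(vegan::nestednodf(b, order = TRUE,
                                    weighted = FALSE)$statistic["NODF"]) / 100
    expect_equal(nodf(b), veg, tolerance = 1e-12)
  }
})

test_that("modularity search attains the exhaustive optimum on small matrices", {
  # closed-form instances
  b2 <- matrix(0, 4, 4); b2[1:2, 1:2] <- 1; b2[3:4, 3:4] <- 1
  res <- barberModularity(b2)
  expect_equal(res$Q, 0.5)
  expect_equal(res$rowModules[1], res$colModules[1])
  expect_false(res$rowModules[1] == res$rowModules[3])
  expect_equal(barberModularity(matrix(1, 3, 3))$Q, 0)

  # brute force over every partition, random 3x3 instances
  set.seed(21)
  for (i in 1:15) {
    b <- matrix(rbinom(9, 1, 0.5), 3, 3)
    if (sum(b) == 0) next
    expect_equal(barberModularity(b, nRestarts = 20, seed = i)$Q,
                 oracleBarberQ(b), tolerance = 1e-9)
  }
  # Q is never below the single-module value 0
  set.seed(22)
  for (i in 1:10) {
    b <- matrix(rbinom(24, 1, 0.3), 4, 6)
    if (sum(b) == 0) next
    expect_gte(barberModularity(b, seed = i)$Q, 0)
  }
})

test_that("the equiprobable null is reproducible and sane at the extremes", {
  set.seed(5)
  b <- matrix(rbinom(100, 1, 0.5), 10, 10)
  p1 <- equiprobableNull(b, "nodf", n = 300, seed = 9)
  p2 <- equiprobableNull(b, "nodf", n = 300, seed = 9)
  expect_identical(pValue(p1), pValue(p2))
  expect_identical(nullDraws(p1), nullDraws(p2))
  expect_error(equiprobableNull(matrix(1, 3, 3), "nodf"), "fill")

  # a strongly nested observed matrix beats Bernoulli noise
  nest <- outer(1:8, 1:8, function(i, j) as.integer(i + j <= 9))
  nest[1, ] <- 1; nest[, 1] <- 1
  pr <- equiprobableNull(nest, "nodf", n = 300, seed = 1)
  expect_lt(pValue(pr), 0.05)
  # and a statistic below every null draw gives p near 1
  anti <- (matrix(1, 8, 8) - diag(8))        # equal fills: NODF 0
  pa <- equiprobableNull(anti, "nodf", n = 300, seed = 2)
  expect_gt(pValue(pa), 0.95)
})

test_that("bipartiteStats runs the full imputation-to-significance path", {
  m <- rbind(c(1.0, 0.9, 0.6, 0.4, 0.0, 0.0),
             c(0.9, 0.8, 0.5, NA,  0.0, 0.0),
             c(0.7, 0.6, 0.0, 0.0, 0.0, 0.0),
             c(0.0, 0.0, 0.0, 0.0, 0.9, 0.8),
             c(0.0, NA,  0.0, 0.0, 0.8, 0.9))
  dimnames(m) <- list(paste0("P", 1:5), paste0("B", 1:6))
  im <- new("InfectionMatrix", scores = m)
  bs <- bipartiteStats(im, nNull = 200, seed = 4)
  expect_true(bs@nestedness >= 0 && bs@nestedness <= 1)
  expect_true(bs@modularity >= 0)
  expect_true(bs@pNestedness > 0 && bs@pNestedness <= 1)
  expect_equal(bs@nNull, 200L)
})

test_that("infection matrices round-trip through the CSV dialect", {
  im <- toyInfectionMatrix()
  im@scores[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  writeInfectionMatrix(im, path)
  back <- readInfectionMatrix(path)
  expect_equal(scores(back), scores(im))
})
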