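#' Assemble a cross-infection matrix from per-spot score tables
#'
#' Combines one or more per-spot score tables (columns `phage_id`,
#' `bacterium_id`, `infectivity`) into a phage x bacteria
#' [InfectionMatrix-class]. Pairs measured more than once (across plates)
#' are averaged; pairs never measured are `NA`.
#'
#' @param ... data.frames of scored spots, or a single list of them.
#' @param rowControls,colControls isolate ids of wildtype controls on the
#'   phage and bacterial axes.
#' @param rowReplicate,colReplicate optional named character vectors mapping
#'   isolate ids to coevolution replicate labels.
#' @return an [InfectionMatrix-class].
#' @examples
#' tab <- data.frame(phage_id = c("P1", "P1", "P2"),
#'                   bacterium_id = c("B1", "B2", "B1"),
#'                   infectivity = c(0.2, 0.4, 1))
#' assembleMatrix(tab)
#' @export
assembleMatrix <- function(..., rowControls = character(),
                           colControls = character(),
                           rowReplicate = NULL, colReplicate = NULL) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]]))
    tabs <- tabs[[1]]
  df <- do.call(rbind, lapply(tabs, function(t) {
    need <- c("phage_id", "bacterium_id", "infectivity")
    if (!all(need %in% names(t)))
      stop("score tables need columns phage_id, bacterium_id, infectivity")
    t[need]
  }))
  if (!nrow(df)) stop("no scored pairs")
  df$phage_id <- as.character(df$phage_id)
  df$bacterium_id <- as.character(df$bacterium_id)
  ph <- sort(unique(df$phage_id))
  ba <- sort(unique(df$bacterium_id))
  agg <- aggregate(infectivity ~ phage_id + bacterium_id, data = df, FUN = mean)
  m <- matrix(NA_real_, length(ph), length(ba), dimnames = list(ph, ba))
  m[cbind(match(agg$phage_id, ph), match(agg$bacterium_id, ba))] <- agg$infectivity
  rr <- if (is.null(rowReplicate)) character() else unname(rowReplicate[ph])
  cr <- if (is.null(colReplicate)) character() else unname(colReplicate[ba])
  new("InfectionMatrix", scores = m,
      rowControls = as.character(rowControls),
      colControls = as.character(colControls),
      rowReplicate = rr, colReplicate = cr)
}

#' Pairwise R-squared concordance between control isolates
#'
#' For every pair of wildtype control isolates on one axis, the squared
#' Pearson correlation of their score vectors across the other axis,
#' dropping missing entries pairwise. Used to check that replicate wildtype
#' profiles agree (the assay's reproducibility check).
#'
#' @param im an [InfectionMatrix-class].
#' @param controlIds isolate ids (>= 2) on the chosen axis; defaults to the
#'   controls recorded in the object.
#' @param axis `"phage"` (rows) or `"bacteria"` (columns).
#' @return data.frame with columns `id1`, `id2`, `n` (shared observations)
#'   and `r2`.
#' @export
concordanceR2 <- function(im, controlIds = NULL,
                          axis = c("bacteria", "phage")) {
  stopifnot(is(im, "InfectionMatrix"))
  axis <- match.arg(axis)
  profiles <- if (axis == "phage") t(scores(im)) else scores(im)
  # columns of `profiles` are now the isolates being compared
  if (is.null(controlIds))
    controlIds <- if (axis == "phage") im@rowControls else im@colControls
  if (length(controlIds) < 2L) stop("need at least two controls on the axis")
  if (!all(controlIds %in% colnames(profiles))) stop("unknown control id")
  pairs <- utils::combn(controlIds, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- profiles[, pairs[1, k]]; b <- profiles[, pairs[2, k]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3L) stop("fewer than 3 shared observations for pair ",
                           pairs[1, k], " / ", pairs[2, k])
    data.frame(id1 = pairs[1, k], id2 = pairs[2, k], n = sum(ok),
               r2 = cor(a[ok], b[ok])^2)
  })
  do.call(rbind, out)
}

#' Cluster isolates into phenotypic classes
#'
#' Hierarchical clustering of isolate score profiles: Euclidean pairwise
#' distances, complete-linkage agglomeration, classes cut at
#' `cutFraction` (default 40%) of the maximum merge height. Profiles must be
#' complete; impute or drop missing scores first.
#'
#' @param im an [InfectionMatrix-class] (or plain score matrix).
#' @param axis `"phage"` clusters rows, `"bacteria"` clusters columns.
#' @param cutFraction fraction of the maximum linkage height at which
#'   classes are cut.
#' @return list of class `ClassAssignment`: `tree` (hclust), `classes`
#'   (named integer), `cutHeight`, `order` (leaf order, isolate ids),
#'   `axis`.
#' @export
clusterIsolates <- function(im, axis = c("phage", "bacteria"),
                            cutFraction = 0.4) {
  axis <- match.arg(axis)
  m <- if (is(im, "InfectionMatrix")) scores(im) else as.matrix(im)
  profiles <- if (axis == "phage") m else t(m)
  if (nrow(profiles) < 2L) stop("need at least 2 isolates on the axis")
  if (anyNA(profiles)) stop("profiles contain missing values; impute first")
  h <- hclust(dist(profiles, method = "euclidean"), method = "complete")
  cutHeight <- cutFraction * max(h$height)
  cls <- cutree(h, h = cutHeight)
  structure(list(tree = h, classes = cls, cutHeight = cutHeight,
                 order = rownames(profiles)[h$order], axis = axis),
            class = "ClassAssignment")
}

#' Impute missing scores from the class-sorted neighbourhood
#'
#' In the class-sorted matrix (rows and columns ordered by their dendrogram
#' leaf order), each missing cell is replaced by the mean of the present
#' values in its 5x5 surrounding window, truncated at the matrix edges.
#' Present values are never altered. A missing cell whose whole
#' neighbourhood is missing is an error.
#'
#' @param im an [InfectionMatrix-class] or plain matrix.
#' @param rowOrder,colOrder isolate orderings (ids or indices) defining the
#'   class-sorted layout; defaults keep the current order.
#' @param window odd window side (default 5).
#' @return matrix in the sorted order with no missing values (an
#'   [InfectionMatrix-class] is returned when one was supplied).
#' @export
imputeMissing <- function(im, rowOrder = NULL, colOrder = NULL, window = 5L) {
  if (window %% 2L != 1L) stop("'window' must be odd")
  isIM <- is(im, "InfectionMatrix")
  m <- if (isIM) scores(im) else as.matrix(im)
  if (!is.null(rowOrder)) m <- m[rowOrder, , drop = FALSE]
  if (!is.null(colOrder)) m <- m[, colOrder, drop = FALSE]
  half <- (window - 1L) / 2L
  miss <- which(is.na(m), arr.ind = TRUE)
  out <- m
  for (k in seq_len(nrow(miss))) {
    i <- miss[k, 1]; j <- miss[k, 2]
    ri <- max(1, i - half):min(nrow(m), i + half)
    cj <- max(1, j - half):min(ncol(m), j + half)
    nb <- m[ri, cj]
    if (all(is.na(nb)))
      stop("missing cell (", i, ",", j, ") has an empty neighbourhood")
    out[i, j] <- mean(nb, na.rm = TRUE)
  }
  if (isIM) {
    res <- im
    res@scores <- out
    res@rowReplicate <- character(); res@colReplicate <- character()
    res
  } else out
}

#' Binarize an infection matrix
#'
#' Entry 1 iff the score is strictly greater than `threshold` (default 0:
#' any detectable lysis counts as an interaction).
#'
#' @param m matrix (no missing values) or [InfectionMatrix-class].
#' @param threshold strict lower cut.
#' @return integer 0/1 matrix.
#' @export
binarizeMatrix <- function(m, threshold = 0) {
  if (is(m, "InfectionMatrix")) m <- scores(m)
  if (anyNA(m)) stop("binarize after imputation: matrix has missing values")
  (m > threshold) * 1L
}

# Drop all-zero rows and columns (the BiMat-style ignore rule).
dropEmpty <- function(b) {
  b[rowSums(b) > 0, colSums(b) > 0, drop = FALSE]
}

#' NODF nestedness of a binary matrix
#'
#' Nestedness by Overlap and Decreasing Fill on a 0--1 scale. Every
#' unordered pair of rows (and of columns) contributes the fraction of the
#' sparser line's 1s that are shared with the denser line when their
#' marginal totals strictly differ, and 0 when they are equal; NODF is the
#' mean contribution over all row pairs and column pairs. Empty rows and
#' columns are removed first. Invariant under row/column permutation.
#'
#' @param b binary matrix (at least 2x2 after removing empty lines).
#' @return numeric in \[0, 1\].
#' @examples
#' nodf(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0)))  # perfectly nested: 1
#' @export
nodf <- function(b) {
  b <- dropEmpty(as.matrix(b))
  if (nrow(b) < 2L || ncol(b) < 2L)
    stop("matrix smaller than 2x2 after removing empty rows/columns")
  pairSum <- function(x) {                 # x: lines in rows
    f <- rowSums(x)
    ov <- tcrossprod(x)                    # shared 1s for each pair
    n <- nrow(x)
    tot <- 0
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      use <- f[i] != f[j]
      tot <- tot + sum((ov[i, j][use]) / pmin(f[i], f[j])[use])
    }
    c(tot, n * (n - 1) / 2)
  }
  r <- pairSum(b)
  cl <- pairSum(t(b))
  (r[1] + cl[1]) / (r[2] + cl[2])
}

# Barber modularity of a labelled bipartite partition.
barberQ <- function(b, gr, gc) {
  m <- sum(b)
  k <- rowSums(b); d <- colSums(b)
  bt <- b - outer(k, d) / m
  sum(bt[outer(gr, gc, "==")]) / m
}

#' Barber bipartite modularity by BRIM-style label optimization
#'
#' Maximizes the Barber bipartite modularity
#' \deqn{Q_b = (1/m) \sum_{ij} (A_{ij} - k_i d_j / m)\, \delta(g_i, g_j)}
#' over joint module assignments of rows and columns, by alternating
#' optimal reassignment of one side given the other (the BRIM recursion)
#' from multiple random initial partitions plus two deterministic ones
#' (all-one-module, and one module per column). The result is never below
#' the single-module value 0 and is deterministic given `seed`.
#'
#' @param b binary matrix with at least one edge.
#' @param nRestarts random restarts.
#' @param seed RNG seed for the restarts.
#' @return list with `Q`, `rowModules`, `colModules` (integer labels,
#'   renumbered consecutively).
#' @export
barberModularity <- function(b, nRestarts = 20L, seed = 1L) {
  b <- as.matrix(b)
  m <- sum(b)
  if (m == 0) stop("no edges")
  nr <- nrow(b); nc <- ncol(b)
  k <- rowSums(b); d <- colSums(b)
  bt <- b - outer(k, d) / m
  K <- nr + nc

  refine <- function(gc) {
    # alternate row- and column-side optimal assignment until Q stalls
    best <- list(Q = -Inf, gr = rep(1L, nr), gc = gc)
    for (it in seq_len(200L)) {
      Cmat <- t(rowsum(t(bt), gc))             # nr x modules-of-gc
      labs <- as.integer(colnames(Cmat))
      gr <- labs[max.col(Cmat, ties.method = "first")]
      Rmat <- t(rowsum(bt, gr))                # nc x modules-of-gr
      labs <- as.integer(colnames(Rmat))
      gc <- labs[max.col(Rmat, ties.method = "first")]
      q <- barberQ(b, gr, gc)
      if (q <= best$Q + 1e-12) break
      best <- list(Q = q, gr = gr, gc = gc)
    }
    best
  }

  starts <- list(rep(1L, nc), seq_len(nc))
  rand <- withSeed(seed, lapply(seq_len(nRestarts), function(i)
    sample.int(K, nc, replace = TRUE)))
  starts <- c(starts, rand)

  best <- list(Q = 0, gr = rep(1L, nr), gc = rep(1L, nc))  # single module
  for (s in starts) {
    res <- refine(s)
    if (res$Q > best$Q + 1e-12) best <- res
  }
  # renumber modules consecutively in order of first appearance
  labs <- unique(c(best$gr, best$gc))
  list(Q = best$Q,
       rowModules = match(best$gr, labs),
       colModules = match(best$gc, labs))
}

# Statistic dispatch used by the null; degenerate draws score 0.
bipartiteStatistic <- function(b, statistic) {
  b2 <- dropEmpty(b)
  if (statistic == "nodf") {
    if (nrow(b2) < 2L || ncol(b2) < 2L) return(0)
    nodf(b2)
  } else {
    if (sum(b2) == 0) return(0)
    barberModularity(b2, nRestarts = 5L, seed = 1L)$Q
  }
}

#' Equiprobable-null permutation test for nestedness or modularity
#'
#' Null matrices are i.i.d. Bernoulli(p) of the observed shape with p equal
#' to the observed fill fraction (the EQUIPROBABLE null). The observed
#' statistic and every null statistic are computed under the same rule
#' (empty rows/columns ignored; degenerate draws score 0), and the p-value
#' is the add-one estimator `(1 + #\{null >= observed\}) / (1 + n)`, so it is
#' never exactly 0 and `p < 1/n` is reported as `1/(1+n)`.
#'
#' @param b observed binary matrix.
#' @param statistic `"nodf"` or `"modularity"`.
#' @param n number of null draws (default 10000).
#' @param seed RNG seed.
#' @return a [PermutationResult-class].
#' @export
equiprobableNull <- function(b, statistic = c("nodf", "modularity"),
                             n = 10000L, seed = 1L) {
  statistic <- match.arg(statistic)
  b <- as.matrix(b)
  p <- mean(b)
  if (p <= 0 || p >= 1) stop("fill fraction must be strictly inside (0, 1)")
  obs <- bipartiteStatistic(b, statistic)
  nr <- nrow(b); nc <- ncol(b)
  nulls <- withSeed(seed, {
    vapply(seq_len(n), function(i) {
      bi <- matrix(rbinom(nr * nc, 1L, p), nr, nc)
      bipartiteStatistic(bi, statistic)
    }, numeric(1))
  })
  newPermutationResult(statistic, obs, nulls, seed)
}

#' Nestedness and modularity of an infection network with significance
#'
#' One-stop wrapper reproducing the bipartite-network analysis of a scored
#' infection matrix: impute missing cells in class-sorted order, binarize,
#' drop empty rows/columns, compute NODF and Barber modularity, and attach
#' equiprobable-null p-values.
#'
#' @param im an [InfectionMatrix-class] (scores may contain missing cells).
#' @param threshold binarization threshold (strict).
#' @param nNull null draws per statistic.
#' @param nRestarts modularity search restarts.
#' @param seed RNG seed.
#' @return a [BipartiteStats-class].
#' @export
bipartiteStats <- function(im, threshold = 0, nNull = 10000L,
                           nRestarts = 20L, seed = 1L) {
  stopifnot(is(im, "InfectionMatrix"))
  m <- scores(im)
  if (anyNA(m)) {
    ro <- clusterIsolates(imputeMissing(im), "phage")$order
    co <- clusterIsolates(imputeMissing(im), "bacteria")$order
    m <- imputeMissing(scores(im), rowOrder = ro, colOrder = co)
  }
  b <- dropEmpty(binarizeMatrix(m, threshold))
  nest <- nodf(b)
  mod <- barberModularity(b, nRestarts = nRestarts, seed = seed)
  pn <- equiprobableNull(b, "nodf", n = nNull, seed = seed)
  pm <- equiprobableNull(b, "modularity", n = nNull, seed = seed + 1L)
  new("BipartiteStats", nestedness = nest, modularity = mod$Q,
      rowModules = as.integer(mod$rowModules),
      colModules = as.integer(mod$colModules),
      pNestedness = pValue(pn), pModularity = pValue(pm),
      nNull = as.integer(nNull), fill = mean(b), seed = as.integer(seed))
}

#' Write / read the infectivity-matrix CSV dialect
#'
#' Phage isolates as rows, bacteria as columns, a leading id column and a
#' header row of bacterial ids; empty cells are missing measurements.
#'
#' @param im an [InfectionMatrix-class].
#' @param path CSV path.
#' @return `writeInfectionMatrix` the path invisibly;
#'   `readInfectionMatrix` an [InfectionMatrix-class].
#' @export
writeInfectionMatrix <- function(im, path) {
  stopifnot(is(im, "InfectionMatrix"))
  m <- scores(im)
  df <- data.frame(phage_id = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeInfectionMatrix
#' @param rowControls,colControls control ids to flag on the read object.
#' @export
readInfectionMatrix <- function(path, rowControls = character(),
                                colControls = character()) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  new("InfectionMatrix", scores = m,
      rowControls = rowControls, colControls = colControls)
}
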