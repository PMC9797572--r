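#' Normalize genome coverage against an ancestor and report CNV candidates
#'
#' Two-step normalization of per-base sequencing coverage: the isolate's
#' coverage is divided by its own median (removing sequencing depth), then
#' by the ancestor's equally median-normalized coverage at the same position
#' (removing locus-specific mappability bias). A normalized value near 2
#' indicates a duplicated region, near 0.5 a lost copy. Contiguous runs at
#' or beyond the thresholds and at least `minSpan` bp long are reported as
#' copy-number candidates for review.
#'
#' Positions where the ancestor has zero coverage cannot be normalized; they
#' are masked `NA` with a warning and break candidate runs.
#'
#' @param iso,anc equal-length non-negative coverage vectors.
#' @param highThresh,lowThresh amplification / deletion thresholds on the
#'   normalized scale.
#' @param minSpan minimum run length (bp) for a candidate.
#' @return list with `cnorm` (normalized coverage) and `candidates`
#'   (data.frame: start, end, type, meanCov).
#' @export
normalizeCoverage <- function(iso, anc, highThresh = 1.5, lowThresh = 0.5,
                              minSpan = 100L) {
  if (length(iso) != length(anc)) stop("coverage vectors differ in length")
  if (any(iso < 0) || any(anc < 0)) stop("coverage must be non-negative")
  zero <- anc == 0
  if (any(zero)) warning(sum(zero), " positions with zero ancestral coverage masked")
  cnorm <- (iso / median(iso)) / (anc / median(anc))
  cnorm[zero] <- NA_real_

  state <- ifelse(is.na(cnorm), "na",
                  ifelse(cnorm >= highThresh, "high",
                         ifelse(cnorm <= lowThresh, "low", "normal")))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("high", "low") & r$lengths >= minSpan
  candidates <- data.frame(
    start = starts[keep], end = ends[keep],
    type = ifelse(r$values[keep] == "high", "amplification", "deletion"),
    meanCov = vapply(which(keep), function(i)
      mean(cnorm[starts[i]:ends[i]]), numeric(1)))
  list(cnorm = cnorm, candidates = candidates)
}

#' Segment overlapping interval events into unique shared events
#'
#' Long deletions and amplifications that overlap between isolates are cut
#' at the union of all event endpoints, so that each original event becomes
#' a set of segments and identical segments across isolates become a single
#' shared predictor. A deletion spanning 1000--3000 bp in isolate A and one
#' spanning 2000--4000 bp in isolate B yield three unique events: the
#' A-only part, the shared middle, and the B-only part. Segmentation is done
#' independently per `type` (a deletion never merges with an amplification).
#' Coordinates are 1-based inclusive; internally the cut uses half-open
#' intervals so covered bases are conserved exactly.
#'
#' @param records data.frame of interval events with columns `isolate_id`,
#'   `type`, `start`, `end` (and any others, carried through).
#' @return data.frame with columns of `records` plus `segment_start`,
#'   `segment_end`, `segment_id`; one row per (event, covered segment).
#' @examples
#' ev <- data.frame(isolate_id = c("A", "B"), type = "deletion",
#'                  start = c(1000, 2000), end = c(3000, 4000))
#' segmentEvents(ev)
#' @export
segmentEvents <- function(records) {
  records <- as.data.frame(records)
  need <- c("isolate_id", "type", "start", "end")
  if (!all(need %in% names(records)))
    stop("records need columns isolate_id, type, start, end")
  if (any(records$start > records$end)) stop("interval start > end")
  out <- lapply(split(records, records$type), function(grp) {
    # half-open cut points over this event type
    bp <- sort(unique(c(grp$start, grp$end + 1L)))
    segs <- data.frame(s = bp[-length(bp)], e = bp[-1] - 1L)
    pieces <- lapply(seq_len(nrow(grp)), function(i) {
      within <- segs$s >= grp$start[i] & segs$e <= grp$end[i]
      cbind(grp[rep(i, sum(within)), , drop = FALSE],
            segment_start = segs$s[within], segment_end = segs$e[within])
    })
    do.call(rbind, pieces)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$segment_id <- paste0(out$type, ":", out$segment_start, "-", out$segment_end)
  out[order(out$segment_start, out$isolate_id), ]
}

# Type codes used in predictor labels, after the figure-label scheme.
typeCode <- c(SNP = "", insertion = "I", deletion = "D", IS = "IS",
              amplification = "CN")
effectCode <- c(intergenic = "ig", synonymous = "syn", nonsynonymous = "",
                frameshift = "fs", inframe = "if", disruption = "")

makeLabel <- function(gene, type, effect, start) {
  base <- ifelse(is.na(gene) | gene == "", paste0("pos", start), gene)
  tc <- typeCode[type]
  ec <- ifelse(is.na(effect), "", effectCode[effect])
  suffix <- paste0(tc, ifelse(tc != "" & ec != "", ",", ""), ec)
  ifelse(suffix == "", base, paste0(base, ":", suffix))
}

#' Encode mutation records as a predictor matrix
#'
#' Builds the isolate x predictor design used for association analysis:
#' SNPs, insertions and IS elements give binary columns; deletions and
#' amplifications are first segmented with [segmentEvents()] and each
#' segment becomes a column -- binary for deletions, integer copy number for
#' amplifications (non-carriers at the ancestral copy number 1). Synonymous
#' SNPs are omitted: they are not expected to carry phenotypic signal and
#' would only inflate the predictor set. Labels follow the
#' `gene:type,effect` scheme (D, I, IS, CN / ig, if, fs), with an index
#' appended to disambiguate repeated labels.
#'
#' @param records mutation table (see [readMutationTable()] for columns).
#' @param isolates isolate ids forming the matrix rows; defaults to those
#'   present in `records`. Supply the full library so unmutated (ancestral)
#'   isolates get all-reference rows.
#' @return a [GenotypeMatrix-class].
#' @export
encodePredictors <- function(records, isolates = NULL) {
  records <- as.data.frame(records)
  if (is.null(records$effect)) records$effect <- NA_character_
  if (is.null(records$gene)) records$gene <- NA_character_
  if (is.null(isolates)) isolates <- sort(unique(records$isolate_id))
  records <- records[!(records$type == "SNP" &
                         !is.na(records$effect) &
                         records$effect == "synonymous"), , drop = FALSE]
  isolates <- as.character(isolates)

  dup <- records[records$type == "SNP", ]
  if (nrow(dup)) {
    key <- paste(dup$isolate_id, dup$start)
    if (anyDuplicated(key)) {
      alts <- tapply(dup$alt, key, function(a) length(unique(a)))
      if (any(alts > 1)) stop("conflicting SNP records for one isolate/site")
    }
  }

  cols <- list(); info <- list()
  addCol <- function(values, label, gene, type, start, end, amplification) {
    cols[[length(cols) + 1L]] <<- values
    info[[length(info) + 1L]] <<- data.frame(
      label = label, gene = gene, type = type, start = start, end = end,
      amplification = amplification, stringsAsFactors = FALSE)
  }

  pointlike <- records[records$type %in% c("SNP", "insertion", "IS"), , drop = FALSE]
  if (nrow(pointlike)) {
    keyOf <- paste(pointlike$type, pointlike$start,
                   pointlike$ref, pointlike$alt, sep = "|")
    for (k in unique(keyOf)) {
      sub <- pointlike[keyOf == k, , drop = FALSE]
      v <- as.numeric(isolates %in% sub$isolate_id)
      addCol(v, makeLabel(sub$gene[1], sub$type[1], sub$effect[1], sub$start[1]),
             sub$gene[1], sub$type[1], sub$start[1], sub$end[1], FALSE)
    }
  }

  intervals <- records[records$type %in% c("deletion", "amplification"), , drop = FALSE]
  if (nrow(intervals)) {
    seg <- segmentEvents(intervals)
    for (sid in unique(seg$segment_id)) {
      sub <- seg[seg$segment_id == sid, , drop = FALSE]
      amp <- sub$type[1] == "amplification"
      if (amp) {
        v <- rep(1, length(isolates))
        cn <- if (!is.null(sub$copy_number)) sub$copy_number else rep(2, nrow(sub))
        v[match(sub$isolate_id, isolates)] <- cn
      } else {
        v <- as.numeric(isolates %in% sub$isolate_id)
      }
      addCol(v, makeLabel(sub$gene[1], sub$type[1], sub$effect[1],
                          sub$segment_start[1]),
             sub$gene[1], sub$type[1], sub$segment_start[1],
             sub$segment_end[1], amp)
    }
  }

  if (!length(cols)) {
    return(new("GenotypeMatrix",
               values = matrix(numeric(0), nrow = length(isolates), ncol = 0,
                               dimnames = list(isolates, NULL)),
               predictorInfo = data.frame(label = character(),
                                          gene = character(), type = character(),
                                          start = integer(), end = integer(),
                                          amplification = logical())))
  }
  values <- do.call(cbind, cols)
  rownames(values) <- isolates
  info <- do.call(rbind, info)
  # disambiguate repeated labels with an index, in genomic order
  info <- info[order(info$start), , drop = FALSE]
  values <- values[, as.integer(rownames(info)), drop = FALSE]
  dupLabels <- info$label[duplicated(info$label)]
  for (lab in unique(dupLabels)) {
    at <- which(info$label == lab)
    info$label[at] <- paste0(lab, "(", seq_along(at), ")")
  }
  colnames(values) <- info$label
  rownames(info) <- NULL
  new("GenotypeMatrix", values = values, predictorInfo = info)
}

#' Join predictors that always co-occur
#'
#' Non-amplification columns with identical value vectors carry no separate
#' information and are merged into one predictor whose compound label
#' concatenates the member labels with `+` in genomic order. Amplification
#' columns are never merged: their integer values depend on copy number and
#' identical patterns may still differ biologically. Applying the join
#' twice is a no-op.
#'
#' @param gm a [GenotypeMatrix-class].
#' @return a [GenotypeMatrix-class] with merged predictors.
#' @export
joinCooccurring <- function(gm) {
  stopifnot(is(gm, "GenotypeMatrix"))
  v <- predictorValues(gm); info <- predictorInfo(gm)
  if (!ncol(v)) return(gm)
  amp <- info$amplification
  key <- apply(v, 2, paste, collapse = ",")
  key[amp] <- paste0("amp-", seq_len(sum(amp)), "-", key[amp])  # never merge
  keep <- !duplicated(key)
  newLabel <- vapply(key[keep], function(k) {
    members <- which(key == k)
    members <- members[order(info$start[members])]
    paste(info$label[members], collapse = "+")
  }, character(1))
  v2 <- v[, keep, drop = FALSE]
  info2 <- info[keep, , drop = FALSE]
  info2$label <- unname(newLabel)
  colnames(v2) <- info2$label
  rownames(info2) <- NULL
  new("GenotypeMatrix", values = v2, predictorInfo = info2)
}

#' Build deduplicated pair observations for regression
#'
#' Joins every scored (phage, bacterium) pair into a joint genotype vector
#' (bacterial predictors followed by phage predictors) and collapses pairs
#' with identical joint genotypes into a single observation whose response
#' is the mean infectivity and whose weight is the number of pooled pairs.
#' Missing scores are dropped; weights therefore sum to the number of
#' scored pairs.
#'
#' @param bactGM,phageGM [GenotypeMatrix-class] objects whose row names
#'   match the infection matrix's column and row ids respectively.
#' @param im an [InfectionMatrix-class].
#' @return list of class `PairObservations`: `x` (unique joint genotypes x
#'   predictors), `y` (mean response), `weight`, `predictorInfo`.
#' @export
buildObservations <- function(bactGM, phageGM, im) {
  stopifnot(is(bactGM, "GenotypeMatrix"), is(phageGM, "GenotypeMatrix"),
            is(im, "InfectionMatrix"))
  m <- scores(im)
  if (!all(rownames(m) %in% rownames(predictorValues(phageGM))))
    stop("phage isolate missing from the phage genotype matrix")
  if (!all(colnames(m) %in% rownames(predictorValues(bactGM))))
    stop("bacterial isolate missing from the bacterial genotype matrix")
  bv <- predictorValues(bactGM); pv <- predictorValues(phageGM)
  idx <- which(!is.na(m), arr.ind = TRUE)
  if (!nrow(idx)) stop("no scored pairs")
  X <- cbind(bv[colnames(m)[idx[, 2]], , drop = FALSE],
             pv[rownames(m)[idx[, 1]], , drop = FALSE])
  y <- m[idx]
  key <- apply(X, 1, paste, collapse = ",")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  xU <- X[first, , drop = FALSE]
  rownames(xU) <- NULL
  yU <- as.numeric(tapply(y, grp, mean)[as.character(seq_len(sum(first)))])
  wU <- as.integer(table(factor(grp, levels = seq_len(sum(first)))))
  pi1 <- predictorInfo(bactGM); pi1$organism <- "bacterium"
  pi2 <- predictorInfo(phageGM); pi2$organism <- "phage"
  structure(list(x = xU, y = yU, weight = wU,
                 predictorInfo = rbind(pi1, pi2)),
            class = "PairObservations")
}

#' Read / write the mutation-table TSV dialect
#'
#' Columns: `isolate_id`, `replicate_id`, `organism`, `type` (SNP,
#' insertion, deletion, IS, amplification), `start`, `end` (1-based
#' inclusive; equal for point events), `ref`, `alt`, `copy_number` (integer
#' >= 2 for amplifications, empty otherwise), `effect` (intergenic,
#' synonymous, nonsynonymous, frameshift, inframe, disruption), `gene`.
#'
#' @param path TSV path.
#' @return data.frame of mutation records.
#' @export
readMutationTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("isolate_id", "type", "start", "end")
  if (!all(need %in% names(df))) stop("not a mutation table: missing columns")
  bad <- df$type == "amplification" & (is.na(df$copy_number) | df$copy_number < 2)
  if (any(bad)) stop("amplifications need copy_number >= 2")
  df
}

#' @rdname readMutationTable
#' @param records mutation records data.frame.
#' @export
writeMutationTable <- function(records, path) {
  write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}
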