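#' Fit the sparse infectivity model with cross-validated Lasso
#'
#' Fits `infectivity ~ joint genotype` by L1-penalized least squares over a
#' 200-point geometric penalty grid anchored at the analytic critical
#' penalty (the smallest lambda nulling every coefficient,
#' `max |X'y| / n` after standardization) and spanning four decades below
#' it. Model selection uses k-fold cross-validation with the
#' one-standard-error rule: the largest penalty whose CV mean squared error
#' is within one standard error of the minimum. Predictors are
#' standardized internally; coefficients are reported on the original
#' scale; the intercept is unpenalized.
#'
#' Folds are formed by a seeded shuffle into k contiguous blocks, so the
#' fit is deterministic given `seed`. A constant response cannot be fit and
#' returns the all-zero model with a warning.
#'
#' @param obs a `PairObservations` list from [buildObservations()], or any
#'   list with elements `x`, `y` (and optionally `weight`).
#' @param k number of CV folds.
#' @param nLambda penalty-grid length.
#' @param lambdaMinRatio smallest-to-largest penalty ratio (1e-4 = four
#'   decades).
#' @param weighted use the pooled-pair weights in the fit (default off: the
#'   deduplicated observations enter equally).
#' @param seed fold-assignment seed.
#' @return a [LassoFit-class].
#' @export
fitLasso <- function(obs, k = 5L, nLambda = 200L, lambdaMinRatio = 1e-4,
                     weighted = FALSE, seed = 1L) {
  x <- as.matrix(obs$x); y <- as.numeric(obs$y)
  n <- nrow(x)
  if (n < k) stop("need at least k observations")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  w <- if (weighted && !is.null(obs$weight)) as.numeric(obs$weight) else rep(1, n)

  if (sd(y) == 0) {
    warning("constant response: returning the all-zero model")
    cf <- setNames(rep(0, ncol(x)), colnames(x))
    return(new("LassoFit", lambda = NA_real_, cvm = NA_real_, cvsd = NA_real_,
               lambdaMin = NA_real_, lambdaSel = NA_real_,
               intercept = y[1], coefficients = cf, cvfit = NULL,
               seed = as.integer(seed)))
  }
  if (all(apply(x, 2, sd) == 0)) stop("rank-0 design: no varying predictor")

  # folds are assigned on a content-canonical ordering of the observations,
  # so permuting the rows permutes the folds with them and the CV splits --
  # hence the selected support -- do not depend on input order
  ord <- order(apply(cbind(x, y), 1, paste, collapse = ","))
  foldid <- integer(n)
  foldid[ord] <- withSeed(seed, sample(rep(seq_len(k), length.out = n)))
  cv <- glmnet::cv.glmnet(x, y, weights = w, foldid = foldid,
                          nlambda = nLambda, lambda.min.ratio = lambdaMinRatio,
                          standardize = TRUE, family = "gaussian")
  cf <- as.numeric(stats::coef(cv, s = "lambda.1se"))
  new("LassoFit", lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
      lambdaMin = cv$lambda.min, lambdaSel = cv$lambda.1se,
      intercept = cf[1],
      coefficients = setNames(cf[-1], colnames(x)),
      cvfit = cv, seed = as.integer(seed))
}

#' Tabulate the nonzero Lasso associations
#'
#' Lists every predictor with a nonzero coefficient at the selected
#' penalty, sorted by coefficient value (strongest resistance associations
#' first), with its sign and any predictor metadata (gene, type, pathway)
#' joined by label.
#'
#' @param fit a [LassoFit-class].
#' @param info optional predictor metadata data.frame with a `label` column
#'   (e.g. `predictorInfo` from [buildObservations()]).
#' @return data.frame: `label`, `coefficient`, `sign`, plus metadata
#'   columns; zero rows when nothing was selected.
#' @export
reportAssociations <- function(fit, info = NULL) {
  stopifnot(is(fit, "LassoFit"))
  nz <- selectedCoef(fit)
  out <- data.frame(label = names(nz), coefficient = unname(nz),
                    sign = ifelse(nz > 0, "+", "-"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$coefficient), , drop = FALSE]
  if (!is.null(info) && nrow(out)) {
    extra <- info[match(out$label, info$label), setdiff(names(info), "label"),
                  drop = FALSE]
    out <- cbind(out, extra)
  }
  rownames(out) <- NULL
  out
}
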