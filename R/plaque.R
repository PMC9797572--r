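#' Describe the spot grid of a cross-infection plate image
#'
#' A plate layout places a regular `rows x cols` grid of non-overlapping
#' square analysis regions (side `side`, odd so a centre pixel exists) on the
#' image. Centres may be given explicitly (an `rows*cols` x 2 matrix of
#' (row, col) pixel coordinates in row-major spot order); otherwise a tight
#' grid with pitch `side` starting at `origin` is assumed. Spots that are
#' intentionally phage-free (carryover controls) can be listed in
#' `emptySpots`.
#'
#' @param rows,cols grid dimensions (default 8 x 12 = 96 spots).
#' @param side analysis-region side L in pixels (odd; default 181).
#' @param centers optional explicit spot centres.
#' @param origin top-left corner (row, col) of the first region when centres
#'   are derived from the grid pitch.
#' @param emptySpots data.frame with columns `row`, `col` of spots left
#'   phage-free by design; NULL for none.
#' @return a list of class `PlateLayout`.
#' @export
plateLayout <- function(rows = 8L, cols = 12L, side = 181L, centers = NULL,
                        origin = c(1L, 1L), emptySpots = NULL) {
  if (side %% 2L != 1L) stop("'side' must be odd so a centre pixel exists")
  if (rows < 1 || cols < 1) stop("empty grid")
  n <- rows * cols
  if (is.null(centers)) {
    half <- (side - 1L) / 2L
    rc <- origin[1] + (seq_len(rows) - 1L) * side + half
    cc <- origin[2] + (seq_len(cols) - 1L) * side + half
    centers <- cbind(rep(rc, each = cols), rep(cc, times = rows))
  } else {
    centers <- as.matrix(centers)
    if (nrow(centers) != n) stop("need one centre per spot")
  }
  if (!is.null(emptySpots)) {
    emptySpots <- as.data.frame(emptySpots)
    if (any(emptySpots$row < 1 | emptySpots$row > rows |
            emptySpots$col < 1 | emptySpots$col > cols))
      stop("empty spot outside the grid")
  }
  structure(list(rows = rows, cols = cols, side = as.integer(side),
                 centers = centers, emptySpots = emptySpots),
            class = "PlateLayout")
}

#' Extract the square spot regions of a plate image
#'
#' Cuts the image into the layout's `rows x cols` analysis squares in
#' row-major order. A region touching the image border exactly is accepted;
#' any pixel beyond it is an error.
#'
#' @param image numeric matrix, intensities in \[0, 255\].
#' @param layout a [plateLayout()].
#' @return list of `side x side` matrices, one per spot, with attributes
#'   `row` and `col`.
#' @export
extractSpotGrid <- function(image, layout) {
  stopifnot(inherits(layout, "PlateLayout"))
  half <- (layout$side - 1L) / 2L
  out <- vector("list", nrow(layout$centers))
  k <- 0L
  for (r in seq_len(layout$rows)) {
    for (cl in seq_len(layout$cols)) {
      k <- k + 1L
      ctr <- layout$centers[k, ]
      r0 <- ctr[1] - half; r1 <- ctr[1] + half
      c0 <- ctr[2] - half; c1 <- ctr[2] + half
      if (r0 < 1 || c0 < 1 || r1 > nrow(image) || c1 > ncol(image))
        stop("spot region (", r, ",", cl, ") outside image bounds")
      reg <- image[r0:r1, c0:c1, drop = FALSE]
      attr(reg, "row") <- r; attr(reg, "col") <- cl
      out[[k]] <- reg
    }
  }
  out
}

#' Percentile-normalize a spot region
#'
#' Rescales a region by `255 / p` where `p` is its `percentile`-th intensity
#' percentile, clipping at 255, so that every pixel at or above that
#' percentile maps to 255. This removes per-spot illumination differences:
#' in dark-field the bright bacterial lawn dominates the upper decile, so
#' after normalization lawns are comparable across spots and plates. A
#' region whose percentile is 0 (no signal) is returned unchanged.
#'
#' @param region numeric matrix in \[0, 255\].
#' @param percentile percentile anchored at 255 (default 90).
#' @return normalized matrix of the same shape.
#' @export
normalizeRegion <- function(region, percentile = 90) {
  if (!length(region)) stop("empty region")
  p <- as.numeric(quantile(region, percentile / 100, names = FALSE))
  if (p <= 0) return(region)
  out <- clamp(region * (255 / p), 0, 255)
  out[region >= p] <- 255            # exact, immune to float fuzz
  out
}

#' Threshold a normalized region into a phage-lysis mask
#'
#' Lysis is dark in dark-field: the mask marks pixels strictly below
#' `threshold`. `phageArea` is the number of masked pixels.
#'
#' @param region normalized region matrix.
#' @param threshold intensity threshold in (0, 255).
#' @return list with `mask` (logical matrix) and `phageArea`.
#' @export
phageMask <- function(region, threshold) {
  if (threshold <= 0 || threshold >= 255) stop("'threshold' must be in (0, 255)")
  mask <- region < threshold
  list(mask = mask, phageArea = sum(mask))
}

#' Score one spot: phage fraction, clearance, infectivity
#'
#' Implements the spot-scoring closed forms on a normalized region `V` with
#' mask `isPhage` and `Vmax = 255`, region side `L`:
#' \deqn{phageFraction = phageArea / L^2}
#' \deqn{clearance = 1 - mean(V[isPhage] / Vmax)}
#' \deqn{infectivity = phageFraction \times clearance}
#' An empty mask (no lysis) yields clearance 0 and infectivity 0 by
#' convention, since the mean over an empty pixel set is undefined and a
#' spot without lysis must score 0.
#'
#' @param region normalized region matrix.
#' @param mask logical matrix of the same shape (from [phageMask()]).
#' @return one-row data.frame: `phageArea`, `phageFraction`, `clearance`,
#'   `infectivity`.
#' @export
scoreSpot <- function(region, mask) {
  if (!identical(dim(region), dim(mask))) stop("mask/region shape mismatch")
  area <- sum(mask)
  pf <- area / length(region)
  cl <- if (area == 0) 0 else 1 - mean(region[mask]) / 255
  data.frame(phageArea = area, phageFraction = pf, clearance = cl,
             infectivity = pf * cl)
}

#' Turbidity of a normalized spot region
#'
#' Total normalized intensity, `sum(V) / (255 L^2)`: 1 for an intact bright
#' lawn, 0 for a fully cleared spot. Acts inversely to infectivity.
#'
#' @param region normalized region matrix.
#' @return single numeric in \[0, 1\].
#' @export
spotTurbidity <- function(region) sum(region) / (255 * length(region))

#' Score every spot of a plate image
#'
#' Convenience wrapper: extracts the grid, normalizes each region, derives a
#' plate-wide lysis threshold (Otsu's method on the pooled normalized
#' histogram when `threshold = "auto"`), and scores every spot.
#'
#' @param image plate image matrix in \[0, 255\].
#' @param layout a [plateLayout()].
#' @param threshold `"auto"` or a fixed intensity in (0, 255); a vector of
#'   per-spot thresholds (row-major) is also accepted for outlier regions.
#' @param percentile normalization percentile.
#' @return data.frame with one row per spot: grid position, scores,
#'   turbidity and the threshold used.
#' @export
scorePlate <- function(image, layout, threshold = "auto", percentile = 90) {
  regions <- extractSpotGrid(image, layout)
  norm <- lapply(regions, normalizeRegion, percentile = percentile)
  if (identical(threshold, "auto")) {
    pooled <- unlist(norm, use.names = FALSE) / 255
    thr <- 255 * EBImage::otsu(matrix(pooled, nrow = 1), range = c(0, 1))
    thr <- rep(thr, length(norm))
  } else {
    thr <- rep(as.numeric(threshold), length.out = length(norm))
  }
  rows <- vapply(regions, attr, integer(1), which = "row")
  cols <- vapply(regions, attr, integer(1), which = "col")
  recs <- lapply(seq_along(norm), function(k) {
    m <- phageMask(norm[[k]], thr[k])
    sc <- scoreSpot(norm[[k]], m$mask)
    cbind(data.frame(row = rows[k], col = cols[k]), sc,
          data.frame(turbidity = spotTurbidity(norm[[k]]), threshold = thr[k]))
  })
  do.call(rbind, recs)
}

#' Carryover quality control on phage-free spots
#'
#' Spots left phage-free by design (about a quarter of each plate) must not
#' show lysis; any such spot whose infectivity exceeds `tol` indicates
#' carryover between spots and is flagged. The plate passes iff no empty
#' spot is flagged.
#'
#' @param scoresTable per-spot data.frame from [scorePlate()] (needs `row`,
#'   `col`, `infectivity`).
#' @param layout the [plateLayout()] whose `emptySpots` define the controls.
#' @param tol infectivity tolerance.
#' @return list with `pass` (logical) and `flagged` (data.frame of offending
#'   spots).
#' @export
carryoverQC <- function(scoresTable, layout, tol = 0.05) {
  stopifnot(inherits(layout, "PlateLayout"))
  empties <- layout$emptySpots
  if (is.null(empties) || !nrow(empties))
    return(list(pass = TRUE, flagged = scoresTable[0, , drop = FALSE]))
  key <- paste(scoresTable$row, scoresTable$col)
  want <- paste(empties$row, empties$col)
  if (!all(want %in% key)) stop("scores do not cover the layout's empty spots")
  sub <- scoresTable[key %in% want, , drop = FALSE]
  flagged <- sub[sub$infectivity > tol, , drop = FALSE]
  list(pass = nrow(flagged) == 0L, flagged = flagged)
}
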