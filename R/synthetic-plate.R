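#' Simulate a cross-infection plate image with known spot scores
#'
#' Renders a dark-field-like plate: a bright bacterial lawn at
#' `background` intensity tiled into a `rows x cols` grid of square spot
#' regions, with a centred square plaque planted in each spot listed in
#' `plaques`. A plaque covers `areaFraction` of its region (realized as the
#' nearest whole-pixel square) at `interior` intensity, darker than the
#' lawn. Spots listed in `layout$emptySpots` style (argument `emptySpots`)
#' get no plaque unless one is planted explicitly, which emulates carryover.
#'
#' Ground truth is recorded on the post-normalization scale of
#' [normalizeRegion()]: with the lawn occupying at least 10% of the region
#' the 90th percentile equals `background`, so the normalized plaque
#' interior is `min(interior * 255 / background, 255)` and
#' `infectivity = realizedFraction * (1 - interiorNorm / 255)`. When a
#' plaque covers more than 90% of its region the percentile anchor falls
#' inside the plaque and the truth accounts for it.
#'
#' @param rows,cols spot grid (default 8 x 12).
#' @param side region side in pixels (odd; default 181).
#' @param plaques data.frame with columns `row`, `col`, `areaFraction`
#'   (\[0, 1\]) and `interior` (mean interior intensity, <= `background`);
#'   NULL for a clean lawn.
#' @param background lawn intensity in (0, 255\].
#' @param noiseSd Gaussian pixel noise sd (truth stays the noiseless value).
#' @param emptySpots data.frame of `row`, `col` spots that are phage-free by
#'   design (recorded in the returned layout for [carryoverQC()]).
#' @param seed RNG seed.
#' @return list with `image` (matrix), `layout` (a [plateLayout()]) and
#'   `truth` (per-spot data.frame: row, col, areaFraction realized,
#'   clearance, infectivity, turbidity on the normalized scale).
#' @examples
#' pl <- data.frame(row = 1, col = 1, areaFraction = 0.5, interior = 80)
#' sim <- simPlateImage(rows = 2, cols = 2, side = 51, plaques = pl,
#'                      background = 200, seed = 1)
#' sim$truth[1, ]
#' @export
simPlateImage <- function(rows = 8L, cols = 12L, side = 181L, plaques = NULL,
                          background = 200, noiseSd = 0, emptySpots = NULL,
                          seed = 1) {
  if (background <= 0 || background > 255) stop("'background' must be in (0, 255]")
  layout <- plateLayout(rows = rows, cols = cols, side = side,
                        emptySpots = emptySpots)
  img <- matrix(background, nrow = rows * side, ncol = cols * side)

  n <- rows * cols
  truth <- data.frame(row = rep(seq_len(rows), each = cols),
                      col = rep(seq_len(cols), times = rows),
                      areaFraction = 0, clearance = 0, infectivity = 0,
                      turbidity = 1)
  interiorOf <- rep(NA_real_, n)

  if (!is.null(plaques) && nrow(plaques)) {
    plaques <- as.data.frame(plaques)
    need <- c("row", "col", "areaFraction", "interior")
    if (!all(need %in% names(plaques)))
      stop("'plaques' needs columns row, col, areaFraction, interior")
    if (anyDuplicated(plaques[c("row", "col")]))
      stop("overlapping plaques: one plaque per spot")
    if (any(plaques$areaFraction < 0 | plaques$areaFraction > 1))
      stop("'areaFraction' must lie in [0, 1]")
    if (any(plaques$interior < 0 | plaques$interior > background))
      stop("plaque interior must be darker than the lawn")
    for (e in seq_len(nrow(plaques))) {
      r <- plaques$row[e]; cl <- plaques$col[e]
      af <- plaques$areaFraction[e]; intn <- plaques$interior[e]
      if (r < 1 || r > rows || cl < 1 || cl > cols) stop("plaque outside grid")
      s <- min(side, round(sqrt(af) * side))    # square patch side
      idx <- (r - 1) * cols + cl
      if (s >= 1) {
        off <- floor((side - s) / 2)
        rr <- ((r - 1) * side + 1 + off):((r - 1) * side + off + s)
        cc <- ((cl - 1) * side + 1 + off):((cl - 1) * side + off + s)
        img[rr, cc] <- intn
        interiorOf[idx] <- intn
        truth$areaFraction[idx] <- (s * s) / (side * side)
      }
    }
  }

  # ground truth on the normalized scale (noiseless construction)
  for (k in seq_len(n)) {
    af <- truth$areaFraction[k]
    p90 <- if (af <= 0.9) background else interiorOf[k]
    if (is.na(p90) || p90 <= 0) p90 <- background
    scale <- 255 / p90
    bgN <- min(background * scale, 255)
    if (af > 0) {
      intN <- min(interiorOf[k] * scale, 255)
      truth$clearance[k] <- 1 - intN / 255
      truth$infectivity[k] <- af * truth$clearance[k]
      truth$turbidity[k] <- (af * intN + (1 - af) * bgN) / 255
    } else {
      truth$turbidity[k] <- bgN / 255
    }
  }

  if (noiseSd > 0)
    img <- withSeed(seed, clamp(img + rnorm(length(img), sd = noiseSd), 0, 255))

  list(image = img, layout = layout, truth = truth)
}

#' Write a plate image as 8-bit grayscale PNG
#'
#' @param image matrix in \[0, 255\].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writePlatePNG <- function(image, path) {
  png::writePNG(clamp(image, 0, 255) / 255, path)
  invisible(path)
}

#' Read a grayscale plate image into a \[0, 255\] matrix
#'
#' Accepts 8/16-bit grayscale PNG or TIFF; multi-channel images are
#' averaged to grayscale.
#'
#' @param path file path (.png or .tif/.tiff).
#' @return numeric matrix in \[0, 255\].
#' @export
readPlateImage <- function(path) {
  x <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
       else tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- apply(x, c(1, 2), mean)
  x * 255
}
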