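#' Preprocess a raw time-lapse stack
#'
#' Background correction for dark-field time-lapse imaging: the first frame
#' is subtracted from every later frame (negative differences clamped to 0),
#' a single channel is selected from multi-channel input (the red channel by
#' default, which carries the best signal-to-noise in dark-field plate
#' imaging), and the field is cropped to the plate. The output therefore has
#' one frame fewer than the input.
#'
#' @param raw numeric array: `c(T, H, W)` grayscale or `c(T, H, W, C)`
#'   multi-channel, intensities in \[0, 255\].
#' @param channel channel index used for multi-channel input (1 = red).
#' @param crop optional crop rectangle `c(row, col, height, width)`,
#'   1-based; NULL keeps the full field.
#' @param frameInterval minutes per frame, carried into the result.
#' @return an [IntensityStack-class] with `T - 1` frames.
#' @export
preprocessStack <- function(raw, channel = 1L, crop = NULL, frameInterval = 10) {
  d <- dim(raw)
  if (length(d) == 4L) {
    if (channel < 1 || channel > d[4]) stop("channel index out of range")
    raw <- raw[, , , channel, drop = TRUE]
    if (d[1] == 1L) dim(raw) <- d[-4]   # keep the frame axis
    d <- dim(raw)
  }
  if (length(d) != 3L) stop("'raw' must be a T x H x W (x C) array")
  if (d[1] < 2L) stop("need at least 2 frames")

  bg <- raw[1, , , drop = TRUE]
  out <- raw[-1, , , drop = FALSE]
  out <- sweep(out, c(2, 3), bg, `-`)
  out <- clamp(out, 0, 255)

  if (!is.null(crop)) {
    if (length(crop) != 4L) stop("'crop' must be c(row, col, height, width)")
    r0 <- crop[1]; c0 <- crop[2]; h <- crop[3]; w <- crop[4]
    if (r0 < 1 || c0 < 1 || h < 1 || w < 1 ||
        r0 + h - 1 > d[2] || c0 + w - 1 > d[3])
      stop("crop outside image bounds")
    out <- out[, r0:(r0 + h - 1), c0:(c0 + w - 1), drop = FALSE]
  }
  new("IntensityStack", values = out, frameInterval = frameInterval)
}

#' Average an intensity stack over square pixel blocks
#'
#' Spatial coarse-graining: every frame is averaged over non-overlapping
#' `block x block` pixel squares (default 10 px, which at the usual plate
#' magnification corresponds to zones of about 1.4 mm via the `pxPerMm`
#' scale of the experiment). Trailing rows/columns that do not fill a
#' complete block are dropped.
#'
#' @param stack an [IntensityStack-class].
#' @param block block side in pixels.
#' @return an [IntensityStack-class] at block resolution.
#' @export
blockAverage <- function(stack, block = 10L) {
  stopifnot(is(stack, "IntensityStack"))
  v <- stack@values
  d <- dim(v)
  if (d[2] < block || d[3] < block) stop("image smaller than one block")
  hb <- d[2] %/% block
  wb <- d[3] %/% block
  v <- v[, seq_len(hb * block), seq_len(wb * block), drop = FALSE]
  dim(v) <- c(d[1], block, hb, block, wb)
  v <- aperm(v, c(2, 4, 1, 3, 5))
  dim(v) <- c(block * block, d[1] * hb * wb)
  out <- colMeans(v)
  dim(out) <- c(d[1], hb, wb)
  new("IntensityStack", values = out, frameInterval = stack@frameInterval)
}

#' Smooth a single-site intensity trace over a sliding time window
#'
#' Trailing moving average over `window` frames (default 4 frames = 30 min
#' at 10 min/frame). The first `window - 1` positions average over the
#' frames available so far (shrinking window), so the output has the same
#' length as the input and frame indices keep their acquisition times.
#'
#' @param trace numeric vector, one intensity per frame.
#' @param window window length in frames; `window = 1` is the identity.
#' @return numeric vector of the same length.
#' @export
temporalSmooth <- function(trace, window = 4L) {
  n <- length(trace)
  if (window < 1) stop("'window' must be >= 1")
  if (n < window) stop("trace shorter than the window")
  if (window == 1L) return(trace)
  cs <- cumsum(trace)
  out <- numeric(n)
  head <- seq_len(window - 1L)
  out[head] <- cs[head] / head
  idx <- window:n
  out[idx] <- (cs[idx] - c(0, cs)[idx - window + 1L]) / window
  out
}

# Candidate local maxima with plateau handling: maximal runs of equal values
# whose (existing) neighbours on both sides are lower; boundary runs count as
# peaks when their single neighbour is lower. Returns one row per peak with
# the plateau centre and extent (the prominence walk starts at the extent).
localMaxima <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k == 1L)                          # constant trace: no peak
    return(data.frame(center = integer(0), start = integer(0), end = integer(0)))
  leftLower <- c(TRUE, r$values[-k] < r$values[-1])     # run i vs run i-1
  rightLower <- c(r$values[-k] > r$values[-1], TRUE)
  isPeak <- leftLower & rightLower
  data.frame(center = as.integer(floor((starts[isPeak] + ends[isPeak]) / 2)),
             start = starts[isPeak], end = ends[isPeak])
}

# Topographic prominence of the plateau peak spanning [s, e]. A side is
# "closed" when walking outward meets strictly higher terrain; closed sides
# contribute the minimum of the walked stretch and the prominence is the
# height above the higher such minimum. A side that runs off the trace end
# without meeting higher terrain does not bound the peak's contour; when
# neither side does (the global maximum) the reference level is the trace
# minimum.
peakProminence <- function(x, s, e) {
  h <- x[s]
  sideMin <- function(seg) {
    stopAt <- which(seg > h)[1]
    if (is.na(stopAt)) -Inf
    else if (stopAt == 1L) h
    else min(seg[seq_len(stopAt - 1L)])
  }
  left <- if (s > 1) sideMin(x[(s - 1):1]) else -Inf
  right <- if (e < length(x)) sideMin(x[(e + 1):length(x)]) else -Inf
  ref <- max(left, right)
  if (is.infinite(ref)) ref <- min(x)
  h - ref
}

#' Detect intensity peaks by prominence and minimum spacing
#'
#' Finds local maxima of a trace (plateaus of equal values count once, at
#' their centre; maxima at the trace boundary are eligible), keeps those
#' whose topographic prominence is at least `minProminence`, and then
#' filters greedily by descending peak height
#' (ties to the earlier index) so that all retained peaks are at least
#' `minDistance` frames apart. The defaults (20 frames, 4 intensity units)
#' are the growth--lysis cycle-counting settings.
#'
#' Prominence is topographic: walking outward from a peak, a side that
#' meets strictly higher terrain contributes the minimum of the walked
#' stretch, and the prominence is the height above the higher such minimum.
#' A side that reaches the end of the trace without meeting higher terrain
#' does not close the peak's contour and places no bound -- so a maximum
#' held until the last frame (territory bacteria never lost, or a final
#' regrowth) keeps its full prominence; for the global maximum the
#' reference level is the trace minimum.
#'
#' Peak detection is invariant to adding a constant to the whole trace, and
#' the number of peaks is non-increasing in both thresholds.
#'
#' @param trace numeric vector (finite).
#' @param minDistance minimum index spacing between retained peaks.
#' @param minProminence minimum topographic prominence.
#' @return data.frame with columns `index`, `height`, `prominence`, ordered
#'   by index; zero rows when nothing qualifies.
#' @export
detectPeaks <- function(trace, minDistance = 20L, minProminence = 4) {
  if (anyNA(trace) || !all(is.finite(trace))) stop("trace must be finite")
  runs <- localMaxima(trace)
  empty <- data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0))
  if (!nrow(runs)) return(empty)
  prom <- vapply(seq_len(nrow(runs)), function(i)
    peakProminence(trace, runs$start[i], runs$end[i]), numeric(1))
  keep <- prom >= minProminence
  cand <- runs$center[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)
  h <- trace[cand]
  ord <- order(-h, cand)               # highest first, earlier on ties
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(cand[i] - cand[kept]) >= minDistance))
      kept <- c(kept, i)
  }
  kept <- kept[order(cand[kept])]
  data.frame(index = cand[kept], height = h[kept], prominence = prom[kept])
}

#' Growth--lysis cycle and dominance maps from a block-resolution stack
#'
#' For every spatial block of a preprocessed, block-averaged stack the trace
#' is smoothed over a sliding `window`, peaks are counted with
#' [detectPeaks()] (each peak is one growth--lysis cycle), and two dominance
#' layers are computed from the unsmoothed trace: `etaFinal`, the intensity
#' in the last frame (high where bacteria ultimately hold the territory),
#' and `etaDiff = etaMax - etaFinal`, the intensity lost after the maximum
#' (high where phage cleared a dense population). The plate-wide median
#' cycle count is taken only over blocks whose maximal intensity exceeds
#' `activityFloor`, so empty agar does not dilute it.
#'
#' @param stack block-resolution [IntensityStack-class].
#' @param window temporal smoothing window, frames.
#' @param minDistance,minProminence peak-detection settings.
#' @param activityFloor intensity a block must exceed (at any time) to enter
#'   the median cycle count.
#' @return a [DominanceMap-class].
#' @export
cycleDominanceMap <- function(stack, window = 4L, minDistance = 20L,
                              minProminence = 4, activityFloor = 4) {
  stopifnot(is(stack, "IntensityStack"))
  v <- stack@values
  d <- dim(v)
  ef <- v[d[1], , , drop = TRUE]
  if (is.null(dim(ef))) ef <- matrix(ef, d[2], d[3])
  emax <- apply(v, c(2, 3), max)
  cyc <- matrix(0L, d[2], d[3])
  for (i in seq_len(d[2])) {
    for (j in seq_len(d[3])) {
      sm <- temporalSmooth(v[, i, j], window)
      cyc[i, j] <- nrow(detectPeaks(sm, minDistance, minProminence))
    }
  }
  active <- emax > activityFloor
  med <- if (any(active)) median(cyc[active]) else NA_real_
  new("DominanceMap", etaFinal = ef, etaDiff = emax - ef,
      cycleCount = cyc, medianCycles = med, activityFloor = activityFloor)
}

#' Write a dominance map to CSV (and optionally a 3-layer TIFF)
#'
#' @param map a [DominanceMap-class].
#' @param csv path of the CSV to write (block_row, block_col, eta_final,
#'   eta_diff, cycles).
#' @param tif optional path of a 3-layer float TIFF (etaFinal, etaDiff,
#'   cycles).
#' @return invisibly, the data.frame written.
#' @export
writeDominanceMap <- function(map, csv, tif = NULL) {
  stopifnot(is(map, "DominanceMap"))
  d <- dim(map@etaFinal)
  df <- data.frame(
    block_row = rep(seq_len(d[1]), times = d[2]),
    block_col = rep(seq_len(d[2]), each = d[1]),
    eta_final = as.vector(map@etaFinal),
    eta_diff = as.vector(map@etaDiff),
    cycles = as.vector(map@cycleCount))
  write.csv(df, csv, row.names = FALSE)
  if (!is.null(tif)) {
    layers <- list(map@etaFinal / 255, map@etaDiff / 255,
                   map@cycleCount / max(1, max(map@cycleCount)))
    tiff::writeTIFF(layers, tif, bits.per.sample = 32L)
  }
  invisible(df)
}
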