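#' Simulate a traveling-wave time-lapse stack with planted lysis cycles
#'
#' Generates a dark-field-like intensity stack emulating a bacterial
#' population expanding as a traveling wave across a swimming plate, with
#' phage lysis events planted at chosen blocks and times. Each lysis event is
#' rendered as a raised-cosine dip of chosen depth followed by regrowth to
#' the plateau, so the trace of an affected block shows one extra intensity
#' peak per event and the peak prominence is controlled by `depth`. The
#' planted number of growth--lysis cycles per block (1 where the wave passed,
#' +1 per lysis event, 0 where it never arrived) is returned as ground truth.
#'
#' The wave front travels left to right at `waveSpeed` block-columns per
#' frame, each block ramping from 0 to `plateau` over `riseFrames` frames
#' once the front arrives. Gaussian noise of sd `noiseSd` is added last and
#' intensities are clamped to \[0, 255\]. With `blockSize > 1` every block
#' value is replicated over a `blockSize x blockSize` pixel tile, so the
#' stack can be pushed through [blockAverage()] first.
#'
#' For planted cycle counts to be recoverable by [detectPeaks()] at the
#' defaults, events in one block should be at least ~50 frames apart, start
#' after the wave has plateaued, end at least `dipHalfWidth` + 20 frames
#' before the last frame, and have `depth` > 4 (the default prominence
#' threshold).
#'
#' @param frames number of frames (>= 8).
#' @param height,width stack size in blocks.
#' @param blockSize pixel tile side per block (1 = generate at block
#'   resolution).
#' @param waveSpeed wave-front speed, block-columns per frame.
#' @param plateau post-colonization intensity level.
#' @param riseFrames frames a block takes to reach the plateau.
#' @param lysisEvents data.frame with columns `row`, `col` (block
#'   coordinates), `onset` (frame of deepest lysis) and `depth` (intensity
#'   units); NULL for none.
#' @param dipHalfWidth half-width of the raised-cosine dip, frames.
#' @param noiseSd Gaussian noise sd, intensity units (>= 0).
#' @param frameInterval minutes per frame.
#' @param seed RNG seed; identical seeds give bit-identical stacks.
#' @return list with `stack` (an [IntensityStack-class]) and `cycles`
#'   (height x width matrix of planted cycle counts).
#' @examples
#' ev <- data.frame(row = 3, col = 2, onset = 120, depth = 20)
#' sim <- simTimelapse(frames = 200, height = 5, width = 5, lysisEvents = ev,
#'                     noiseSd = 0, seed = 1)
#' sim$cycles[3, 2]  # 2: colonization plus one lysis/regrowth event
#' @export
simTimelapse <- function(frames = 300, height = 50, width = 50, blockSize = 1,
                         waveSpeed = 0.5, plateau = 100, riseFrames = 10,
                         lysisEvents = NULL, dipHalfWidth = 10,
                         noiseSd = 0, frameInterval = 10, seed = 1) {
  if (frames < 8) stop("'frames' must be at least 8")
  if (height < 1 || width < 1 || blockSize < 1)
    stop("degenerate dimensions")
  if (noiseSd < 0) stop("'noiseSd' must be non-negative")
  if (waveSpeed <= 0) stop("'waveSpeed' must be positive")

  if (!is.null(lysisEvents)) {
    lysisEvents <- as.data.frame(lysisEvents)
    need <- c("row", "col", "onset", "depth")
    if (!all(need %in% names(lysisEvents)))
      stop("'lysisEvents' needs columns row, col, onset, depth")
    if (any(lysisEvents$row < 1 | lysisEvents$row > height |
            lysisEvents$col < 1 | lysisEvents$col > width))
      stop("lysis event outside the block grid")
    if (any(lysisEvents$onset < 1 | lysisEvents$onset > frames))
      stop("lysis onset outside the recorded frames")
    if (any(lysisEvents$depth <= 0)) stop("lysis depth must be positive")
  }

  tt <- seq_len(frames)
  # smooth monotone colonization ramp, one per block-column
  ramp <- function(arrival) {
    u <- clamp((tt - arrival) / riseFrames, 0, 1)
    plateau * 0.5 * (1 - cos(pi * u))
  }
  arrivals <- (seq_len(width) - 1) / waveSpeed + 1

  block <- array(0, dim = c(frames, height, width))
  for (j in seq_len(width)) {
    tr <- ramp(arrivals[j])
    block[, , j] <- matrix(tr, nrow = frames, ncol = height)
  }

  cycles <- matrix(0L, height, width)
  arrived <- outer(rep(1, height), arrivals + riseFrames <= frames)
  cycles[arrived > 0] <- 1L

  if (!is.null(lysisEvents) && nrow(lysisEvents)) {
    for (e in seq_len(nrow(lysisEvents))) {
      r <- lysisEvents$row[e]; cl <- lysisEvents$col[e]
      on <- lysisEvents$onset[e]; dp <- lysisEvents$depth[e]
      u <- (tt - on) / dipHalfWidth
      dip <- ifelse(abs(u) < 1, dp * 0.5 * (1 + cos(pi * u)), 0)
      block[, r, cl] <- pmax(block[, r, cl] - dip, 0)
      if (cycles[r, cl] > 0L) cycles[r, cl] <- cycles[r, cl] + 1L
    }
  }

  if (noiseSd > 0) {
    block <- withSeed(seed, block + rnorm(length(block), sd = noiseSd))
  }
  block <- clamp(block, 0, 255)

  if (blockSize > 1) {
    px <- block[, rep(seq_len(height), each = blockSize),
                  rep(seq_len(width), each = blockSize), drop = FALSE]
  } else px <- block

  list(stack = new("IntensityStack", values = px, frameInterval = frameInterval),
       cycles = cycles)
}
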