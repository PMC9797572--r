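#' Read and write time-lapse stacks
#'
#' A stack is stored either as a multi-page TIFF or as a numbered series of
#' grayscale PNG frames. Multi-channel frames are reduced by selecting
#' `channel` (1 = red). Intensities are returned on the 0--255 scale.
#'
#' @param path multi-page TIFF path (`readStackTIFF`) or output path.
#' @param paths character vector of frame files in temporal order
#'   (`readStackPNG`), e.g. from `Sys.glob()`.
#' @param channel channel selected from RGB frames.
#' @param frameInterval minutes per frame for the returned stack.
#' @return an [IntensityStack-class]; writers return paths invisibly.
#' @name stackIO
NULL

#' @rdname stackIO
#' @export
readStackTIFF <- function(path, channel = 1L, frameInterval = 10) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  asStack(frames, channel, frameInterval)
}

#' @rdname stackIO
#' @export
readStackPNG <- function(paths, channel = 1L, frameInterval = 10) {
  asStack(lapply(paths, png::readPNG), channel, frameInterval)
}

asStack <- function(frames, channel, frameInterval) {
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , channel]
    f * 255
  })
  d <- dim(frames[[1]])
  v <- array(unlist(frames, use.names = FALSE), dim = c(d[1], d[2], length(frames)))
  v <- aperm(v, c(3, 1, 2))
  new("IntensityStack", values = v, frameInterval = frameInterval)
}

#' @rdname stackIO
#' @param stack an [IntensityStack-class].
#' @param dir,prefix output directory and file prefix for the PNG series.
#' @export
writeStackPNG <- function(stack, dir, prefix = "frame") {
  stopifnot(is(stack, "IntensityStack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack@values)
  paths <- file.path(dir, sprintf("%s_%04d.png", prefix, seq_len(d[1])))
  for (t in seq_len(d[1]))
    png::writePNG(stack@values[t, , ] / 255, paths[t])
  invisible(paths)
}

#' @rdname stackIO
#' @export
writeStackTIFF <- function(stack, path) {
  stopifnot(is(stack, "IntensityStack"))
  frames <- lapply(seq_len(dim(stack@values)[1]),
                   function(t) stack@values[t, , ] / 255)
  tiff::writeTIFF(frames, path, bits.per.sample = 8L)
  invisible(path)
}
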