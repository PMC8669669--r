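#' Frame stacks
#'
#' A `FrameStack` holds a time-ordered grayscale video as an `H x W x T`
#' numeric array on its native intensity scale (8/16-bit integer data are
#' promoted to double without rescaling), plus optional acquisition metadata.
#'
#' @param frames numeric `H x W x T` array (or a list of equally sized
#'   matrices) of finite, non-negative intensities; at least 2 frames.
#' @param pixel_size_um optional micrometers per pixel.
#' @param frame_rate_hz optional frames per second.
#' @return an object of class `FrameStack`.
#' @export
frame_stack <- function(frames, pixel_size_um = NULL, frame_rate_hz = NULL) {
  if (is.list(frames)) {
    dims <- vapply(frames, dim, integer(2))
    if (length(frames) >= 2 && any(dims != dims[, 1]))
      cm_validation_error("all frames must have identical dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[1, 1], dims[2, 1], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3)
    cm_validation_error("frames must be an H x W x T array")
  if (dim(frames)[3] < 2)
    cm_validation_error("a FrameStack needs at least 2 frames")
  if (!all(is.finite(frames)) || any(frames < 0))
    cm_validation_error("frame intensities must be finite and non-negative")
  storage.mode(frames) <- "double"
  structure(list(frames = frames,
                 pixel_size_um = pixel_size_um,
                 frame_rate_hz = frame_rate_hz),
            class = "FrameStack")
}

#' @export
print.FrameStack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("FrameStack: %d frames of %d x %d px, intensity range [%g, %g]\n",
              d[3], d[1], d[2], min(x$frames), max(x$frames)))
  if (!is.null(x$frame_rate_hz))
    cat(sprintf("  frame rate: %g Hz\n", x$frame_rate_hz))
  if (!is.null(x$pixel_size_um))
    cat(sprintf("  pixel size: %g um\n", x$pixel_size_um))
  invisible(x)
}

#' @export
dim.FrameStack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3]

frame_at <- function(stack, t) stack$frames[, , t]
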