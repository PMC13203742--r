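#' Frame sequence container
#'
#' The universal currency of the package: an ordered stack of 2-D grayscale
#' intensity frames with bit-depth and acquisition metadata. Frames are held
#' as an integer `H x W x T` array; raw acquisitions are 8-bit, all
#' intermediate products of the pipeline are 16-bit.
#'
#' @param frames An `H x W x T` numeric array (or a single `H x W` matrix,
#'   treated as one frame). Values must lie within the declared bit-depth
#'   range; they are stored as integers.
#' @param bit_depth Either 8 or 16.
#' @param frame_rate Acquisition rate in Hz (metadata).
#' @param pixel_size Pixel pitch in micrometers (metadata only).
#' @return An object of class `frame_sequence` with fields `frames`,
#'   `bit_depth`, `frame_rate`, `pixel_size`.
#' @examples
#' fs <- frame_sequence(array(0L, c(4, 4, 2)), bit_depth = 8)
#' n_frames(fs)
#' @export
frame_sequence <- function(frames, bit_depth = 8L, frame_rate = 40,
                           pixel_size = 0.187) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be an H x W x T array or an H x W matrix")
  if (dim(frames)[3] < 1L) stop("a frame sequence needs at least one frame")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  maxval <- bit_depth_max(bit_depth)
  rng <- range(frames)
  if (is.na(rng[1])) stop("frames contain missing values")
  if (rng[1] < 0 || rng[2] > maxval)
    stop(sprintf("frame values must lie in [0, %d] for %d-bit data",
                 maxval, bit_depth))
  if (!is.integer(frames)) {
    frames <- array(as.integer(round(frames)), dim(frames))
  }
  structure(
    list(frames = frames, bit_depth = bit_depth,
         frame_rate = frame_rate, pixel_size = pixel_size),
    class = "frame_sequence")
}

bit_depth_max <- function(bit_depth) if (bit_depth == 8L) 255L else 65535L

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_sequence> %d frames of %d x %d, %d-bit, %.5g Hz (%.3g um/px)\n",
    d[3], d[1], d[2], x$bit_depth, x$frame_rate, x$pixel_size))
  cat(sprintf("  intensity range: [%d, %d]\n",
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' @rdname frame_sequence
#' @param x A `frame_sequence`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "frame_sequence"))
  dim(x$frames)[3]
}

#' @export
dim.frame_sequence <- function(x) dim(x$frames)

# Internal: clone a sequence with replaced frames/metadata. Callers
# guarantee the frames are integer-valued and in range, so the public
# constructor's validation pass over the whole stack is skipped.
fs_replace <- function(x, frames, bit_depth = x$bit_depth) {
  structure(list(frames = frames, bit_depth = as.integer(bit_depth),
                 frame_rate = x$frame_rate, pixel_size = x$pixel_size),
            class = "frame_sequence")
}
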