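#' Read a multi-page TIFF stack
#'
#' Reads an 8- or 16-bit grayscale multi-page TIFF into a
#' [frame_sequence]. Values are read as raw integer sample values, so a
#' write/read cycle with [write_stack()] is bit-exact.
#'
#' @param path Path to a multi-page TIFF file.
#' @param frame_rate,pixel_size Metadata attached to the returned sequence
#'   (TIFF tags do not reliably carry them).
#' @return A [frame_sequence].
#' @export
read_stack <- function(path, frame_rate = 40, pixel_size = 0.187) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) stop("not a readable TIFF stack: ", path,
                             " (", conditionMessage(e), ")"))
  if (length(pages) == 0L) stop("TIFF contains no pages: ", path)
  if (length(dim(pages[[1]])) != 2L)
    stop("only single-channel grayscale TIFFs are supported ",
         "(got ", tail(dim(pages[[1]]), 1), " channels)")
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits) || !bits %in% c(8L, 16L))
    stop("only 8- or 16-bit grayscale TIFFs are supported")
  frames <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  frame_sequence(frames, bit_depth = bits, frame_rate = frame_rate,
                 pixel_size = pixel_size)
}

#' Write a frame sequence as a multi-page TIFF
#'
#' @param seq A [frame_sequence].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  maxval <- bit_depth_max(seq$bit_depth)
  pages <- lapply(seq_len(n_frames(seq)),
                  function(i) seq$frames[, , i] / maxval)
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = seq$bit_depth,
                    compression = "LZW"),
    error = function(e) stop("failed to write TIFF: ", path,
                             " (", conditionMessage(e), ")"))
  invisible(path)
}

#' Write a binary mask stack as an 8-bit {0, 255} TIFF
#'
#' @param mask A logical (or 0/1) `H x W x T` array.
#' @param path Output path.
#' @export
write_mask_stack <- function(mask, path) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  frames <- array(255L * (mask != 0), dim(mask))
  write_stack(frame_sequence(frames, bit_depth = 8L), path)
}
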