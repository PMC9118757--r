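#' Read a multi-page TIFF video stack
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @return 3-D numeric array with dimensions `(frame, row, column)` holding
#'   the stored counts, with attribute `n_frames`.
#' @seealso [write_video_stack()] for the storage convention.
#' @export
read_video_stack <- function(path) {
  if (!file.exists(path)) {
    stop("I/O error: file not found: ", path, call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  if (length(pages) == 0) {
    stop("empty-input error: TIFF has zero pages: ", path, call. = FALSE)
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("format error: TIFF pages have inconsistent shapes", call. = FALSE)
  }
  video <- array(0, dim = c(length(pages), dims[1, 1], dims[2, 1]))
  for (f in seq_along(pages)) video[f, , ] <- pages[[f]]
  video
}

#' Write a video stack as a 16-bit multi-page TIFF
#'
#' Counts are rounded to integers and stored as 16-bit grayscale samples, so
#' integer-valued stacks with counts in `[0, 65535]` round-trip exactly
#' through [read_video_stack()]. Values outside that range are clipped with
#' a warning.
#'
#' @param video 3-D array `(frame, row, column)`, a single matrix, or a list
#'   of matrices.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_video_stack <- function(video, path) {
  if (is.matrix(video)) {
    pages <- list(video)
  } else if (is.list(video)) {
    pages <- video
  } else if (is.array(video) && length(dim(video)) == 3) {
    pages <- lapply(seq_len(dim(video)[1]), function(f) video[f, , ])
  } else {
    stop("validation error: `video` must be a matrix, list of matrices, ",
         "or (frame, row, column) array", call. = FALSE)
  }
  if (length(pages) == 0) {
    stop("empty-input error: no frames to write", call. = FALSE)
  }
  mx <- 65535
  pages <- lapply(pages, function(p) {
    p <- round(p)
    if (any(p < 0 | p > mx)) {
      warning("counts clipped to [0, 65535] on write", call. = FALSE)
      p <- pmin(pmax(p, 0), mx)
    }
    p / mx
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Split a dual-view frame into registered colour views
#'
#' Dual-view acquisition projects the same rectangular field of view twice
#' onto one sensor: the green channel on the top `view_height_px` rows and
#' the red channel on the rows immediately below. The red view is translated
#' by `geometry$channel_offset_px = (dx, dy)` (content moves by `+dx`
#' columns and `+dy` rows; uncovered pixels are zero) so both views share
#' the green view's coordinate frame.
#'
#' @param frame 2-D intensity matrix (one video frame).
#' @param geometry An [acquisition_geometry()] with `dual_view = TRUE`.
#' @return Named list `list(green =, red =)` of `view_height_px` x width
#'   matrices in one coordinate frame.
#' @export
split_channels <- function(frame, geometry) {
  if (!isTRUE(geometry$dual_view)) {
    stop("misuse error: split_channels() requires a dual_view geometry",
         call. = FALSE)
  }
  if (!is.matrix(frame)) {
    stop("validation error: `frame` must be a matrix", call. = FALSE)
  }
  vh <- geometry$view_height_px
  if (nrow(frame) < 2 * vh) {
    stop("geometry error: frame has ", nrow(frame),
         " rows; needs >= 2 * view_height_px = ", 2 * vh, call. = FALSE)
  }
  off <- geometry$channel_offset_px
  if (anyNA(off)) {
    stop("misuse error: channel_offset_px is unset; register the views first",
         call. = FALSE)
  }
  green <- frame[seq_len(vh), , drop = FALSE]
  red_raw <- frame[vh + seq_len(vh), , drop = FALSE]
  red <- translate_image(red_raw, dx = off[1], dy = off[2])
  list(green = green, red = red)
}

# Integer rigid translation; content moves by (+dx cols, +dy rows),
# exposed pixels filled with 0.
translate_image <- function(img, dx, dy) {
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  if (dx == 0 && dy == 0) return(img)
  out <- matrix(0, nrow(img), ncol(img))
  src_r <- seq_len(nrow(img)) - dy
  src_c <- seq_len(ncol(img)) - dx
  ok_r <- src_r >= 1 & src_r <= nrow(img)
  ok_c <- src_c >= 1 & src_c <= ncol(img)
  out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}
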