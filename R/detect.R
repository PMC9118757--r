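#' Detection and linking parameters
#'
#' @param spot_diameter_px Odd search/separation size (px); also sets the
#'   fitting window (`floor(diameter/2) + 2` pixels half-width).
#' @param min_mass Minimum integrated background-subtracted intensity.
#' @param max_displacement_px Linking search radius per frame step.
#' @param memory_frames Maximum gap (frames) bridged by the linker.
#' @param min_track_frames Minimum spots for a trajectory to be retained.
#' @param threshold Pixel-level candidate threshold; `NULL` (default) uses
#'   `median + 3 * mad` of the frame.
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(spot_diameter_px = 7, min_mass = 100,
                             max_displacement_px = 5, memory_frames = 3,
                             min_track_frames = 50, threshold = NULL) {
  assert_number(spot_diameter_px, "spot_diameter_px", 3)
  if (spot_diameter_px %% 2 != 1) {
    stop("validation error: `spot_diameter_px` must be odd", call. = FALSE)
  }
  assert_number(min_mass, "min_mass", 0)
  assert_number(max_displacement_px, "max_displacement_px", 0, strict = TRUE)
  assert_number(memory_frames, "memory_frames", 0)
  assert_number(min_track_frames, "min_track_frames", 0)
  if (!is.null(threshold)) assert_number(threshold, "threshold")
  structure(list(spot_diameter_px = as.integer(spot_diameter_px),
                 min_mass = min_mass,
                 max_displacement_px = max_displacement_px,
                 memory_frames = as.integer(memory_frames),
                 min_track_frames = as.integer(min_track_frames),
                 threshold = threshold),
            class = "detection_params")
}

#' Localize diffraction-limited spots in one frame
#'
#' Candidates are strict local maxima above the pixel threshold; each is
#' refined by a least-squares fit of a pixel-integrated 2-D Gaussian
#' (amplitude, sub-pixel center, width, flat background), falling back to a
#' background-subtracted weighted centroid when the fit does not converge.
#' Detections closer than `spot_diameter_px` are reduced to the brightest.
#'
#' @param frame 2-D intensity matrix.
#' @param params A [detection_params()].
#' @return Data frame with `x_px`, `y_px` (0-based pixel coordinates, pixel
#'   centers at integers), `sigma_px`, `intensity` (integrated counts above
#'   background), `background`, `converged`.
#' @export
locate_spots <- function(frame, params = detection_params()) {
  stopifnot(is.matrix(frame))
  if (!all(is.finite(frame))) {
    stop("validation error: frame contains non-finite values", call. = FALSE)
  }
  thr <- params$threshold %||%
    (median(frame) + 3 * mad(frame))
  radius <- (params$spot_diameter_px - 1L) %/% 2L
  cand <- find_candidates_cpp(frame, radius, thr)
  empty <- data.frame(x_px = numeric(), y_px = numeric(),
                      sigma_px = numeric(), intensity = numeric(),
                      background = numeric(), converged = logical())
  if (nrow(cand) == 0) return(empty)
  half <- radius + 2L
  fits <- fit_spots_cpp(frame, cand[, 1], cand[, 2], half, 60L,
                        0.5 * params$min_mass)
  fits <- as.data.frame(fits)
  keep <- fits$intensity >= params$min_mass &
    fits$x_px >= 0 & fits$x_px < ncol(frame) &
    fits$y_px >= 0 & fits$y_px < nrow(frame) &
    is.finite(fits$sigma_px) & fits$sigma_px > 0 &
    # degenerate wide fits (flat noise patches) are not spots
    fits$sigma_px <= params$spot_diameter_px / 2
  fits <- fits[keep, , drop = FALSE]
  if (nrow(fits) > 1) {
    fits <- fits[order(-fits$intensity), , drop = FALSE]
    kept <- rep(TRUE, nrow(fits))
    for (i in seq_len(nrow(fits))[-1]) {
      d2 <- (fits$x_px[seq_len(i - 1)][kept[seq_len(i - 1)]] - fits$x_px[i])^2 +
        (fits$y_px[seq_len(i - 1)][kept[seq_len(i - 1)]] - fits$y_px[i])^2
      if (any(d2 < params$spot_diameter_px^2)) kept[i] <- FALSE
    }
    fits <- fits[kept, , drop = FALSE]
  }
  rownames(fits) <- NULL
  fits[, c("x_px", "y_px", "sigma_px", "intensity", "background", "converged")]
}

#' Localize spots in every frame of a stack
#'
#' @param video 3-D array `(frame, row, column)`.
#' @param params A [detection_params()].
#' @param frames Optional 0-based frame indices the pages correspond to
#'   (default `0:(n-1)`).
#' @return Data frame of spots with a 0-based `frame` column.
#' @export
locate_stack <- function(video, params = detection_params(), frames = NULL) {
  stopifnot(is.array(video), length(dim(video)) == 3)
  nf <- dim(video)[1]
  if (is.null(frames)) frames <- seq_len(nf) - 1L
  stopifnot(length(frames) == nf)
  res <- vector("list", nf)
  for (k in seq_len(nf)) {
    s <- locate_spots(video[k, , ], params)
    if (nrow(s) > 0) s$frame <- frames[k]
    res[[k]] <- s
  }
  res <- res[vapply(res, nrow, integer(1)) > 0]
  if (length(res) == 0) {
    out <- data.frame(x_px = numeric(), y_px = numeric(),
                      sigma_px = numeric(), intensity = numeric(),
                      background = numeric(), converged = logical(),
                      frame = integer())
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
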