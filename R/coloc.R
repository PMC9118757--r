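#' Colocalization parameters
#'
#' @param max_distance_nm Maximum summary inter-channel distance for a pair
#'   to qualify (default 320 nm, i.e. 4 px at 80 nm).
#' @param min_overlap_frames Minimum number of common frames.
#' @param summary_statistic `"median"` (default) or `"mean"` distance over
#'   the temporal overlap.
#' @return Object of class `coloc_params`.
#' @export
colocalization_params <- function(max_distance_nm = 320,
                                  min_overlap_frames = 20,
                                  summary_statistic = c("median", "mean")) {
  assert_number(max_distance_nm, "max_distance_nm", 0, strict = TRUE)
  assert_number(min_overlap_frames, "min_overlap_frames", 1)
  summary_statistic <- match.arg(summary_statistic)
  structure(list(max_distance_nm = max_distance_nm,
                 min_overlap_frames = as.integer(min_overlap_frames),
                 summary_statistic = summary_statistic),
            class = "coloc_params")
}

#' Dynamic two-channel trajectory colocalization
#'
#' For every green-red trajectory pair sharing at least
#' `min_overlap_frames` frames, the summary (median or mean) inter-channel
#' distance over the common frames is computed; a pair qualifies when it is
#' at most `max_distance_nm`. Each moving green trajectory is assigned its
#' nearest qualifying red partner, and the colocalized fraction is the
#' share of moving green trajectories with a partner. Both channels must be
#' registered into one coordinate frame (see [split_channels()]).
#'
#' @param green,red Trajectory tables in one coordinate frame.
#' @param geometry An [acquisition_geometry()].
#' @param params A [colocalization_params()].
#' @param phase_par A [phase_params()] used to classify moving green
#'   trajectories when `moving_ids` is not given.
#' @param moving_ids Optional integer vector of green `particle_id`s to
#'   treat as moving (skips classification).
#' @return Object of class `coloc_result`: list with `pairs` (data frame
#'   `green_id`, `red_id`, `n_overlap`, `summary_distance_nm` of the
#'   assigned partners), `colocalized_fraction`, `n_moving_green`,
#'   `n_colocalized`.
#' @export
match_trajectories <- function(green, red,
                               geometry = acquisition_geometry(),
                               params = colocalization_params(),
                               phase_par = phase_params(),
                               moving_ids = NULL) {
  if (isTRUE(geometry$dual_view) && anyNA(geometry$channel_offset_px)) {
    stop("misuse error: channels are not registered ",
         "(channel_offset_px unset)", call. = FALSE)
  }
  stat <- match.fun(params$summary_statistic)
  g_parts <- split_trajectories(green)
  r_parts <- split_trajectories(red)

  if (is.null(moving_ids)) {
    moving_ids <- vapply(g_parts, function(p) {
      if (nrow(p) < 2) return(NA_integer_)
      ph <- parse_phases(p, phase_par, geometry)
      if (classify_moving(p, ph, phase_par)) p$particle_id[1] else NA_integer_
    }, integer(1))
    moving_ids <- moving_ids[!is.na(moving_ids)]
  }

  pair_rows <- list()
  for (g in g_parts) {
    gid <- g$particle_id[1]
    if (!(gid %in% moving_ids)) next
    best <- NULL
    for (r in r_parts) {
      common <- intersect(g$frame, r$frame)
      if (length(common) < params$min_overlap_frames) next
      gi <- match(common, g$frame)
      ri <- match(common, r$frame)
      d_nm <- sqrt((g$x_px[gi] - r$x_px[ri])^2 +
                     (g$y_px[gi] - r$y_px[ri])^2) * geometry$pixel_size_nm
      s <- stat(d_nm)
      if (s <= params$max_distance_nm &&
          (is.null(best) || s < best$summary_distance_nm)) {
        best <- data.frame(green_id = gid, red_id = r$particle_id[1],
                           n_overlap = length(common),
                           summary_distance_nm = s)
      }
    }
    if (!is.null(best)) pair_rows[[length(pair_rows) + 1]] <- best
  }
  pairs <- if (length(pair_rows) > 0) do.call(rbind, pair_rows) else
    data.frame(green_id = integer(), red_id = integer(),
               n_overlap = integer(), summary_distance_nm = numeric())
  n_moving <- length(moving_ids)
  structure(list(
    pairs = pairs,
    colocalized_fraction = if (n_moving > 0) nrow(pairs) / n_moving
      else NA_real_,
    n_moving_green = n_moving,
    n_colocalized = nrow(pairs)
  ), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d / %d moving green trajectories colocalized (fraction %.3f)\n",
              x$n_colocalized, x$n_moving_green, x$colocalized_fraction))
  invisible(x)
}

# Even-odd point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    denom <- vy[j] - vy[i]
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) /
        ifelse(denom == 0, Inf, denom)
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  inside
}

# Pixels (0-based centers at integers) inside a polygon given as a matrix
# with columns x, y in pixel coordinates.
pixels_in_polygon <- function(image, polygon) {
  polygon <- as.matrix(polygon)
  cs <- max(0, floor(min(polygon[, 1]))):min(ncol(image) - 1, ceiling(max(polygon[, 1])))
  rs <- max(0, floor(min(polygon[, 2]))):min(nrow(image) - 1, ceiling(max(polygon[, 2])))
  if (length(cs) == 0 || length(rs) == 0) return(matrix(integer(0), ncol = 2))
  grid <- expand.grid(row = rs, col = cs)
  ok <- point_in_polygon(grid$col, grid$row, polygon[, 1], polygon[, 2])
  as.matrix(grid[ok, c("row", "col"), drop = FALSE])
}

#' Background-subtracted mean intensity over a branch ROI
#'
#' Mean counts per pixel over the pixels whose centers fall inside the ROI
#' polygon, minus the same mean over a background polygon drawn in a region
#' without branches (the standard readout for fluorophore decoration of a
#' neurite segment, typically drawn over a 30 um branch length).
#'
#' @param image 2-D intensity matrix (e.g. the first green-channel frame).
#' @param roi Polygon matrix (columns x, y, 0-based pixel coordinates).
#' @param background Background polygon in the same coordinates.
#' @return Background-subtracted mean counts per pixel (scalar). A
#'   background polygon overlapping the ROI underestimates the signal; this
#'   raises a warning.
#' @export
branch_roi_intensity <- function(image, roi, background) {
  stopifnot(is.matrix(image))
  roi_px <- pixels_in_polygon(image, roi)
  bg_px <- pixels_in_polygon(image, background)
  if (nrow(roi_px) == 0) {
    stop("validation error: ROI polygon encloses no pixel centers",
         call. = FALSE)
  }
  if (nrow(bg_px) == 0) {
    stop("validation error: background polygon encloses no pixel centers",
         call. = FALSE)
  }
  if (nrow(merge(as.data.frame(roi_px), as.data.frame(bg_px))) > 0) {
    warning("background polygon overlaps the ROI; signal will be ",
            "underestimated", call. = FALSE)
  }
  mean(image[roi_px + 1L]) - mean(image[bg_px + 1L])
}
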