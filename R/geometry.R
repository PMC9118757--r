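#' Acquisition geometry
#'
#' Describes the camera and sampling geometry of a video: physical pixel
#' size in the sample plane, frame rate, video duration, sensor dimensions
#' and, for two-colour acquisitions, the dual-view layout in which the two
#' spectral channels share one sensor as two stacked rectangular views.
#'
#' @param pixel_size_nm Length of one pixel in the sample plane (nm).
#' @param frame_rate_hz Acquisition rate (frames per second).
#' @param duration_s Video duration (seconds).
#' @param sensor_width_px,sensor_height_px Sensor size in pixels.
#' @param dual_view `TRUE` when the sensor carries two stacked colour views
#'   of the same field of view.
#' @param view_height_px Rows per colour view when `dual_view`.
#' @param channel_offset_px Length-2 numeric `(dx, dy)`: rigid translation
#'   applied to the red view to bring it into the green view's coordinate
#'   frame (see [split_channels()]).
#'
#' @return An object of class `acquisition_geometry` (a named list).
#' @examples
#' geom <- acquisition_geometry()
#' geom$pixel_size_nm
#' @export
acquisition_geometry <- function(pixel_size_nm = 80,
                                 frame_rate_hz = 20,
                                 duration_s = 120,
                                 sensor_width_px = 1004,
                                 sensor_height_px = 1002,
                                 dual_view = FALSE,
                                 view_height_px = 501,
                                 channel_offset_px = c(0, 0)) {
  assert_number(pixel_size_nm, "pixel_size_nm", 0, strict = TRUE)
  assert_number(frame_rate_hz, "frame_rate_hz", 0, strict = TRUE)
  assert_number(duration_s, "duration_s", 0, strict = TRUE)
  assert_number(sensor_width_px, "sensor_width_px", 1)
  assert_number(sensor_height_px, "sensor_height_px", 1)
  assert_flag(dual_view, "dual_view")
  assert_number(view_height_px, "view_height_px", 1)
  if (!is.numeric(channel_offset_px) || length(channel_offset_px) != 2) {
    stop("validation error: `channel_offset_px` must be numeric (dx, dy)",
         call. = FALSE)
  }
  if (dual_view && 2 * view_height_px > sensor_height_px) {
    stop("geometry error: 2 * view_height_px exceeds sensor_height_px",
         call. = FALSE)
  }
  structure(list(
    pixel_size_nm = pixel_size_nm,
    frame_rate_hz = frame_rate_hz,
    duration_s = duration_s,
    sensor_width_px = as.integer(sensor_width_px),
    sensor_height_px = as.integer(sensor_height_px),
    dual_view = dual_view,
    view_height_px = as.integer(view_height_px),
    channel_offset_px = as.numeric(channel_offset_px)
  ), class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat("<acquisition_geometry>\n")
  cat(sprintf("  pixel: %g nm, rate: %g Hz, duration: %g s (%d frames)\n",
              x$pixel_size_nm, x$frame_rate_hz, x$duration_s, n_frames(x)))
  cat(sprintf("  sensor: %d x %d px%s\n", x$sensor_width_px,
              x$sensor_height_px,
              if (x$dual_view) sprintf(", dual view (%d rows per colour)",
                                       x$view_height_px) else ""))
  invisible(x)
}

#' Number of frames implied by a geometry
#' @param geometry An [acquisition_geometry()].
#' @return Integer frame count `round(duration_s * frame_rate_hz)`.
#' @export
n_frames <- function(geometry) {
  as.integer(round(geometry$duration_s * geometry$frame_rate_hz))
}

# Physical extent (um) of the analysed view. For dual-view geometries the
# per-colour view height is used.
fov_extent_um <- function(geometry) {
  h_px <- if (geometry$dual_view) geometry$view_height_px else geometry$sensor_height_px
  c(width_um = geometry$sensor_width_px * geometry$pixel_size_nm / 1000,
    height_um = h_px * geometry$pixel_size_nm / 1000)
}

um_to_px <- function(um, geometry) um * 1000 / geometry$pixel_size_nm
px_to_um <- function(px, geometry) px * geometry$pixel_size_nm / 1000
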