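#' Default analysis configuration
#'
#' All tunable parameters of the pipeline, grouped by stage. Values mirror
#' the study conditions: 80 nm pixels, 20 frames/s, 2-minute videos, a 0.8
#' confinement-ratio threshold and a measured PSF SD of 112 nm.
#'
#' @return Nested named list with sections `geometry`, `detection`, `phases`,
#'   `optics`, `coloc` and `morphometry`.
#' @export
default_config <- function() {
  list(
    geometry = list(
      pixel_size_nm = 80,
      frame_rate_hz = 20,
      duration_s = 120,
      sensor_width_px = 1004,
      sensor_height_px = 1002,
      dual_view = FALSE,
      view_height_px = 501,
      channel_offset_px = c(0, 0)
    ),
    detection = list(
      spot_diameter_px = 7,
      min_mass = 100,
      max_displacement_px = 5,
      memory_frames = 3,
      min_track_frames = 50,
      threshold = NULL
    ),
    phases = list(
      confinement_threshold = 0.8,
      window_frames = 5,
      min_phase_frames = 2,
      min_directed_displacement_um = 1.0
    ),
    optics = list(
      sigma_psf_nm = 112,
      photons_per_frame = 5000,
      background_counts = 10,
      read_noise_sd = 2,
      object_sigma_nm = 0
    ),
    coloc = list(
      max_distance_nm = 320,
      min_overlap_frames = 20,
      summary_statistic = "median"
    ),
    morphometry = list(
      sigma_psf_nm = 112,
      emission_wavelength_nm = 700,
      numerical_aperture = 1.49,
      use_empirical_psf = FALSE
    )
  )
}

# numeric keys checked on load; anything listed here must parse as a number
numeric_config_keys <- function() {
  cfg <- default_config()
  unlist(lapply(cfg, function(sec) {
    names(sec)[vapply(sec, is.numeric, logical(1))]
  }), use.names = FALSE)
}

#' Load a configuration file with overrides
#'
#' Reads a YAML key-value document and merges it over [default_config()];
#' `overrides` are applied last, so precedence is
#' defaults < file < overrides. Keys may be given nested under their section
#' (`detection: {min_mass: 50}`) or flat (`min_mass: 50`); flat keys are
#' routed to the section that defines them.
#'
#' @param path Path to a YAML file, or `NULL` for defaults only.
#' @param overrides Named list of values applied after the file.
#' @return List as [default_config()], with `$geometry` replaced by a
#'   validated [acquisition_geometry()].
#' @examples
#' cfg <- load_config(NULL, overrides = list(pixel_size_nm = 100))
#' cfg$geometry$pixel_size_nm
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("configuration error: file not found: ", path, call. = FALSE)
    }
    file_cfg <- yaml::read_yaml(path)
    cfg <- apply_config_values(cfg, file_cfg %||% list())
  }
  cfg <- apply_config_values(cfg, overrides)
  validate_config(cfg)
  cfg$geometry <- do.call(acquisition_geometry, cfg$geometry)
  cfg
}

# Merge `values` (possibly a mix of section lists and flat keys) into `cfg`.
apply_config_values <- function(cfg, values) {
  if (length(values) == 0) return(cfg)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("configuration error: all configuration entries must be named",
         call. = FALSE)
  }
  for (key in names(values)) {
    val <- values[[key]]
    if (key %in% names(cfg) && is.list(val)) {
      cfg[[key]] <- modifyList(cfg[[key]], val, keep.null = TRUE)
    } else {
      placed <- FALSE
      for (section in names(cfg)) {
        if (key %in% names(cfg[[section]])) {
          cfg[[section]][[key]] <- val
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        warning("unknown configuration key ignored: ", key, call. = FALSE)
      }
    }
  }
  cfg
}

validate_config <- function(cfg) {
  num_keys <- numeric_config_keys()
  for (section in names(cfg)) {
    for (key in names(cfg[[section]])) {
      val <- cfg[[section]][[key]]
      if (key %in% num_keys && !is.null(val) &&
          (!is.numeric(val) || anyNA(suppressWarnings(as.numeric(val))))) {
        stop("validation error: configuration key `", key,
             "` must be numeric, got: ", paste(format(val), collapse = ", "),
             call. = FALSE)
      }
    }
  }
  invisible(cfg)
}
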