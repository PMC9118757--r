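#' Empty trajectory table
#'
#' @return Zero-row data frame with the canonical trajectory columns
#'   (`fov_id`, `condition`, `channel`, `particle_id`, `frame`, `x_px`,
#'   `y_px`, `sigma_px`, `intensity`, `background`).
#' @export
empty_trajectories <- function() {
  data.frame(fov_id = character(), condition = character(),
             channel = character(), particle_id = integer(),
             frame = integer(), x_px = numeric(), y_px = numeric(),
             sigma_px = numeric(), intensity = numeric(),
             background = numeric(), stringsAsFactors = FALSE)
}

# Fill in missing annotation columns so partial tables (e.g. fresh linker
# output) can be written without boilerplate.
complete_trajectory_columns <- function(trajectories,
                                        fov_id = "fov1",
                                        condition = "none",
                                        channel = "red") {
  defaults <- list(fov_id = fov_id, condition = condition, channel = channel,
                   sigma_px = NA_real_, intensity = NA_real_,
                   background = NA_real_)
  for (col in names(defaults)) {
    if (!col %in% names(trajectories)) trajectories[[col]] <- defaults[[col]]
  }
  trajectories
}

#' Write a trajectory table
#'
#' One row per spot, comma separated, preceded by a header comment that
#' declares the numeric round-trip precision. Coordinates and intensities
#' are written with `digits` significant digits.
#'
#' @param trajectories Data frame with the columns of [empty_trajectories()]
#'   (extra columns are written too).
#' @param path Output path.
#' @param digits Significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path, digits = 9) {
  missing_cols <- setdiff(TRAJECTORY_COLUMNS, names(trajectories))
  if (length(missing_cols) > 0) {
    stop("format error: trajectory table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ord <- c(TRAJECTORY_COLUMNS, setdiff(names(trajectories), TRAJECTORY_COLUMNS))
  out <- trajectories[, ord, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = digits)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cargotrack trajectory table v1; numeric precision: %d significant digits",
                     digits), con)
  write.table(out, con, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a trajectory table written by [write_trajectories()]
#'
#' @param path File path.
#' @return Data frame of spots. Unknown extra columns are kept with a
#'   warning; a missing required column is a format error.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) {
    stop("I/O error: file not found: ", path, call. = FALSE)
  }
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRAJECTORY_COLUMNS, names(tab))
  if (length(missing_cols) > 0) {
    stop("format error: trajectory file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(tab), TRAJECTORY_COLUMNS)
  if (length(extra) > 0) {
    warning("unknown trajectory column(s) kept: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) > 0) {
    tab <- tab[order(tab$channel, tab$particle_id, tab$frame), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

# Split a trajectory table into per-particle data frames ordered by frame.
# Particles are keyed by channel + particle_id so two-channel tables are safe.
split_trajectories <- function(trajectories) {
  if (nrow(trajectories) == 0) return(list())
  key <- if ("channel" %in% names(trajectories)) {
    paste(trajectories$channel, trajectories$particle_id, sep = "/")
  } else {
    as.character(trajectories$particle_id)
  }
  parts <- split(trajectories, key)
  lapply(parts, function(p) {
    p <- p[order(p$frame), , drop = FALSE]
    if (anyDuplicated(p$frame)) {
      stop("validation error: duplicated frame within particle ",
           p$particle_id[1], call. = FALSE)
    }
    rownames(p) <- NULL
    p
  })
}
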