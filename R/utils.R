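`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

assert_number <- function(x, name, lower = -Inf, strict = FALSE, len = 1) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stop("validation error: `", name, "` must be numeric of length ", len,
         call. = FALSE)
  }
  ok <- if (strict) all(x > lower) else all(x >= lower)
  if (!ok) {
    stop("validation error: `", name, "` must be ",
         if (strict) "> " else ">= ", lower, call. = FALSE)
  }
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x)) {
    stop("validation error: `", name, "` must be TRUE or FALSE", call. = FALSE)
  }
  invisible(x)
}

# Required column layout of every trajectory/spot table.
TRAJECTORY_COLUMNS <- c("fov_id", "condition", "channel", "particle_id",
                        "frame", "x_px", "y_px", "sigma_px", "intensity",
                        "background")
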