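# Crocker-Grier style frame-to-frame linking: within each frame the
# candidate links (distance <= max_displacement_px) are grouped into
# independent sub-networks and each sub-network is solved exactly for the
# assignment minimizing total squared displacement, with a penalty of
# max_displacement^2 for starting a new track. Tracks unmatched for at most
# memory_frames keep their identity and may resume.

# Exact minimum-cost assignment of columns (new spots) to distinct rows
# (active tracks) or to NA (new track, costing `penalty`). Branch and bound;
# components are small, so full enumeration is cheap.
best_assignment <- function(D2, penalty) {
  nb <- ncol(D2)
  best_cost <- Inf
  best <- rep(NA_integer_, nb)
  used <- rep(FALSE, nrow(D2))
  cur <- rep(NA_integer_, nb)
  rec <- function(j, cost) {
    if (cost >= best_cost) return(invisible())
    if (j > nb) {
      best_cost <<- cost
      best <<- cur
      return(invisible())
    }
    cand <- which(!used & is.finite(D2[, j]))
    if (length(cand) > 1) cand <- cand[order(D2[cand, j])]
    for (i in cand) {
      used[i] <<- TRUE
      cur[j] <<- i
      rec(j + 1L, cost + D2[i, j])
      used[i] <<- FALSE
      cur[j] <<- NA_integer_
    }
    rec(j + 1L, cost + penalty)
  }
  rec(1L, 0)
  best
}

# Greedy fallback for implausibly large sub-networks: accept candidate links
# in order of increasing distance.
greedy_assignment <- function(D2) {
  nb <- ncol(D2)
  out <- rep(NA_integer_, nb)
  finite <- which(is.finite(D2))
  if (length(finite) == 0) return(out)
  ord <- finite[order(D2[finite])]
  used_a <- rep(FALSE, nrow(D2))
  for (k in ord) {
    i <- (k - 1) %% nrow(D2) + 1
    j <- (k - 1) %/% nrow(D2) + 1
    if (!used_a[i] && is.na(out[j])) {
      out[j] <- i
      used_a[i] <- TRUE
    }
  }
  out
}

#' Link localized spots into trajectories
#'
#' Frame-to-frame assignment minimizing total squared displacement subject
#' to a per-step search radius (Crocker-Grier); a particle unmatched for at
#' most `memory_frames` consecutive frames resumes under the same
#' `particle_id`. Ids are dense integers starting at 1, in order of track
#' birth.
#'
#' @param spots Data frame with `frame`, `x_px`, `y_px` (extra columns kept).
#' @param params A [detection_params()].
#' @return `spots` with a `particle_id` column, ordered by particle then
#'   frame.
#' @export
link_spots <- function(spots, params = detection_params()) {
  stopifnot(all(c("frame", "x_px", "y_px") %in% names(spots)))
  if (nrow(spots) == 0) {
    spots$particle_id <- integer(0)
    return(spots)
  }
  r2 <- params$max_displacement_px^2
  mem <- params$memory_frames
  n <- nrow(spots)
  ord0 <- order(spots$frame)
  spots <- spots[ord0, , drop = FALSE]
  pid <- integer(n)

  frames_seq <- seq(min(spots$frame), max(spots$frame))
  fidx <- split(seq_len(n), factor(spots$frame, levels = frames_seq))

  act_id <- integer(0)
  act_x <- numeric(0)
  act_y <- numeric(0)
  act_f <- integer(0)
  next_id <- 1L

  for (fi in seq_along(frames_seq)) {
    f <- frames_seq[fi]
    alive <- act_f >= f - 1L - mem
    act_id <- act_id[alive]; act_x <- act_x[alive]
    act_y <- act_y[alive]; act_f <- act_f[alive]
    rows <- fidx[[fi]]
    nb <- length(rows)
    if (nb == 0) next
    bx <- spots$x_px[rows]
    by <- spots$y_px[rows]
    na <- length(act_id)
    assign_b <- rep(NA_integer_, nb)
    if (na > 0) {
      D2 <- outer(act_x, bx, "-")^2 + outer(act_y, by, "-")^2
      D2[D2 > r2] <- Inf
      # sub-networks via union-find over rows (1..na) and cols (na+1..na+nb)
      parent <- seq_len(na + nb)
      findp <- function(x) {
        while (parent[x] != x) {
          parent[x] <<- parent[parent[x]]
          x <- parent[x]
        }
        x
      }
      link_idx <- which(is.finite(D2))
      for (k in link_idx) {
        i <- as.integer((k - 1L) %% na) + 1L
        j <- as.integer((k - 1L) %/% na) + 1L
        ri <- findp(i); rj <- findp(na + j)
        if (ri != rj) parent[ri] <- rj
      }
      comp_b <- vapply(seq_len(nb), function(j) findp(na + j), numeric(1))
      comp_a <- vapply(seq_len(na), function(i) findp(i), numeric(1))
      for (comp in unique(comp_b)) {
        Bj <- which(comp_b == comp)
        Ai <- which(comp_a == comp)
        if (length(Ai) == 0) next  # all isolated: new tracks
        D2s <- D2[Ai, Bj, drop = FALSE]
        sol <- if (length(Bj) <= 10) best_assignment(D2s, r2) else
          greedy_assignment(D2s)
        assign_b[Bj] <- ifelse(is.na(sol), NA_integer_, Ai[sol])
      }
    }
    for (j in seq_len(nb)) {
      a <- assign_b[j]
      if (is.na(a)) {
        act_id <- c(act_id, next_id)
        act_x <- c(act_x, bx[j])
        act_y <- c(act_y, by[j])
        act_f <- c(act_f, f)
        pid[rows[j]] <- next_id
        next_id <- next_id + 1L
      } else {
        pid[rows[j]] <- act_id[a]
        act_x[a] <- bx[j]
        act_y[a] <- by[j]
        act_f[a] <- f
      }
    }
  }
  spots$particle_id <- pid
  spots <- spots[order(spots$particle_id, spots$frame), , drop = FALSE]
  rownames(spots) <- NULL
  spots
}

#' Drop short trajectories
#'
#' Keeps trajectories with at least `min_track_frames` localized spots.
#'
#' @param trajectories Trajectory table with `particle_id` (and optionally
#'   `channel`).
#' @param params A [detection_params()], or a single number used directly as
#'   the minimum spot count.
#' @return Filtered table; attributes `n_kept` and `n_dropped` count
#'   trajectories.
#' @export
filter_trajectories <- function(trajectories, params = detection_params()) {
  min_frames <- if (is.numeric(params)) params else params$min_track_frames
  if (length(min_frames) != 1 || is.na(min_frames) || min_frames < 0) {
    stop("validation error: minimum track length must be a single ",
         "non-negative number", call. = FALSE)
  }
  if (nrow(trajectories) == 0) {
    attr(trajectories, "n_kept") <- 0L
    attr(trajectories, "n_dropped") <- 0L
    return(trajectories)
  }
  key <- if ("channel" %in% names(trajectories)) {
    paste(trajectories$channel, trajectories$particle_id, sep = "/")
  } else {
    as.character(trajectories$particle_id)
  }
  sizes <- table(key)
  keep_keys <- names(sizes)[sizes >= min_frames]
  out <- trajectories[key %in% keep_keys, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_kept") <- length(keep_keys)
  attr(out, "n_dropped") <- length(sizes) - length(keep_keys)
  out
}

#' Track a video stack end to end
#'
#' Convenience wrapper: localize every frame, link, and drop short tracks.
#'
#' @param video 3-D array `(frame, row, column)`.
#' @param params A [detection_params()].
#' @param channel,condition,fov_id Annotation columns for the output table.
#' @return Trajectory table (see [empty_trajectories()]).
#' @export
track_video <- function(video, params = detection_params(), channel = "red",
                        condition = "none", fov_id = "fov1") {
  spots <- locate_stack(video, params)
  traj <- link_spots(spots, params)
  traj <- filter_trajectories(traj, params)
  traj <- complete_trajectory_columns(traj, fov_id = fov_id,
                                      condition = condition,
                                      channel = channel)
  traj$converged <- NULL
  cols <- c(TRAJECTORY_COLUMNS, setdiff(names(traj), TRAJECTORY_COLUMNS))
  traj[, cols, drop = FALSE]
}
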