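# Independent reference implementations used as oracles. Deliberately
# naive (explicit loops, no shared code with the package internals).

# Windowed confinement ratio, one frame at a time.
ref_confinement <- function(x, y, w) {
  n <- length(x)
  out <- numeric(n)
  h <- (w - 1) / 2
  for (i in seq_len(n)) {
    if (n < w) {
      a <- 1; b <- n
    } else {
      a <- max(1, i - h); b <- min(n, i + h)
    }
    path <- 0
    if (b > a) {
      for (k in a:(b - 1)) {
        path <- path + sqrt((x[k + 1] - x[k])^2 + (y[k + 1] - y[k])^2)
      }
    }
    net <- sqrt((x[b] - x[a])^2 + (y[b] - y[a])^2)
    out[i] <- if (path > 0) net / path else 0
  }
  pmin(pmax(out, 0), 1)
}

# Threshold + shortest-run-first merging, returning per-frame go labels.
ref_parse_labels <- function(x, y, w, threshold, min_len) {
  lab <- ref_confinement(x, y, w) > threshold
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_len)
    if (length(short) == 0) break
    j <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    lab[starts[j]:ends[j]] <- !r$values[j]
  }
  lab
}

# Expand parse_phases() output back to per-frame go labels.
phases_to_labels <- function(phases) {
  rep(phases$kind == "go", phases$n_frames)
}

# Exact two-tailed Mann-Whitney p by full enumeration of group assignments.
# For tie-free data the U distribution is symmetric about na*nb/2, so the
# two-tailed p is the probability of |U - mu| at least as large as observed.
mw_enum_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  u_of <- function(aa, bb) sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  u_obs <- u_of(a, b)
  combs <- utils::combn(na + nb, na)
  us <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mu <- na * nb / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Random mixed go/stop trajectory in pixel coordinates: directed segments
# (step_px per frame along a random direction) alternating with stationary
# jitter, plus localization noise.
random_gostop_traj <- function(n_frames, step_px = 0.6, jitter_px = 0.15) {
  x <- numeric(n_frames); y <- numeric(n_frames)
  pos <- c(runif(1, 20, 40), runif(1, 20, 40))
  going <- runif(1) < 0.5
  remaining <- 0
  theta <- runif(1, 0, 2 * pi)
  for (i in seq_len(n_frames)) {
    if (remaining <= 0) {
      going <- !going
      remaining <- sample(3:25, 1)
      if (going) theta <- runif(1, 0, 2 * pi)
    }
    if (going) pos <- pos + step_px * c(cos(theta), sin(theta))
    x[i] <- pos[1] + rnorm(1, 0, jitter_px)
    y[i] <- pos[2] + rnorm(1, 0, jitter_px)
    remaining <- remaining - 1
  }
  data.frame(particle_id = 1L, frame = seq_len(n_frames) - 1L,
             x_px = x, y_px = y)
}
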