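# Independent oracles and fixture builders. These deliberately use naive,
# brute-force computations so they stay independent of the implementation
# paths they check.

# straight-line track at constant speed (um/min), heading east
constant_velocity_track <- function(speed_um_min, n = 10L, dt = 30,
                                    cell_id = "cv") {
  step <- speed_um_min / 60 * dt
  track(cell_id, frames = 0:(n - 1L), x = step * (0:(n - 1L)), y = rep(0, n),
        frame_interval = dt)
}

# oracle for smoothed speed: direct arithmetic over the window of the two
# steps before and the two after frame i
oracle_smoothed_speed <- function(x, y, t) {
  n <- length(x)
  inst <- sapply(seq_len(n - 1L), function(j) {
    sqrt((x[j + 1] - x[j])^2 + (y[j + 1] - y[j])^2) / (t[j + 1] - t[j]) * 60
  })
  sapply(seq_len(n), function(i) {
    js <- intersect((i - 2L):(i + 1L), seq_len(n - 1L))
    mean(inst[js])
  })
}

# rigid-body transform of a track (rotation by theta then translation)
rigid_transform <- function(tr, theta = 0, shift = c(0, 0)) {
  Rm <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  p <- tr$positions %*% t(Rm)
  track(tr$cell_id, tr$frames, p[, 1] + shift[1], p[, 2] + shift[2],
        times = tr$times, channels = tr$channels,
        frame_interval = tr$frame_interval)
}

# brute-force pixel-set arithmetic on a list of logical masks: represents
# each foreground pixel as a "row:col" string and uses set operations
oracle_union_count <- function(masks) {
  pix <- unlist(lapply(masks, function(m) {
    idx <- which(m, arr.ind = TRUE)
    paste(idx[, 1], idx[, 2], sep = ":")
  }))
  length(unique(pix))
}

oracle_overlap_count <- function(a, b) {
  pa <- which(a, arr.ind = TRUE); pb <- which(b, arr.ind = TRUE)
  length(intersect(paste(pa[, 1], pa[, 2], sep = ":"),
                   paste(pb[, 1], pb[, 2], sep = ":")))
}

# exhaustive-enumeration two-sided p for the Mann-Whitney U statistic
oracle_mann_whitney_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  idx <- utils::combn(length(pooled), n_a)
  u_of <- function(av, bv) sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  u_obs <- u_of(a, b)
  mu <- n_a * length(b) / 2
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Monte-Carlo stay-probability of finely sampled Brownian motion: the chance
# that the max displacement from the start stays within radius r over time
# t_w, at diffusion D
oracle_stay_probability <- function(D, t_w, r, n_rep = 10000L, n_sub = 200L,
                                    seed = 42L) {
  set.seed(seed)
  sd_step <- sqrt(2 * D * t_w / n_sub)
  hits <- replicate(n_rep, {
    pos <- apply(matrix(stats::rnorm(2L * n_sub, 0, sd_step), ncol = 2),
                 2, cumsum)
    sqrt(max(pos[, 1]^2 + pos[, 2]^2)) <= r
  })
  mean(hits)
}

# toy 2-cell track table on disk, returns the path
write_toy_track_csv <- function(path, gap = FALSE) {
  frames <- if (gap) c(0L, 1L, 5L) else 0:2
  df <- rbind(
    data.frame(cell_id = "a", frame = frames, time_s = frames * 30,
               x_um = c(0, 1, 2), y_um = c(0, 0, 1), calcium_ratio = c(1, 2, 3)),
    data.frame(cell_id = "b", frame = 0:2, time_s = (0:2) * 30,
               x_um = c(5, 6, 7), y_um = c(5, 5, 5), calcium_ratio = c(1, 1, 1)))
  # shuffle rows: readers must sort
  df <- df[c(4, 1, 6, 2, 5, 3), ]
  utils::write.csv(df, path, row.names = FALSE)
  path
}
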