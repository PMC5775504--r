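# Transient-confinement detection and synapse/kinapse classification.
#
# The confinement score follows the Simson-Saxton probability-level approach
# developed for single-particle tracks of membrane proteins: for sliding
# windows along the track, estimate the probability (psi) that a freely
# diffusing particle with the track's diffusion coefficient would remain
# within the spatial span observed in the window. Improbably tight spans give
# a high score L; runs of high L demarcate periods of relative confinement,
# whose positional spread R^2/t then decides stable synapse vs motile kinapse.

#' Estimate a short-lag diffusion coefficient from a track
#'
#' Ordinary least squares of the time-averaged mean squared displacement
#' against lag time through the origin, MSD(tau) = 4 D tau, over lags
#' `1..max_lag` frames. For directed or mixed (synapse/kinapse) motion this
#' upper-bounds the free diffusion coefficient, which is the conservative
#' direction for the confinement probability. D is floored at a small
#' positive epsilon so downstream probabilities stay defined.
#'
#' @param track An `sk_track` longer than `max_lag`.
#' @param max_lag Maximum lag in frames (default 4).
#' @param epsilon Floor for D, um^2/s.
#' @return An `sk_motion_stats`: `D` (um^2/s), `mean_speed` (um/min),
#'   `smoothed_speed` (um/min per frame), `msd` (per-lag table).
#' @export
estimate_diffusion <- function(track, max_lag = 4L, epsilon = 1e-6) {
  n <- n_frames(track)
  if (n <= max_lag || max_lag < 2L) {
    stop("track too short: need length > max_lag >= 2")
  }
  pos <- track$positions
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(k) {
    d <- pos[(1L + k):n, , drop = FALSE] - pos[1L:(n - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  tau <- lags * track$frame_interval
  slope <- sum(msd * tau) / sum(tau^2)
  sp <- smoothed_speed(track)
  structure(list(D = max(slope / 4, epsilon), mean_speed = mean(sp),
                 smoothed_speed = sp,
                 msd = data.frame(lag_frames = lags, tau_s = tau, msd = msd)),
            class = "sk_motion_stats")
}

#' @export
print.sk_motion_stats <- function(x, ...) {
  cat(sprintf("<sk_motion_stats> D = %.4g um^2/s, mean speed %.2f um/min\n",
              x$D, x$mean_speed))
  invisible(x)
}

# Simson-type chance probability for a window: duration t_w (s), observed
# excursion radius r (um, max displacement from the window's first point),
# free diffusion D (um^2/s). The calibrated relation
# log10(psi) = 0.2048 - 2.5117 * D * t / r^2 approximates the probability
# that a freely diffusing particle stays within r of its starting point for
# time t; evaluated at the observed excursion radius it is approximately a
# probability integral transform, i.e. near-uniform under the null.
simson_psi <- function(D, t_w, r, psi_floor) {
  r2 <- r^2
  if (r2 <= 0) return(psi_floor)
  min(max(10^(0.2048 - 2.5117 * D * t_w / r2), psi_floor), 1)
}

#' Per-frame confinement score
#'
#' For each frame and each window length, the window centred on the frame
#' yields a chance probability psi via the Simson-type relation
#' `log10(psi) = 0.2048 - 2.5117 * D * t / r^2`, where r is the maximum
#' displacement from the window's first position (the excursion radius whose
#' stay-probability the relation was calibrated on) and t the window
#' duration. Evaluated at the observed radius, psi is approximately uniform
#' under free diffusion, which is what makes the score's threshold a chance
#' probability. psi maps to the score by the fixed transform
#' `L = max(0, -ln(psi) - 1)`, so the demarcation threshold L > 3 corresponds
#' to psi < e^-4 ~ 0.018, matching the printed chance bound of < 0.017 within
#' rounding. The per-frame score averages L over all window lengths; a window
#' length that does not fully fit contributes 0 (frames near track ends are
#' never called confined).
#'
#' @param track An `sk_track`.
#' @param motion `sk_motion_stats` for the track; computed if `NULL`.
#' @param windows Window lengths in frames (default `c(10, 15, 20, 25, 30)`).
#' @param L_max Score cap; psi is floored at `exp(-(L_max + 1))` so that
#'   degenerate zero-spread windows stay finite.
#' @return An `sk_confinement_profile`: `L` and `psi` per frame,
#'   `window_lengths`, and the `frame_interval` used.
#' @export
confinement_score <- function(track, motion = NULL,
                              windows = c(10L, 15L, 20L, 25L, 30L),
                              L_max = 10) {
  n <- n_frames(track)
  windows <- sort(unique(as.integer(windows)))
  if (any(windows < 3L)) stop("windows must be >= 3 frames")
  windows <- windows[windows <= n]
  if (!length(windows)) stop("no window fits the track")
  if (is.null(motion)) motion <- estimate_diffusion(track)
  psi_floor <- exp(-(L_max + 1))
  pos <- track$positions
  Lmat <- matrix(0, nrow = n, ncol = length(windows))
  for (wi in seq_along(windows)) {
    w <- windows[wi]
    h1 <- (w - 1L) %/% 2L
    h2 <- w - 1L - h1
    for (i in (1L + h1):(n - h2)) {
      idx <- (i - h1):(i + h2)
      dx <- pos[idx, 1] - pos[idx[1L], 1]
      dy <- pos[idx, 2] - pos[idx[1L], 2]
      r <- sqrt(max(dx^2 + dy^2))
      t_w <- track$times[i + h2] - track$times[i - h1]
      psi <- simson_psi(motion$D, t_w, r, psi_floor)
      Lmat[i, wi] <- max(0, -log(psi) - 1)
    }
  }
  L <- rowMeans(Lmat)
  structure(list(L = L, psi = pmin(exp(-(L + 1)), 1),
                 window_lengths = windows,
                 frame_interval = track$frame_interval),
            class = "sk_confinement_profile")
}

#' Demarcate periods of relative confinement
#'
#' Maximal runs of consecutive frames with score `L > L_threshold` lasting at
#' least `min_duration` frames become confined periods. Because the score at
#' a frame averages windows centred on it, a genuinely confined bout is
#' eroded at both ends by up to half a window (windows straddling the bout
#' edge pick up free motion and score low). When `edge_correction` is `TRUE`
#' (default) each run is therefore extended frame by frame, on each side,
#' while the position stays inside the run's confinement zone (within the
#' core run's excursion radius of its centroid, plus 1 um of slack), up to
#' half the largest window per side; overlapping runs are merged. Zone
#' statistics (R, t, spread) are computed over the extended run.
#'
#' @param track The `sk_track` the profile was computed from.
#' @param profile `sk_confinement_profile` from [confinement_score()].
#' @param L_threshold Demarcation threshold (default 3).
#' @param min_duration Minimum run length in frames (default 10, i.e. 5 min at
#'   30-s frames) to suppress single-frame flickers.
#' @param edge_correction Extend runs by half the smallest window (default
#'   `TRUE`).
#' @return Data frame of class `sk_confined_periods`, one row per period:
#'   `start_frame`/`end_frame` (1-based indices into the track), `t` (frames),
#'   `R` (zone diameter, um), `spread` (R^2/t, um^2/frame).
#' @export
demarcate_confined_periods <- function(track, profile, L_threshold = 3,
                                       min_duration = 10L,
                                       edge_correction = TRUE) {
  n <- n_frames(track)
  stopifnot(length(profile$L) == n)
  above <- profile$L > L_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) && edge_correction) {
    pad_max <- max(profile$window_lengths) %/% 2L
    pos <- track$positions
    for (k in seq_along(starts)) {
      core <- starts[k]:ends[k]
      ctr <- colMeans(pos[core, , drop = FALSE])
      zone <- sqrt(max((pos[core, 1] - ctr[1])^2 +
                       (pos[core, 2] - ctr[2])^2)) + 1
      inside <- function(i) {
        sqrt((pos[i, 1] - ctr[1])^2 + (pos[i, 2] - ctr[2])^2) <= zone
      }
      s <- starts[k]
      while (s > 1L && starts[k] - s < pad_max && inside(s - 1L)) s <- s - 1L
      e <- ends[k]
      while (e < n && e - ends[k] < pad_max && inside(e + 1L)) e <- e + 1L
      starts[k] <- s; ends[k] <- e
    }
    # merge runs that the extension made overlap or touch
    ms <- starts[1]; me <- ends[1]; out_s <- integer(); out_e <- integer()
    for (k in seq_along(starts)[-1]) {
      if (starts[k] <= me + 1L) me <- max(me, ends[k])
      else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
             ms <- starts[k]; me <- ends[k] }
    }
    starts <- c(out_s, ms); ends <- c(out_e, me)
  }
  periods <- data.frame(start_frame = integer(), end_frame = integer(),
                        t = integer(), R = numeric(), spread = numeric())
  if (length(starts)) {
    R <- vapply(seq_along(starts), function(k) {
      max_pairwise_distance(track$positions[starts[k]:ends[k], , drop = FALSE])
    }, numeric(1))
    t <- ends - starts + 1L
    periods <- data.frame(start_frame = starts, end_frame = ends,
                          t = t, R = R, spread = R^2 / t)
  }
  class(periods) <- c("sk_confined_periods", "data.frame")
  periods
}

#' Classify confined periods as positionally stable or not
#'
#' A confined period is called stable (synapse-like) when its positional
#' spread R^2/t falls below the threshold, 0.666 um^2/frame by default --
#' the value found to represent positional stability on uniformly coated
#' stimulatory surfaces.
#'
#' @param periods `sk_confined_periods` from [demarcate_confined_periods()].
#' @param spread_threshold um^2/frame (default 0.666).
#' @return The periods with a logical `stable` column appended.
#' @export
classify_stability <- function(periods, spread_threshold = 0.666) {
  periods$stable <- periods$spread < spread_threshold
  periods
}

#' Positional stability index and per-frame state labels
#'
#' Frames inside stable confined periods are labelled `stable_synapse`; all
#' other frames `motile_kinapse`. The positional stability index (PSI) is the
#' fraction of frames in the stable state; PSI > 0.5 means the cell spent
#' more time in synapse mode than in kinapse mode.
#'
#' @param track An `sk_track`.
#' @param periods Classified periods (with `stable` column); non-stable rows
#'   are ignored.
#' @return An `sk_track_classification`: `state` (factor per frame),
#'   `psi_index`, `cell_id`.
#' @export
positional_stability_index <- function(track, periods) {
  n <- n_frames(track)
  stable <- logical(n)
  if (nrow(periods)) {
    if (is.null(periods$stable)) stop("periods must carry a 'stable' column")
    for (k in which(periods$stable)) {
      stable[periods$start_frame[k]:periods$end_frame[k]] <- TRUE
    }
  }
  state <- factor(ifelse(stable, "stable_synapse", "motile_kinapse"),
                  levels = c("stable_synapse", "motile_kinapse"))
  structure(list(cell_id = track$cell_id, state = state,
                 psi_index = mean(stable)),
            class = "sk_track_classification")
}

#' @export
print.sk_track_classification <- function(x, ...) {
  cat(sprintf("<sk_track_classification> cell %s: PSI = %.3f (%d frames)\n",
              x$cell_id, x$psi_index, length(x$state)))
  invisible(x)
}

#' Full synapse/kinapse classification of one track
#'
#' Convenience wrapper chaining [estimate_diffusion()], [confinement_score()],
#' [demarcate_confined_periods()], [classify_stability()] and
#' [positional_stability_index()].
#'
#' @inheritParams confinement_score
#' @inheritParams demarcate_confined_periods
#' @inheritParams classify_stability
#' @param motion Optional `sk_motion_stats` (e.g. with a cohort-pooled D);
#'   estimated from the track when `NULL`.
#' @return List with `classification`, `periods`, `profile`, `motion`.
#' @export
classify_track <- function(track, windows = c(10L, 15L, 20L, 25L, 30L),
                           L_threshold = 3, min_duration = 10L,
                           spread_threshold = 0.666, L_max = 10,
                           edge_correction = TRUE, motion = NULL) {
  if (is.null(motion)) motion <- estimate_diffusion(track)
  profile <- confinement_score(track, motion, windows = windows, L_max = L_max)
  periods <- demarcate_confined_periods(track, profile,
                                        L_threshold = L_threshold,
                                        min_duration = min_duration,
                                        edge_correction = edge_correction)
  periods <- classify_stability(periods, spread_threshold)
  cls <- positional_stability_index(track, periods)
  list(classification = cls, periods = periods, profile = profile,
       motion = motion)
}

#' Per-track PSI summary table for a set of tracks
#'
#' The free-motion diffusion coefficient entering the confinement score is
#' estimated per track, but a track that stays confined throughout carries no
#' information about its own free motility -- its short-lag MSD reflects only
#' the confined jiggle, and the score cannot flag anything as improbable.
#' With `pool_D = TRUE` (default) each track's D is therefore floored at the
#' cohort median D: cells imaged together share conditions, so the cohort's
#' typical motility stands in for cells that never moved.
#'
#' @param tracks List of `sk_track`.
#' @param pool_D Floor per-track D at the cohort median (default `TRUE`).
#' @param ... Passed to [classify_track()].
#' @return Data frame: `cell_id`, `psi_index`, `n_stable_periods`,
#'   `total_confined_min`, `mean_speed_um_min`.
#' @export
psi_table <- function(tracks, pool_D = TRUE, ...) {
  motions <- lapply(tracks, estimate_diffusion)
  if (pool_D && length(tracks) > 1L) {
    d_med <- stats::median(vapply(motions, function(m) m$D, numeric(1)))
    motions <- lapply(motions, function(m) { m$D <- max(m$D, d_med); m })
  }
  rows <- lapply(seq_along(tracks), function(k) {
    tr <- tracks[[k]]
    res <- classify_track(tr, motion = motions[[k]], ...)
    per <- res$periods
    data.frame(cell_id = tr$cell_id,
               psi_index = res$classification$psi_index,
               n_stable_periods = sum(per$stable),
               total_confined_min = sum(per$t) * tr$frame_interval / 60,
               mean_speed_um_min = res$motion$mean_speed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Arrest coefficient (optional extra metric)
#'
#' Fraction of frames whose smoothed speed falls below a threshold. Provided
#' as a conventional motility summary alongside the positional stability
#' index; the two need not agree.
#'
#' @param track An `sk_track`.
#' @param speed_threshold um/min (default 2).
#' @return Scalar in `[0, 1]`.
#' @export
arrest_coefficient <- function(track, speed_threshold = 2) {
  mean(smoothed_speed(track) < speed_threshold)
}
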