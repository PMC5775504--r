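# Synthetic-data generators with ground truth: two-state (synapse/kinapse)
# motility, Brownian null tracks, exponential spot-residence times, and disk
# mask movies. Every generator is deterministic under a fixed seed and emits
# the labels needed to score the downstream metrics without re-derivation.

#' Parameters for the two-state motility simulator
#'
#' Defaults mimic the imaging regime the analysis targets: 30-s frames over a
#' 2-h movie (240 frames), kinapse crawling near 8 um/min with a ~2-min
#' heading persistence, and synapse dwells confined within a 2-um radius.
#' The stationary stable-dwell fraction is
#' `dwell_synapse / (dwell_synapse + dwell_kinapse)`.
#'
#' @param speed_kinapse Kinapse crawl speed, um/min.
#' @param persistence_time Heading persistence time of the kinapse walk, s.
#' @param confinement_radius Synapse confinement radius, um.
#' @param dwell_synapse,dwell_kinapse Mean exponential dwell times, s.
#' @param frame_interval Seconds per frame.
#' @param n_frames Movie length in frames.
#' @param seed RNG seed.
#' @param step_sd_synapse Per-axis step s.d. inside a synapse, um/frame;
#'   default `confinement_radius / 8`.
#' @return A `two_state_params` list.
#' @export
two_state_params <- function(speed_kinapse = 8, persistence_time = 120,
                             confinement_radius = 2, dwell_synapse = 900,
                             dwell_kinapse = 900, frame_interval = 30,
                             n_frames = 240L, seed = 1L,
                             step_sd_synapse = confinement_radius / 8) {
  p <- list(speed_kinapse = speed_kinapse,
            persistence_time = persistence_time,
            confinement_radius = confinement_radius,
            dwell_synapse = dwell_synapse, dwell_kinapse = dwell_kinapse,
            frame_interval = frame_interval, n_frames = as.integer(n_frames),
            seed = as.integer(seed), step_sd_synapse = step_sd_synapse)
  num <- unlist(p[c("speed_kinapse", "persistence_time", "confinement_radius",
                    "dwell_synapse", "dwell_kinapse", "frame_interval",
                    "n_frames", "step_sd_synapse")])
  if (any(num <= 0)) stop("all two-state parameters must be positive")
  if (p$dwell_synapse < frame_interval || p$dwell_kinapse < frame_interval) {
    stop("dwell means must be at least one frame interval")
  }
  structure(p, class = "two_state_params")
}

#' Simulate a two-state (synapse/kinapse) track with ground truth
#'
#' Alternating exponential dwells between two motility modes. Kinapse: a
#' persistent random walk -- the heading diffuses with angular variance
#' `2 * dt / persistence_time` per step while the step length is
#' `speed_kinapse * dt`. Synapse: a Gaussian random walk (per-axis s.d.
#' `step_sd_synapse`) reflected at a circular boundary of
#' `confinement_radius` around the entry point. The initial state is drawn
#' from the stationary dwell-fraction.
#'
#' @param params A [two_state_params()] object.
#' @param cell_id Identifier for the emitted track.
#' @return List with `track` (an `sk_track`) and `truth` (per-frame `state`
#'   labels `"synapse"`/`"kinapse"`, `stable_fraction`, and the params).
#' @export
simulate_two_state_track <- function(params = two_state_params(),
                                     cell_id = "sim") {
  p <- params
  set.seed(p$seed)
  n <- p$n_frames
  dt <- p$frame_interval
  p_syn <- p$dwell_synapse / (p$dwell_synapse + p$dwell_kinapse)
  state <- character(n)
  pos <- matrix(0, n, 2)
  cur <- if (stats::runif(1) < p_syn) "synapse" else "kinapse"
  dwell_left <- stats::rexp(1, 1 / (if (cur == "synapse") p$dwell_synapse
                                    else p$dwell_kinapse))
  heading <- stats::runif(1, 0, 2 * pi)
  anchor <- pos[1, ]
  step_kin <- p$speed_kinapse / 60 * dt
  sd_head <- sqrt(2 * dt / p$persistence_time)
  state[1] <- cur
  for (i in 2:n) {
    dwell_left <- dwell_left - dt
    if (dwell_left <= 0) {
      cur <- if (cur == "synapse") "kinapse" else "synapse"
      dwell_left <- stats::rexp(1, 1 / (if (cur == "synapse") p$dwell_synapse
                                        else p$dwell_kinapse))
      if (cur == "synapse") anchor <- pos[i - 1L, ]
      if (cur == "kinapse") heading <- stats::runif(1, 0, 2 * pi)
    }
    if (cur == "kinapse") {
      heading <- heading + stats::rnorm(1, 0, sd_head)
      pos[i, ] <- pos[i - 1L, ] + step_kin * c(cos(heading), sin(heading))
    } else {
      cand <- pos[i - 1L, ] + stats::rnorm(2, 0, p$step_sd_synapse)
      d <- sqrt(sum((cand - anchor)^2))
      if (d > p$confinement_radius) {
        # radial reflection at the confinement boundary
        d_new <- max(2 * p$confinement_radius - d, 0)
        cand <- anchor + (cand - anchor) / d * d_new
      }
      pos[i, ] <- cand
    }
    state[i] <- cur
  }
  tr <- track(cell_id, frames = 0:(n - 1L), x = pos[, 1], y = pos[, 2],
              frame_interval = dt)
  truth <- list(state = state, stable_fraction = mean(state == "synapse"),
                params = p)
  list(track = tr, truth = truth)
}

#' Simulate a pure Brownian (free-diffusion) null track
#'
#' I.i.d. Gaussian increments with per-axis variance `2 * D * dt` -- the
#' null model under which the confinement score's chance probability is
#' calibrated.
#'
#' @param D Diffusion coefficient, um^2/s (> 0; `D = 0` gives a stationary
#'   track).
#' @param n_frames Track length.
#' @param frame_interval Seconds per frame.
#' @param seed RNG seed.
#' @param cell_id Identifier.
#' @return An `sk_track`.
#' @export
simulate_brownian_track <- function(D, n_frames = 240L, frame_interval = 30,
                                    seed = 1L, cell_id = "brownian") {
  stopifnot(D >= 0)
  set.seed(seed)
  sd_step <- sqrt(2 * D * frame_interval)
  steps <- matrix(stats::rnorm(2L * (n_frames - 1L), 0, sd_step),
                  ncol = 2)
  pos <- rbind(c(0, 0), apply(steps, 2, cumsum))
  track(cell_id, frames = 0:(n_frames - 1L), x = pos[, 1], y = pos[, 2],
        frame_interval = frame_interval)
}

#' Simulate exponential spot-residence times
#'
#' First-order exit kinetics: lifetimes are exponential with rate
#' `ln(2) / half_life`, censored at the observation horizon. All cells
#' attach at t = 0, matching the protocol where imaging starts once the
#' spots are occupied.
#'
#' @param half_life Planted half-life, hours.
#' @param n_cells Number of records.
#' @param horizon Observation horizon, hours.
#' @param seed RNG seed.
#' @return `sk_interaction_records` with a `planted_half_life` attribute.
#' @export
simulate_residence_times <- function(half_life, n_cells = 300L, horizon = 8,
                                     seed = 1L) {
  stopifnot(half_life > 0, horizon > 0)
  set.seed(seed)
  life_h <- stats::rexp(n_cells, rate = log(2) / half_life)
  cen <- life_h >= horizon
  recs <- interaction_records(
    cell_id = sprintf("cell%04d", seq_len(n_cells)),
    spot_id = rep(1L, n_cells), attach_time = 0,
    exit_time = pmin(life_h, horizon) * 3600, censored = cen)
  attr(recs, "planted_half_life") <- half_life
  recs
}

#' Render a disk-cell mask movie along a track
#'
#' Per frame, a disk of `cell_radius` centred on the track position,
#' rasterized by pixel-centre inclusion on a raster covering `extent`.
#' Frames whose disk is clipped by the raster edge are flagged.
#'
#' @param track An `sk_track`.
#' @param cell_radius um (> `pixel_size`).
#' @param pixel_size um per pixel.
#' @param extent `c(xmin, ymin, xmax, ymax)` in um, or `c(width, height)`
#'   anchored at the origin.
#' @return An `sk_mask_series` with a logical `clipped` attribute per frame.
#' @export
render_mask_movie <- function(track, cell_radius, pixel_size, extent) {
  stopifnot(cell_radius > pixel_size)
  if (length(extent) == 2L) extent <- c(0, 0, extent[1], extent[2])
  xs <- seq(extent[1], extent[3], by = pixel_size)
  ys <- seq(extent[2], extent[4], by = pixel_size)
  n <- n_frames(track)
  r2 <- cell_radius^2
  clipped <- logical(n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    cx <- track$positions[i, 1]; cy <- track$positions[i, 2]
    masks[[i]] <- outer(ys, xs, function(y, x) (x - cx)^2 + (y - cy)^2 <= r2)
    clipped[i] <- (cx - cell_radius < extent[1] ||
                   cx + cell_radius > extent[3] ||
                   cy - cell_radius < extent[2] ||
                   cy + cell_radius > extent[4])
  }
  if (any(clipped)) {
    warning(sum(clipped), " frame(s) clipped at the raster edge")
  }
  ms <- mask_series(track$frames, masks, pixel_size,
                    origin = c(extent[1], extent[2]))
  attr(ms, "clipped") <- clipped
  ms
}

#' Simulate a cell engaging a stimulatory spot (with ground truth)
#'
#' A scripted approach-arrest(-exit) trajectory for testing arrest detection
#' and virtual synchronization: the cell crawls straight toward the spot
#' centre at `approach_speed`, jitters tightly on the spot from
#' `arrest_frame`, and (optionally) departs radially at `exit_frame`,
#' possibly latching onto a neighbouring spot. A `calcium_ratio` channel
#' steps from 1 to `calcium_amplitude` at arrest; `cell_area` steps from 80
#' to 160 um^2 (spreading).
#'
#' @param grid An `sk_spot_grid`.
#' @param spot_id Target spot.
#' @param arrest_frame 1-based frame at which the cell is first arrested.
#' @param exit_frame 1-based departure frame, or `NA` to stay for the movie.
#' @param n_frames Movie length.
#' @param approach_speed um/min before arrest and after exit.
#' @param jitter_sd Positional jitter on the spot, um.
#' @param calcium_amplitude Plateau of the calcium step.
#' @param rejoin_spot_id Neighbouring spot to latch onto after exit (`NA` to
#'   just leave).
#' @param frame_interval Seconds per frame.
#' @param seed RNG seed.
#' @param cell_id Identifier.
#' @return List with `track` and `truth` (`arrest_frame`, `exit_frame`,
#'   `spot_id`).
#' @export
simulate_spot_engagement <- function(grid, spot_id, arrest_frame = 21L,
                                     exit_frame = NA_integer_,
                                     n_frames = 120L, approach_speed = 8,
                                     jitter_sd = 0.3,
                                     calcium_amplitude = 2.5,
                                     rejoin_spot_id = NA_integer_,
                                     frame_interval = 30, seed = 1L,
                                     cell_id = "engage") {
  set.seed(seed)
  ctr <- unlist(grid$centers[grid$centers$spot_id == spot_id, c("x", "y")])
  step <- approach_speed / 60 * frame_interval
  pos <- matrix(NA_real_, n_frames, 2)
  # approach along -x so that the pre-arrest path is unambiguous
  start <- ctr + c(-step * (arrest_frame - 1L), 0)
  for (i in seq_len(n_frames)) {
    if (i < arrest_frame) {
      pos[i, ] <- start + c(step * (i - 1L), 0)
    } else if (is.na(exit_frame) || i < exit_frame) {
      pos[i, ] <- ctr + stats::rnorm(2, 0, jitter_sd)
    } else {
      if (!is.na(rejoin_spot_id)) {
        ctr2 <- unlist(grid$centers[grid$centers$spot_id == rejoin_spot_id,
                                    c("x", "y")])
        k <- i - exit_frame
        travel <- ceiling(sqrt(sum((ctr2 - ctr)^2)) / step)
        if (k >= travel) pos[i, ] <- ctr2 + stats::rnorm(2, 0, jitter_sd)
        else pos[i, ] <- ctr + (ctr2 - ctr) * k / travel
      } else {
        pos[i, ] <- ctr + c(step * (i - exit_frame + 1L), 0)
      }
    }
  }
  arrested <- seq_len(n_frames) >= arrest_frame &
    (is.na(exit_frame) | seq_len(n_frames) < exit_frame)
  ca <- ifelse(arrested, calcium_amplitude, 1) +
    stats::rnorm(n_frames, 0, 0.02)
  area <- ifelse(arrested, 160, 80) + stats::rnorm(n_frames, 0, 2)
  tr <- track(cell_id, frames = 0:(n_frames - 1L), x = pos[, 1], y = pos[, 2],
              channels = list(calcium_ratio = ca, cell_area = area),
              frame_interval = frame_interval)
  list(track = tr,
       truth = list(arrest_frame = arrest_frame, exit_frame = exit_frame,
                    spot_id = spot_id))
}
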