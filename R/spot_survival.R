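# Interaction of tracked cells with stimulatory spot grids: occupancy,
# arrest detection, virtual synchronization around arrest, and half-life of
# interaction from first-order exit kinetics.

#' Per-frame spot occupancy of a track
#'
#' A frame is assigned to a spot iff the centroid lies within the spot radius
#' of that spot's centre. With spacing >= diameter the disks are disjoint, so
#' assignment is unambiguous.
#'
#' @param track An `sk_track`.
#' @param grid An `sk_spot_grid`.
#' @return Integer vector of spot ids, `NA` where the centroid is on no spot.
#' @export
assign_occupancy <- function(track, grid) {
  r <- grid$diameter / 2
  cx <- grid$centers$x; cy <- grid$centers$y
  pos <- track$positions
  vapply(seq_len(nrow(pos)), function(i) {
    d2 <- (pos[i, 1] - cx)^2 + (pos[i, 2] - cy)^2
    j <- which.min(d2)
    if (d2[j] <= r^2) grid$centers$spot_id[j] else NA_integer_
  }, integer(1))
}

#' Detect arrest events of a track on stimulatory spots
#'
#' Arrest is called operationally: a run of at least `dwell` frames during
#' which the cell occupies one spot and its smoothed speed stays below
#' `speed_threshold`. The attach time is the first frame of that run. The
#' cell exits when its centroid stays beyond the spot radius plus a
#' hysteresis margin for at least `dwell` frames (protrusive wobble across
#' the spot edge does not count as leaving); the exit time is the first frame
#' of that excursion. If the movie ends first the record is censored at the
#' last observed time. Later arrests of the same cell (typically on a
#' neighbouring spot) are tallied as re-engagements on the first record and
#' excluded from survival analysis.
#'
#' @param track An `sk_track`.
#' @param grid An `sk_spot_grid`.
#' @param speed_threshold um/min (default 2).
#' @param dwell Frames of sustained occupancy/low speed (default 10 = 5 min).
#' @param hysteresis Extra margin beyond the spot radius, um (default 2).
#' @return Data frame (`sk_interaction_records`): `cell_id`, `spot_id`,
#'   `attach_time` (s), `exit_time` (s; censoring horizon when censored),
#'   `censored`, `re_engagements`. Zero rows when no arrest occurs.
#' @export
detect_arrest <- function(track, grid, speed_threshold = 2, dwell = 10L,
                          hysteresis = 2) {
  occ <- assign_occupancy(track, grid)
  sp <- smoothed_speed(track)
  n <- n_frames(track)
  # arrival-step speed (um/min) at each frame; frame 1 inherits frame 2's
  inst <- c(NA_real_, sqrt(rowSums(diff(track$positions)^2)) /
                      diff(track$times) * 60)
  inst[1L] <- inst[2L]
  r_exit <- grid$diameter / 2 + hysteresis
  recs <- list()
  i <- 1L
  while (i <= n - dwell + 1L) {
    s <- occ[i]
    if (!is.na(s) &&
        !anyNA(occ[i:(i + dwell - 1L)]) &&
        all(occ[i:(i + dwell - 1L)] == s) &&
        all(sp[i:(i + dwell - 1L)] < speed_threshold)) {
      attach_frame <- i
      # the smoothed speed lags the true stop; walk back over occupied
      # frames whose arrival step is already slow
      while (attach_frame > 1L && !is.na(occ[attach_frame - 1L]) &&
             occ[attach_frame - 1L] == s &&
             inst[attach_frame - 1L] < speed_threshold) {
        attach_frame <- attach_frame - 1L
      }
      ctr <- unlist(grid$centers[grid$centers$spot_id == s, c("x", "y")])
      d <- sqrt((track$positions[, 1] - ctr[1])^2 +
                (track$positions[, 2] - ctr[2])^2)
      outside <- d > r_exit
      exit_frame <- NA_integer_
      j <- attach_frame + 1L
      while (j <= n) {
        if (outside[j]) {
          run_end <- min(n, j + dwell - 1L)
          if (all(outside[j:run_end]) &&
              (run_end - j + 1L >= dwell || run_end == n)) {
            exit_frame <- j
            break
          }
        }
        j <- j + 1L
      }
      censored <- is.na(exit_frame)
      exit_time <- if (censored) track$times[n] else track$times[exit_frame]
      recs[[length(recs) + 1L]] <- data.frame(
        cell_id = track$cell_id, spot_id = s,
        attach_time = track$times[attach_frame],
        exit_time = exit_time, censored = censored,
        re_engagements = 0L, stringsAsFactors = FALSE)
      if (censored) break
      i <- exit_frame + dwell  # resume scan after the departure excursion
    } else {
      i <- i + 1L
    }
  }
  if (!length(recs)) {
    out <- data.frame(cell_id = character(), spot_id = integer(),
                      attach_time = numeric(), exit_time = numeric(),
                      censored = logical(), re_engagements = integer(),
                      stringsAsFactors = FALSE)
  } else {
    out <- recs[[1L]]
    out$re_engagements <- length(recs) - 1L
  }
  class(out) <- c("sk_interaction_records", "data.frame")
  out
}

#' Detect arrests across a set of tracks
#'
#' Applies [detect_arrest()] per track and keeps each cell's first record
#' (re-engagements stay tallied, excluded from survival by contract).
#'
#' @param tracks List of `sk_track`.
#' @param grid An `sk_spot_grid`.
#' @param ... Passed to [detect_arrest()].
#' @return Combined `sk_interaction_records` data frame.
#' @export
detect_arrests <- function(tracks, grid, ...) {
  out <- do.call(rbind, lapply(tracks, detect_arrest, grid = grid, ...))
  rownames(out) <- NULL
  class(out) <- c("sk_interaction_records", "data.frame")
  out
}

#' Construct interaction records directly
#'
#' For synthetic residence-time experiments and file import.
#'
#' @param cell_id,spot_id,attach_time,exit_time,censored,re_engagements
#'   Per-record vectors; `exit_time` carries the observation horizon for
#'   censored records.
#' @return `sk_interaction_records` data frame.
#' @export
interaction_records <- function(cell_id, spot_id, attach_time, exit_time,
                                censored = FALSE, re_engagements = 0L) {
  out <- data.frame(cell_id = as.character(cell_id),
                    spot_id = as.integer(spot_id),
                    attach_time = as.numeric(attach_time),
                    exit_time = as.numeric(exit_time),
                    censored = as.logical(censored),
                    re_engagements = as.integer(re_engagements),
                    stringsAsFactors = FALSE)
  bad <- !out$censored & out$exit_time <= out$attach_time
  if (any(bad)) stop("exit_time must exceed attach_time for uncensored records")
  class(out) <- c("sk_interaction_records", "data.frame")
  out
}

#' Half-life from a percent-remaining curve
#'
#' Least squares of `ln(percent)` on time over points with at least one
#' remaining cell; under first-order exit kinetics the half-life is
#' `ln(2)/|slope|`. By default bins are weighted by the inverse sampling
#' variance of `ln(percent)` under binomial tallying, proportional to
#' `S/(1 - S)` for survival fraction S: equal weights let the late, sparse
#' bins -- whose log values fluctuate most -- dominate the fit error.
#' `weights = "equal"` gives the plain unweighted fit; a numeric vector
#' supplies custom weights.
#'
#' @param times_h Bin times, hours.
#' @param percent Percent of initially arrested cells remaining (0-100].
#' @param weights `"ivar"` (default), `"equal"`, or a numeric vector.
#' @return An `sk_survival_fit`: `times`, `percent_remaining`, `ln_percent`,
#'   `slope` (1/h), `r_squared`, `half_life` (h; `Inf` with
#'   `no_decay = TRUE` when the curve does not decay).
#' @export
halflife_from_curve <- function(times_h, percent, weights = "ivar") {
  keep <- is.finite(percent) & percent > 0
  if (sum(keep) < 2L) stop("fewer than 2 usable bins: fit refused")
  x <- times_h[keep]; y <- log(percent[keep])
  w <- if (is.numeric(weights)) weights[keep]
       else if (identical(weights, "equal")) rep(1, sum(keep))
       else percent[keep] / pmax(100 - percent[keep], 2)
  fit <- stats::lm(y ~ x, weights = w)
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  no_decay <- slope >= -1e-12
  structure(list(times = times_h, percent_remaining = percent,
                 ln_percent = ifelse(percent > 0, log(percent), NA_real_),
                 slope = slope, r_squared = r2,
                 half_life = if (no_decay) Inf else log(2) / abs(slope),
                 no_decay = no_decay),
            class = "sk_survival_fit")
}

#' @export
print.sk_survival_fit <- function(x, ...) {
  cat(sprintf(
    "<sk_survival_fit> half-life %s h (slope %.4g /h, R^2 %.3f, %d bins)\n",
    if (is.infinite(x$half_life)) "Inf" else sprintf("%.3g", x$half_life),
    x$slope, x$r_squared, length(x$times)))
  invisible(x)
}

#' Fit first-order exit kinetics to interaction records
#'
#' Tallies the percentage of initially arrested cells still on their original
#' spot at regular time bins (time measured since each cell's own attachment)
#' and fits `ln(percent)` against time with inverse-variance bin weights
#' (see [halflife_from_curve()]). This is the log-linear
#' percent-remaining method, not Kaplan-Meier: a censored cell counts as
#' remaining until its observation horizon and then leaves the tally
#' denominator altogether. Re-engagements are excluded by contract. The
#' percent curve is made non-increasing (running minimum) so late
#' denominator shrinkage cannot raise it.
#'
#' @param records `sk_interaction_records` (>= 5 rows).
#' @param bin Bin width, hours (default 0.25 = 15 min).
#' @param horizon Last bin, hours; default the largest observed
#'   residence/censoring time.
#' @return An `sk_survival_fit` (see [halflife_from_curve()]), plus
#'   `n_records` and `n_censored`.
#' @export
fit_survival <- function(records, bin = 0.25, horizon = NULL) {
  if (nrow(records) < 5L) stop("need at least 5 interaction records")
  res_h <- (records$exit_time - records$attach_time) / 3600
  cen <- records$censored
  if (is.null(horizon)) horizon <- max(res_h)
  tt <- seq(0, horizon, by = bin)
  percent <- vapply(tt, function(t) {
    in_denom <- !cen | res_h >= t
    if (!any(in_denom)) return(NA_real_)
    remaining <- in_denom & (res_h > t | (cen & res_h >= t))
    100 * sum(remaining) / sum(in_denom)
  }, numeric(1))
  percent <- cummin(ifelse(is.na(percent), 0, percent))
  if (all(percent[-1L] >= 100)) {
    fit <- halflife_from_curve(tt, percent)  # no_decay = TRUE path
  } else if (sum(percent > 0) < 2L) {
    stop("all cells exited in the first bin: fit refused")
  } else {
    fit <- halflife_from_curve(tt, percent)
  }
  fit$n_records <- nrow(records)
  fit$n_censored <- sum(cen)
  fit
}

#' Plot a survival fit (ln percent-remaining vs time)
#'
#' @param x An `sk_survival_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sk_survival_fit <- function(x, ...) {
  keep <- is.finite(x$ln_percent)
  graphics::plot(x$times[keep], x$ln_percent[keep],
                 xlab = "time since arrest (h)", ylab = "ln(% remaining)",
                 pch = 16, ...)
  if (!x$no_decay) {
    graphics::abline(stats::lm(x$ln_percent[keep] ~ x$times[keep]),
                     col = "red")
  }
  invisible(x)
}

#' Virtually synchronize per-cell signals around arrest
#'
#' Re-indexes each arrested cell's chosen channel to time since its own
#' attachment and averages across cells at each relative time -- the
#' "virtual synchronization" used to overlay calcium influx, arrest and
#' spreading around spot engagement.
#'
#' @param tracks List of `sk_track` (cells without a record are ignored).
#' @param records `sk_interaction_records` giving each cell's attach time.
#' @param channel Channel name; the special name `"speed"` uses the smoothed
#'   speed (um/min).
#' @param window Seconds before/after arrest to retain (default 300).
#' @return An `sk_aligned_profile`: `channel`, `relative_times` (s),
#'   `mean`, `n` (cells contributing per time), and matrix `traces`
#'   (cells x times).
#' @export
virtual_synchronize <- function(tracks, records, channel, window = 300) {
  if (inherits(tracks, "sk_track")) tracks <- list(tracks)
  ids <- vapply(tracks, function(t) t$cell_id, character(1))
  use <- records[records$cell_id %in% ids, , drop = FALSE]
  if (!nrow(use)) stop("nothing to align: no cells with arrest events")
  dt <- tracks[[1L]]$frame_interval
  rel <- seq(-window, window, by = dt)
  traces <- matrix(NA_real_, nrow = nrow(use), ncol = length(rel),
                   dimnames = list(use$cell_id, NULL))
  for (k in seq_len(nrow(use))) {
    tr <- tracks[[match(use$cell_id[k], ids)]]
    vals <- if (identical(channel, "speed")) smoothed_speed(tr)
            else tr$channels[[channel]]
    if (is.null(vals)) stop("track ", tr$cell_id, " lacks channel ", channel)
    tloc <- tr$times - use$attach_time[k]
    j <- match(round(rel / dt), round(tloc / dt))
    traces[k, !is.na(j)] <- vals[j[!is.na(j)]]
  }
  n_at <- colSums(!is.na(traces))
  structure(list(channel = channel, relative_times = rel,
                 mean = colMeans(traces, na.rm = TRUE), n = n_at,
                 n_cells = nrow(use), traces = traces),
            class = "sk_aligned_profile")
}

#' @export
print.sk_aligned_profile <- function(x, ...) {
  cat(sprintf("<sk_aligned_profile> %s: %d cells, %+d..%+d s around arrest\n",
              x$channel, x$n_cells, min(x$relative_times),
              max(x$relative_times)))
  invisible(x)
}
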