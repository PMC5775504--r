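test_that("estimate_diffusion recovers D on Brownian tracks and bounds", {
  still <- track("s", 0:9, rep(0, 10), rep(0, 10))
  expect_equal(estimate_diffusion(still)$D, 1e-6)  # floored at epsilon
  D <- 0.05
  tr <- simulate_brownian_track(D, n_frames = 2001L, seed = 7)
  expect_lt(abs(estimate_diffusion(tr)$D - D) / D, 0.15)
  # ballistic: MSD = (v tau)^2, the origin-constrained fit upper-bounds D
  v <- 0.1  # um/s
  bal <- track("b", 0:99, v * 30 * (0:99), rep(0, 100))
  msd <- estimate_diffusion(bal)$msd
  expect_equal(msd$msd, (v * msd$tau_s)^2)
  expect_gt(estimate_diffusion(bal)$D, D)
  expect_error(estimate_diffusion(track("t", 0:3, 1:4, 1:4)), "too short")
})

test_that("L transform calibration: L = 3 corresponds to psi = e^-4", {
  # the fixed transform L = -ln(psi) - 1 puts the demarcation threshold at
  # psi = e^-4 ~ 0.0183, i.e. the printed < 0.017 chance bound within rounding
  psi_at_3 <- exp(-(3 + 1))
  expect_equal(psi_at_3, exp(-4))
  expect_lt(abs(psi_at_3 - 0.017), 0.002)
})

test_that("stationary track maxes the confinement score in the interior", {
  tr <- track("s", 0:49, rep(0, 50), rep(0, 50))
  prof <- confinement_score(tr, estimate_diffusion(tr))
  interior <- 16:35  # all windows fit here
  expect_true(all(prof$L[interior] == 10))  # L_max cap via the psi floor
  expect_true(all(prof$L >= 0))
  expect_true(all(prof$psi > 0 & prof$psi <= 1))
})

test_that("confinement psi matches Monte-Carlo stay-probability in regime", {
  # calibrated regime: D t / r^2 <= ~0.8 (psi above the ~0.015 decision
  # scale); the relation is a continuous-diffusion asymptotic, so the oracle
  # samples Brownian motion finely within the window
  D <- 0.02; w <- 20L; t_w <- (w - 1L) * 30
  for (x in c(0.1, 0.3, 0.5, 0.6)) {
    r <- sqrt(D * t_w / x)
    psi_formula <- 10^(0.2048 - 2.5117 * x)
    psi_mc <- oracle_stay_probability(D, t_w, r, n_rep = 8000L,
                                      seed = round(1000 * x))
    expect_lt(abs(psi_formula - psi_mc) / psi_mc, 0.30)
  }
})

test_that("demarcation finds planted runs and respects min_duration", {
  tr <- simulate_brownian_track(0.02, n_frames = 100L, seed = 1)
  prof <- confinement_score(tr, estimate_diffusion(tr))
  prof$L <- rep(0, 100)
  expect_equal(nrow(demarcate_confined_periods(tr, prof)), 0L)
  prof$L[31:70] <- 5
  per <- demarcate_confined_periods(tr, prof, edge_correction = FALSE)
  expect_equal(nrow(per), 1L)
  expect_equal(c(per$start_frame, per$end_frame), c(31L, 70L))
  expect_equal(per$t, 40L)
  prof$L <- rep(0, 100); prof$L[11:15] <- 5  # shorter than min_duration
  expect_equal(nrow(demarcate_confined_periods(tr, prof)), 0L)
})

test_that("planted confined bout is detected with >= 80% frame overlap", {
  # hand-build one kinapse-synapse-kinapse sandwich: 60-frame confined bout
  sim_k <- simulate_two_state_track(
    two_state_params(dwell_synapse = 30, dwell_kinapse = 1e9,
                     frame_interval = 30, n_frames = 240, seed = 11))
  expect_true(all(sim_k$truth$state[-1] == "kinapse"))
  pos <- sim_k$track$positions
  set.seed(12)
  bout <- 91:150
  anchor <- pos[90, ]
  conf <- matrix(anchor, nrow = 60, ncol = 2, byrow = TRUE) +
    matrix(rnorm(120, 0, 0.3), ncol = 2)
  pos[bout, ] <- conf
  shift <- pos[150, ] - sim_k$track$positions[150, ]
  pos[151:240, ] <- sweep(sim_k$track$positions[151:240, , drop = FALSE],
                          2, -shift)
  tr <- track("planted", 0:239, pos[, 1], pos[, 2])
  res <- classify_track(tr)
  detected <- logical(240)
  for (k in seq_len(nrow(res$periods))) {
    detected[res$periods$start_frame[k]:res$periods$end_frame[k]] <- TRUE
  }
  expect_gte(sum(detected[bout]) / 60, 0.80)
})

test_that("classify_stability applies the 0.666 um^2/frame threshold", {
  per <- data.frame(start_frame = c(1L, 50L, 100L), end_frame = c(30L, 79L, 129L),
                    t = c(30L, 30L, 30L), R = c(4, 0, 5))
  per$spread <- per$R^2 / per$t
  out <- classify_stability(per)
  expect_equal(out$stable, c(TRUE, TRUE, FALSE))  # 0.533, 0, 0.833
  expect_equal(out$spread[1], 16 / 30)
})

test_that("positional stability index counts stable-frame fraction", {
  tr <- simulate_brownian_track(0.02, n_frames = 60L, seed = 2)
  all_per <- data.frame(start_frame = 1L, end_frame = 60L, t = 60L,
                        R = 1, spread = 1 / 60, stable = TRUE)
  expect_equal(positional_stability_index(tr, all_per)$psi_index, 1)
  none <- all_per[0, ]
  cls <- positional_stability_index(tr, none)
  expect_equal(cls$psi_index, 0)
  expect_true(all(cls$state == "motile_kinapse"))
  half <- data.frame(start_frame = 1L, end_frame = 30L, t = 30L,
                     R = 1, spread = 1 / 30, stable = TRUE)
  expect_equal(positional_stability_index(tr, half)$psi_index, 0.5)
})

test_that("two-state recovery: cohort PSI within 0.15 of realized truth", {
  for (f in c(0.3, 0.7)) {
    sims <- lapply(1:6, function(s) simulate_two_state_track(
      two_state_params(dwell_synapse = f * 3600,
                       dwell_kinapse = (1 - f) * 3600,
                       seed = 500L + 10L * round(10 * f) + s)))
    truth <- mean(vapply(sims, function(x) x$truth$stable_fraction, 1))
    tab <- psi_table(lapply(sims, `[[`, "track"))
    expect_lt(abs(mean(tab$psi_index) - truth), 0.15)
  }
})

test_that("threshold monotonicity properties hold", {
  sim <- simulate_two_state_track(two_state_params(seed = 21))
  tr <- sim$track
  motion <- estimate_diffusion(tr)
  prof <- confinement_score(tr, motion)
  confined_time <- function(Lth) {
    per <- demarcate_confined_periods(tr, prof, L_threshold = Lth)
    if (!nrow(per)) 0L else sum(per$t)
  }
  psi_at <- function(sth) {
    per <- demarcate_confined_periods(tr, prof)
    positional_stability_index(tr, classify_stability(per, sth))$psi_index
  }
  # raising L threshold can only shrink total confined time
  times <- vapply(c(2, 3, 5, 8), confined_time, 1L)
  expect_true(all(diff(times) <= 0))
  # lowering the spread threshold can only decrease the PSI
  psis <- vapply(c(1.5, 0.666, 0.3, 0.1), psi_at, 1)
  expect_true(all(diff(psis) <= 0))
})

test_that("longer synapse dwell raises mean PSI (kinase-inhibition analogue)", {
  mean_psi <- function(dwell_syn, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_two_state_track(
        two_state_params(dwell_synapse = dwell_syn, dwell_kinapse = 900,
                         seed = s))
      classify_track(sim$track)$classification$psi_index
    }, 1))
  }
  expect_gt(mean_psi(2700, 1:5), mean_psi(450, 1:5))
})

test_that("arrest coefficient is the sub-threshold frame fraction", {
  tr <- constant_velocity_track(6, n = 20)
  expect_equal(arrest_coefficient(tr, speed_threshold = 2), 0)
  expect_equal(arrest_coefficient(tr, speed_threshold = 10), 1)
})
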