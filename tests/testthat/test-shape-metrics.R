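test_that("sampling efficiency forced values are exact", {
  still <- track("s", 0:29, rep(15, 30), rep(15, 30))
  ms <- render_mask_movie(still, cell_radius = 4, pixel_size = 0.5,
                          extent = c(30, 30))
  se <- sampling_efficiency(ms, n_steps = 20L)
  expect_equal(se$mean_efficiency, 1 / 20)
  # pairwise-disjoint footprints: small squares marching across the raster
  masks <- lapply(1:20, function(i) {
    m <- matrix(FALSE, 10, 80)
    m[4:6, (4 * i - 3):(4 * i - 1)] <- TRUE
    m
  })
  msd <- mask_series(0:19, masks, pixel_size = 1)
  expect_equal(sampling_efficiency(msd, n_steps = 20L)$mean_efficiency, 1)
})

test_that("sampling efficiency equals brute-force pixel-set arithmetic", {
  set.seed(6)
  tr <- track("w", 0:24, 12 + cumsum(rnorm(25, 0, 1.5)),
              12 + cumsum(rnorm(25, 0, 1.5)))
  ms <- render_mask_movie(tr, cell_radius = 3, pixel_size = 1,
                          extent = c(-20, -20, 44, 44))
  se <- sampling_efficiency(ms, n_steps = 10L)
  for (row in sample(nrow(se$windows), 3)) {
    s <- which(ms$frames == se$windows$start_frame[row])
    idx <- s:(s + 9L)
    expect_equal(se$windows$unique_pixels[row],
                 oracle_union_count(ms$masks[idx]))
    expect_equal(se$windows$total_pixels[row],
                 sum(vapply(ms$masks[idx], sum, 1)))
  }
})

test_that("windows containing empty masks are skipped", {
  masks <- lapply(1:12, function(i) {
    m <- matrix(FALSE, 8, 8); if (i != 6) m[3:5, 3:5] <- TRUE; m
  })
  ms <- mask_series(0:11, masks, 1)
  se <- sampling_efficiency(ms, n_steps = 5L)
  expect_true(length(se$skipped) == 5L)  # every window covering frame 6
  expect_error(sampling_efficiency(ms, n_steps = 12L), "empty")
})

test_that("protrusion index forced values follow the overlap definitions", {
  g <- build_spot_grid(10, 30, c(40, 40))
  ctr <- g$centers[1, ]
  # cell disk radius 3 wholly inside the 10-um spot
  inside <- track("in", 0:4, rep(ctr$x, 5), rep(ctr$y, 5))
  ms_in <- render_mask_movie(inside, 3, 0.25, c(0, 0, 40, 40))
  pm <- protrusion_index(ms_in, g, ctr$spot_id)
  expect_true(all(pm$fractional_overlap == 1))
  expect_true(all(pm$max_possible_overlap == 1))
  expect_true(all(pm$protrusion_index == 0))
  # same cell wholly outside the spot
  outside <- track("out", 0:4, rep(ctr$x + 15, 5), rep(ctr$y, 5))
  ms_out <- render_mask_movie(outside, 3, 0.25, c(0, 0, 40, 40))
  pm_out <- protrusion_index(ms_out, g, ctr$spot_id)
  expect_true(all(pm_out$fractional_overlap == 0))
  expect_true(all(pm_out$protrusion_index == 1))
  # a cell twice the spot area fully covering the spot: f = m = 0.5
  spot_px <- rasterize_spot(g, ctr$spot_id, c(160, 160), 0.25)
  big <- matrix(FALSE, 160, 160)
  ord <- order((row(big) - ctr$y / 0.25 - 1)^2 + (col(big) - ctr$x / 0.25 - 1)^2)
  big[ord[seq_len(2 * sum(spot_px))]] <- TRUE  # concentric, covers the spot
  ms_big <- mask_series(0L, list(big), 0.25)
  pm_big <- protrusion_index(ms_big, g, ctr$spot_id)
  expect_equal(pm_big$fractional_overlap, 0.5)
  expect_equal(pm_big$max_possible_overlap, 0.5)
  expect_equal(pm_big$protrusion_index, 0)
})

test_that("overlap areas equal brute-force set arithmetic on small rasters", {
  set.seed(8)
  g <- build_spot_grid(10, 30, c(32, 32))
  tr <- track("w", 0:9, 16 + cumsum(rnorm(10, 0, 2)),
              16 + cumsum(rnorm(10, 0, 2)))
  ms <- render_mask_movie(tr, 4, 0.5, c(0, 0, 31.5, 31.5))  # 64x64 raster
  spot <- rasterize_spot(g, 1, dim(ms$masks[[1]]), 0.5, ms$origin)
  pm <- protrusion_index(ms, g, 1)
  for (i in seq_len(10)) {
    expect_equal(pm$overlap_area_um2[i] / 0.25,
                 oracle_overlap_count(ms$masks[[i]], spot))
  }
})

test_that("protrusion index invariants and monotonicity in distance", {
  g <- build_spot_grid(10, 30, c(40, 40))
  ctr <- g$centers[1, ]
  dists <- c(0, 2, 4, 6, 9, 14)
  pis <- vapply(dists, function(d) {
    tr <- track("d", 0L, ctr$x + d, ctr$y)
    ms <- render_mask_movie(tr, 4, 0.25, c(-20, -20, 60, 60))
    pm <- protrusion_index(ms, g, ctr$spot_id)
    expect_true(pm$fractional_overlap <= pm$max_possible_overlap + 1e-12)
    expect_true(pm$protrusion_index >= 0 && pm$protrusion_index <= 1)
    pm$protrusion_index
  }, 1)
  expect_true(all(diff(pis) >= 0))
})

test_that("resolution stability: halving pixel size moves metrics < 2%", {
  set.seed(10)
  tr <- track("r", 0:24, 20 + cumsum(rnorm(25, 0, 1)),
              20 + cumsum(rnorm(25, 0, 1)))
  g <- build_spot_grid(10, 30, c(40, 40))
  vals <- lapply(c(0.5, 0.25), function(px) {
    ms <- render_mask_movie(tr, 5, px, c(-10, -10, 50, 50))
    c(se = sampling_efficiency(ms, 20L)$mean_efficiency,
      pi = mean(protrusion_index(ms, g, 1)$protrusion_index))
  })
  expect_lt(abs(vals[[1]]["se"] - vals[[2]]["se"]) / vals[[2]]["se"], 0.02)
  expect_lt(abs(vals[[1]]["pi"] - vals[[2]]["pi"]), 0.02)
})

test_that("overlap contour pools points under the m trace", {
  g <- build_spot_grid(10, 30, c(40, 40))
  ctr <- g$centers[1, ]
  still <- track("a", 0:3, rep(ctr$x, 4), rep(ctr$y, 4))
  ms <- render_mask_movie(still, 3, 0.25, c(0, 0, 40, 40))
  pm <- protrusion_index(ms, g, 1)
  oc <- overlap_contour(list(pm, pm))
  # all mass at area ratio <= 1, f = 1
  nz <- which(oc$density > 0, arr.ind = TRUE)
  expect_true(all(oc$ratio_mid[nz[, 1]] <= 1))
  expect_true(all(oc$f_mid[nz[, 2]] > 0.95))
  # boundary trace values
  expect_equal(oc$trace$m[abs(oc$trace$area_ratio - 0.55) < 0.01], 1)
  tr2 <- oc$trace$m[abs(oc$trace$area_ratio - 1.95) < 0.01]
  expect_equal(tr2, 1 / 1.95)
})

test_that("motile synthetic cells sample more and protrude more", {
  g <- build_spot_grid(10, 30, c(90, 90))
  ctr <- g$centers[6, ]
  make <- function(step_sd, seed) {
    set.seed(seed)
    tr <- track(paste0("m", seed, step_sd), 0:39,
                ctr$x + cumsum(rnorm(40, 0, step_sd)),
                ctr$y + cumsum(rnorm(40, 0, step_sd)))
    render_mask_movie(tr, 4.5, 0.5, c(ctr$x - 40, ctr$y - 40,
                                      ctr$x + 40, ctr$y + 40))
  }
  confined <- make(0.15, 1); motile <- make(1.2, 1)
  expect_gt(sampling_efficiency(motile, 20L)$mean_efficiency,
            sampling_efficiency(confined, 20L)$mean_efficiency)
  expect_gt(mean(protrusion_index(motile, g, 6)$protrusion_index),
            mean(protrusion_index(confined, g, 6)$protrusion_index))
})
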