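test_that("time-lapse generator is deterministic and conserves cell counts", {
  p <- timelapse_params(n_cells = 15, field_size = c(192, 192),
                        hazard_per_group = c(control = 0.12, high = 0.04),
                        seed = 7)
  sim1 <- sim_timelapse(p)
  sim2 <- sim_timelapse(p)
  expect_identical(sim1$truth, sim2$truth)
  expect_identical(sim1$frames$control[[2]]$channels,
                   sim2$frames$control[[2]]$channels)
  expect_equal(nrow(sim1$truth), 30)
  expect_true(all(sim1$truth$row >= 1 & sim1$truth$row <= 192))
  expect_true(all(sim1$truth$col >= 1 & sim1$truth$col <= 192))
  # death precedes (or equals start of) detachment wherever both exist
  both <- !is.na(sim1$truth$detach_time_h)
  expect_true(all(sim1$truth$death_time_h[both] <=
                    sim1$truth$detach_time_h[both]))
})

test_that("empty and degenerate time-lapse cases behave", {
  p0 <- timelapse_params(n_cells = 0, field_size = c(96, 96),
                         hazard_per_group = c(control = 0.1), seed = 1)
  sim <- sim_timelapse(p0)
  expect_equal(nrow(sim$truth), 0)
  fr <- sim$frames$control[[1]]
  # background + noise only: nothing near a cell's brightness
  expect_lt(max(get_channel(fr, "red")), 200)
  expect_error(timelapse_params(timepoints_h = c(6, 6, 12)), "increasing")
  expect_error(timelapse_params(field_size = c(0, 64)), "positive")
  expect_error(timelapse_params(r_live = 1.8, r_dead = 0.5), "r_dead")
})

test_that("green channel tracks red times the live/dead ratio", {
  p <- timelapse_params(n_cells = 8, field_size = c(192, 192),
                        hazard_per_group = c(control = 0.25),
                        noise_sigma = 0, jitter_px = 0, detach_prob = 0,
                        seed = 3)
  sim <- sim_timelapse(p)
  tr <- sim$truth
  for (ti in c(1, 4)) {
    fr <- sim$frames$control[[ti]]
    red <- get_channel(fr, "red")
    green <- get_channel(fr, "green")
    t <- fr$timepoint
    for (i in seq_len(nrow(tr))) {
      rr <- round(tr$row[i])
      cc <- round(tr$col[i])
      expected_r <- if (t < tr$death_time_h[i]) 0.5 else 1.8
      meas <- (green[rr, cc] - 100) / (red[rr, cc] - 100)
      expect_equal(meas, expected_r, tolerance = 1e-6)
    }
  }
})

test_that("higher hazard gives lower true survival at every timepoint", {
  p <- timelapse_params(n_cells = 200, field_size = c(768, 768),
                        hazard_per_group = c(control = 0.12, treated = 0.04),
                        seed = 21)
  sim <- sim_timelapse(p)
  tr <- sim$truth
  for (t in c(6, 12, 18)) {
    s_ctrl <- mean(tr$death_time_h[tr$group == "control"] > t)
    s_trt <- mean(tr$death_time_h[tr$group == "treated"] > t)
    expect_lt(s_ctrl, s_trt)
  }
})

test_that("death times follow the specified exponential hazard", {
  sim <- sim_fate_tracks(1000, c(g = 0.1), schedule = c(0, 6),
                         detach_prob = 0, seed = 99)
  d <- sim$truth$death_time_h
  ks <- stats::ks.test(d, "pexp", rate = 0.1)
  expect_gt(ks$p.value, 0.01)
})

test_that("foci generator matches its Poisson specification", {
  sim0 <- sim_foci_stack(n_cells = 12, lambda = 0, field_size = c(256, 256),
                         seed = 2)
  expect_true(all(sim0$truth$n_foci == 0))
  expect_equal(nrow(sim0$foci), 0)
  # with cells but no foci, green stays near diffuse level (< 2x level)
  expect_lt(max(get_channel(sim0$frame, "green")),
            2 * max(sim0$truth$cell_level))

  sim <- sim_foci_stack(n_cells = 100, lambda = 5, seed = 4)
  expect_equal(nrow(sim$truth), 100)
  se <- sqrt(5 / 100)
  expect_lt(abs(mean(sim$truth$n_foci) - 5), 3 * se)
  expect_equal(sum(sim$truth$n_foci), nrow(sim$foci))

  # focus peak pixels reach >= 10x the per-cell diffuse level by construction
  simf <- sim_foci_stack(n_cells = 6, lambda = 3, field_size = c(256, 256),
                         foci_intensity_factor = 20, noise_sigma = 0,
                         seed = 6)
  g <- get_channel(simf$frame, "green")
  lev <- setNames(simf$truth$cell_level, simf$truth$cell_id)
  for (k in seq_len(nrow(simf$foci))) {
    r <- round(simf$foci$row[k])
    c <- round(simf$foci$col[k])
    peak <- max(g[(r - 1):(r + 1), (c - 1):(c + 1)])
    expect_gte(peak, 10 * lev[[simf$foci$cell_id[k]]])
  }
  expect_error(sim_foci_stack(foci_intensity_factor = 1), "undetectable")
})

test_that("colony generator produces the requested geometry", {
  empty <- sim_colony_image(n_colonies = 0, seed = 1)
  expect_equal(nrow(empty$truth), 0)
  expect_lt(diff(range(empty$image)), 50)

  sim <- sim_colony_image(n_colonies = 3, field_size = c(256, 256),
                          noise_sigma = 0, seed = 5)
  expect_equal(nrow(sim$truth), 3)
  expect_false(any(sim$truth$overlaps))

  ov <- sim_colony_image(n_colonies = 2, field_size = c(128, 128),
                         radius_range = c(30, 30), allow_overlap = TRUE,
                         noise_sigma = 0, seed = 14)
  expect_equal(nrow(ov$truth), 2)
  d <- sqrt(diff(ov$truth$row)^2 + diff(ov$truth$col)^2)
  if (d <= sum(ov$truth$radius_px) + 2) {
    expect_true(all(ov$truth$overlaps))
  }
  expect_error(sim_colony_image(radius_range = c(300, 400),
                                field_size = c(128, 128)), "exceed")
})

test_that("flow generator produces separated populations and a debris cluster", {
  all_un <- sim_flow_events(2000, stained_fraction = 0, seed = 2)
  expect_true(all(all_un$truth$label %in% c("unstained", "debris")))

  sim <- sim_flow_events(20000, stained_fraction = 0.5, shift_factor = 100,
                         seed = 3)
  expect_equal(nrow(sim$events), 20000)
  lf <- log10(sim$events$fluor)
  dens <- stats::density(lf)
  # two well-separated fluorescence modes: high density mass near log10(100)
  # and near log10(100 * 100), low density in between
  mid <- mean(dens$y[dens$x > 2.5 & dens$x < 3.5])
  lo_mode <- max(dens$y[dens$x < 2.5])
  hi_mode <- max(dens$y[dens$x > 3.5])
  expect_gt(lo_mode, 5 * mid)
  expect_gt(hi_mode, 5 * mid)

  # division peaks at shift, shift/2, shift/4
  div <- sim_flow_events(30000, stained_fraction = 1, shift_factor = 100,
                         division_peaks = 3, debris_fraction = 0, seed = 8)
  med <- tapply(div$events$fluor, div$truth$division, median)
  expect_equal(unname(med[["2"]] / med[["1"]]), 0.5, tolerance = 0.05)
  expect_equal(unname(med[["3"]] / med[["1"]]), 0.25, tolerance = 0.05)

  expect_error(sim_flow_events(0), "positive")
})

test_that("OCR trace generator encodes the four phases and truth metrics", {
  noiseless <- sim_ocr_trace(100, 40, 180, 20, noise_sigma = 0, seed = 1)
  expect_equal(unique(noiseless$trace$ocr[noiseless$trace$phase == "basal"]),
               100)
  expect_equal(unique(noiseless$trace$ocr[noiseless$trace$phase == "fccp"]),
               180)
  expect_equal(noiseless$truth$spare_pct, 100)
  flat <- sim_ocr_trace(100, 40, 100, 20, noise_sigma = 0, seed = 1)
  expect_equal(flat$truth$spare_pct, 0)
  expect_error(sim_ocr_trace(100, 40, 180, 20, n_per_phase = 0), "at least")
  expect_error(sim_ocr_trace(50, 40, 180, 60), "basal_ocr")
})

test_that("tiff round trip preserves the series within storage precision", {
  p <- timelapse_params(n_cells = 5, field_size = c(96, 96),
                        hazard_per_group = c(control = 0.1), seed = 9)
  sim <- sim_timelapse(p)
  path <- withr::local_tempfile(fileext = ".tif")
  write_timelapse_tiff(sim$frames$control, path)
  back <- read_timelapse_tiff(path)
  expect_equal(length(back), 4)
  expect_equal(back[[2]]$timepoint, 6)
  expect_equal(names(back[[1]]$channels), c("red", "green"))
  expect_equal(back[[3]]$channels$red,
               sim$frames$control[[3]]$channels$red,
               tolerance = 1e-6)
})
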