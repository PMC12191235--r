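test_that("viability normalization matches the blank/control formula", {
  expect_equal(normalize_viability(1100, 100, 1100), 100)
  expect_equal(normalize_viability(100, 100, 1100), 0)
  expect_equal(normalize_viability(600, 100, 1100), 50)
  # replicates averaged before normalization
  expect_equal(normalize_viability(c(500, 700), c(90, 110), c(1000, 1200)),
               50)
  expect_error(normalize_viability(500, 1100, 1000), "assay failed")
})

test_that("viability is invariant to affine luminometer rescaling", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      tr <- runif(3, 200, 900)
      bl <- runif(3, 50, 150)
      z <- runif(3, 1000, 1500)
      gain <- runif(1, 0.5, 4)
      offset <- runif(1, -50, 200)
    })
    expect_equal(
      normalize_viability(gain * tr + offset, gain * bl + offset,
                          gain * z + offset),
      normalize_viability(tr, bl, z),
      tolerance = 1e-10
    )
  }
})

test_that("plate-level viability table normalizes each group", {
  plate <- tibble::tibble(
    group = rep(c("blank", "0Gy", "10Gy", "10Gy+sEV"), each = 2),
    lum = c(100, 100, 1050, 1150, 580, 620, 840, 860)
  )
  vt <- viability_table(plate, blank = "blank", reference = "0Gy")
  expect_equal(vt$viability_pct[vt$group == "0Gy"], 100)
  expect_equal(vt$viability_pct[vt$group == "10Gy"], 50)
  expect_equal(vt$viability_pct[vt$group == "10Gy+sEV"], 75)
  expect_error(viability_table(plate, blank = "nope"), "blank")
})

test_that("colony quantification counts disjoint colonies and flags merges", {
  blank <- matrix(50, 256, 256) + matrix(abs(rnorm(256^2, 0, 2)), 256)
  expect_equal(nrow(quantify_colonies(blank)), 0)

  sim <- sim_colony_image(n_colonies = 3, field_size = c(384, 384),
                          radius_range = c(12, 18), noise_sigma = 2,
                          seed = 7)
  col <- quantify_colonies(sim$image)
  expect_equal(nrow(col), 3)
  hits <- match_to_truth(col$row, col$col, sim$truth$row, sim$truth$col,
                         max_dist = 6)
  expect_false(any(is.na(hits)))
  expect_lt(max(abs(col$area_px - sim$truth$area_px[hits]) /
                  sim$truth$area_px[hits]), 0.05)
  expect_false(any(col$flag_merged))

  # per-seed exact counts on disjoint colonies
  for (seed in c(2, 9, 15)) {
    s <- sim_colony_image(n_colonies = 8, field_size = c(448, 448),
                          seed = seed)
    expect_equal(nrow(quantify_colonies(s$image)), 8)
  }

  # two touching discs merge into one flagged object
  img <- matrix(50, 256, 256)
  img <- radassay:::add_disc(img, 120, 110, 25, 500)
  img <- radassay:::add_disc(img, 120, 156, 25, 500)
  merged <- quantify_colonies(img)
  expect_equal(nrow(merged), 1)
  expect_true(merged$flag_merged)
  # micron conversion when pixel size is known
  withpx <- quantify_colonies(img, pixel_size = 0.65)
  expect_equal(withpx$area_um2, withpx$area_px * 0.65^2)
})

test_that("singlet gating removes the debris cluster, keeps cells", {
  sim <- sim_flow_events(20000, stained_fraction = 0.5,
                         debris_fraction = 0.1, seed = 12)
  ev <- dplyr::mutate(sim$events, label = sim$truth$label)
  gated <- gate_singlets(ev)
  expect_lt(mean(gated$label == "debris"), 0.01)
  kept_cells <- sum(gated$label != "debris") /
    sum(ev$label != "debris")
  expect_gte(kept_cells, 0.99)

  clean <- tibble::tibble(fsc = c(4e4, 6e4), ssc = c(2e4, 3e4))
  expect_identical(gate_singlets(clean), clean)
  expect_error(gate_singlets(clean[0, ]), "empty")
})

test_that("positivity gating follows the unstained-reference percentile", {
  ref <- sim_flow_events(20000, stained_fraction = 0, seed = 3)$events
  ref <- gate_singlets(ref)
  # events identical to the reference: positive fraction = 1 - percentile
  self <- gate_positive(ref, ref, percentile = 99)
  expect_equal(self$positive_fraction, 0.01, tolerance = 0.25)

  sim <- sim_flow_events(20000, stained_fraction = 0.5, shift_factor = 100,
                         seed = 4)
  ev <- gate_singlets(dplyr::mutate(sim$events, label = sim$truth$label))
  pos <- gate_positive(ev, ref)
  true_frac <- mean(ev$label == "stained")
  expect_lt(abs(pos$positive_fraction - true_frac), 0.02)

  const <- tibble::tibble(fluor = rep(420, 50))
  expect_equal(gate_positive(const, ref)$mfi_all, 420)
  geo <- gate_positive(ev, ref, mfi = "geometric")
  expect_lt(geo$mfi_all, pos$mfi_all) # geometric mean below arithmetic
  expect_error(gate_positive(ev, ref[0, ]), "empty unstained")
})

test_that("positive fraction is invariant to a common gain", {
  ref <- gate_singlets(sim_flow_events(10000, stained_fraction = 0,
                                       seed = 5)$events)
  ev <- gate_singlets(sim_flow_events(10000, stained_fraction = 0.4,
                                      seed = 6)$events)
  base <- gate_positive(ev, ref)
  for (k in c(0.3, 2, 11)) {
    sc <- gate_positive(dplyr::mutate(ev, fluor = fluor * k),
                        dplyr::mutate(ref, fluor = fluor * k))
    expect_equal(sc$positive_fraction, base$positive_fraction)
    expect_equal(sc$mfi_all, k * base$mfi_all, tolerance = 1e-12)
  }
})

test_that("sEV dosing arithmetic reproduces the published dose levels", {
  expect_equal(sev_dose(1e8, 1, 2e4), 5000)
  expect_equal(sev_dose(2.5e7, 1, 1e4), 2500)
  expect_equal(sev_dose(1.5e9, 1, 1e5), 15000)
  expect_equal(sev_dose(0, 1, 1e4), 0)
  # concentration x volume form
  expect_equal(sev_dose(2e8, 0.5, 2e4), 5000)
  expect_error(sev_dose(1e8, 1, 0), "positive")
})

test_that("stress-test metrics recover truth and reject invalid traces", {
  sim <- sim_ocr_trace(100, 40, 180, 20, noise_sigma = 0, seed = 1)
  m <- seahorse_metrics(sim$trace)
  expect_equal(m$basal_resp, 80)
  expect_equal(m$maximal_resp, 160)
  expect_equal(m$spare_abs, 80)
  expect_equal(m$spare_pct, 100)
  expect_equal(m$spare_pct, sim$truth$spare_pct)

  flat <- sim_ocr_trace(100, 40, 100, 20, noise_sigma = 0, seed = 1)
  expect_equal(seahorse_metrics(flat$trace)$spare_pct, 0)

  # noisy traces recover truth within sampling error
  for (seed in c(3, 8)) {
    noisy <- sim_ocr_trace(100, 40, 180, 20, n_per_phase = 6,
                           noise_sigma = 3, seed = seed)
    mn <- seahorse_metrics(noisy$trace)
    expect_lt(abs(mn$basal_resp - 80), 3 * 3 / sqrt(6) + 3 * 3)
    expect_lt(abs(mn$spare_pct - 100), 25)
  }

  bad <- sim_ocr_trace(100, 40, 180, 20, noise_sigma = 0, seed = 1)$trace
  bad$ocr[bad$phase == "rot_aa"] <- 150
  expect_error(seahorse_metrics(bad), "trace invalid")
  expect_error(seahorse_metrics(bad[bad$phase != "fccp", ]), "phases")
})
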