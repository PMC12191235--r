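make_cell <- function(size = 64, interior = 10, from = 10, to = 54) {
  img <- matrix(interior, size, size)
  lab <- matrix(0L, size, size)
  lab[from:to, from:to] <- 1L
  list(img = img, lab = lab)
}

test_that("per-cell background is the trimmed in-mask median", {
  cl <- make_cell()
  bg <- estimate_background(cl$img, cl$lab)
  expect_equal(bg$background, 10)

  # 2% of in-mask pixels at 200 do not move the trimmed median
  bright <- cl$img
  idx <- which(cl$lab == 1L)
  bright[idx[seq_len(round(0.02 * length(idx)))]] <- 200
  expect_equal(estimate_background(bright, cl$lab)$background, 10)

  expect_error(estimate_background(cl$img, matrix(0L, 64, 64)), "empty mask")
})

test_that("the order-of-magnitude contrast rule accepts 20x and rejects 5x", {
  cl <- make_cell()
  spot20 <- cl$img
  spot20[30:31, 30:31] <- 200 # 20x background
  expect_equal(detect_foci(spot20, cl$lab)$count, 1)

  spot5 <- cl$img
  spot5[30:31, 30:31] <- 50 # 5x background: below an order of magnitude
  expect_equal(detect_foci(spot5, cl$lab)$count, 0)

  # punctum metadata: centroid, area, contrast
  rec <- detect_foci(spot20, cl$lab)
  p <- rec$puncta[[1]]
  expect_equal(nrow(p), 1)
  expect_equal(p$area, 4)
  expect_equal(p$row, 30.5)
  expect_equal(p$contrast, 20)

  # area bounds reject hot pixels and saturated patches
  hot <- cl$img
  hot[30, 30] <- 500
  expect_equal(detect_foci(hot, cl$lab, min_punctum_area_px = 2)$count, 0)
  big <- cl$img
  big[20:40, 20:40] <- 200
  expect_equal(detect_foci(big, cl$lab, max_punctum_area_px = 50)$count, 0)

  expect_error(detect_foci(cl$img, matrix(0L, 64, 64)), "no compartments")
  expect_error(detect_foci(cl$img, cl$lab, contrast_factor = 1), "> 1")
})

test_that("counts are gain-invariant and monotone in the contrast factor", {
  # well-separated foci (9 px apart) so candidate regions stay disjoint even
  # at permissive contrast factors; merging of overlapping candidate regions
  # is a documented limitation of threshold-based counting
  sim <- sim_foci_stack(n_cells = 15, lambda = 2, field_size = c(448, 448),
                        nucleus_radius_px = 20, min_focus_sep_px = 9,
                        seed = 23)
  nuc <- segment_nuclei(sim$frame)
  g <- get_channel(sim$frame, "green")
  base <- detect_foci(g, nuc)
  scaled <- detect_foci(3.7 * g, nuc)
  expect_equal(scaled$count, base$count)

  prev <- NULL
  for (cf in c(25, 15, 10, 5, 2)) {
    cur <- detect_foci(g, nuc, contrast_factor = cf)$count
    if (!is.null(prev)) expect_true(all(cur >= prev))
    prev <- cur
  }
  # contrast factor beyond any pixel: zero everywhere
  none <- detect_foci(g, nuc, contrast_factor = 1e9)
  expect_true(all(none$count == 0))
})

test_that("detection recovers Poisson truth with small error at default SNR", {
  sim <- sim_foci_stack(n_cells = 100, lambda = 5, seed = 5)
  nuc <- segment_nuclei(sim$frame)
  rec <- detect_foci(get_channel(sim$frame, "green"), nuc)
  hits <- match_to_truth(nuc$objects$row, nuc$objects$col,
                         sim$truth$row, sim$truth$col)
  expect_false(any(is.na(hits)))
  mae <- mean(abs(rec$count - sim$truth$n_foci[hits]))
  expect_lte(mae, 0.5)
})

test_that("gamma-H2AX and 53BP1 paths agree given the same compartments", {
  # same stack counted against nuclear masks vs cell masks derived from the
  # same geometry: the operator chain is identical, only compartments differ
  sim <- sim_foci_stack(n_cells = 15, lambda = 3, field_size = c(320, 320),
                        seed = 12)
  g <- get_channel(sim$frame, "green")
  nuc <- segment_nuclei(sim$frame)
  rec_dapi <- detect_foci(g, nuc, marker = "gH2AX")
  rec_live <- detect_foci(g, nuc$labels, marker = "53BP1")
  expect_equal(rec_dapi$count, rec_live$count)
  expect_equal(rec_dapi$marker[1], "gH2AX")
  expect_equal(rec_live$marker[1], "53BP1")
})

test_that("timecourse summaries preserve counts and flag n=1 strata", {
  one <- tibble::tibble(group = "g", timepoint = 0, count = 3)
  s1 <- foci_timecourse(one)
  expect_equal(s1$mean_count, 3)
  expect_true(is.na(s1$sem))

  two <- tibble::tibble(group = "g", timepoint = 3, count = c(2, 4))
  s2 <- foci_timecourse(two)
  expect_equal(s2$mean_count, 3)
  expect_equal(s2$sem, 1)

  sim <- sim_foci_stack(n_cells = 120, lambda = c(lo = 2, hi = 6),
                        field_size = c(768, 768), seed = 9)
  rec <- dplyr::mutate(sim$truth, count = n_foci, timepoint = 4)
  s3 <- foci_timecourse(rec, schedule = 4)
  for (g in c("lo", "hi")) {
    lam <- c(lo = 2, hi = 6)[[g]]
    row <- s3[s3$group == g, ]
    expect_lt(abs(row$mean_count - lam), 3 * sqrt(lam / row$n))
  }
  expect_error(foci_timecourse(rec, schedule = c(0, 4)), "scheduled")
})

test_that("group comparisons match hand-computed ANOVA and detect effects", {
  # identical constant groups: between-group SS 0, F reported as 0
  flat <- tibble::tibble(group = rep(c("a", "b"), each = 5), count = 3)
  ct <- compare_counts(flat)
  expect_equal(ct$anova$sumsq[ct$anova$term == "group"], 0)
  expect_equal(ct$anova$statistic[ct$anova$term == "group"], 0)
  expect_equal(ct$anova$p.value[ct$anova$term == "group"], 1)

  # textbook 3-group example against a hand sums-of-squares decomposition
  counts <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(8, 9, 10))
  d <- tibble::tibble(group = rep(names(counts), each = 3),
                      count = unlist(counts))
  grand <- mean(d$count)
  ss_between <- sum(vapply(counts, function(v) {
    3 * (mean(v) - grand)^2
  }, numeric(1)))
  ss_within <- sum(vapply(counts, function(v) {
    sum((v - mean(v))^2)
  }, numeric(1)))
  f_hand <- (ss_between / 2) / (ss_within / 6)
  ct2 <- compare_counts(d)
  g_row <- ct2$anova[ct2$anova$term == "group", ]
  expect_equal(g_row$sumsq, ss_between)
  expect_equal(g_row$statistic, f_hand)
  expect_equal(nrow(ct2$tukey), 3)

  # power check: lambda 2 vs 6 at n=50/group separates easily
  withr::with_seed(31, {
    sim <- tibble::tibble(
      group = rep(c("lo", "hi"), each = 50),
      count = c(rpois(50, 2), rpois(50, 6))
    )
  })
  expect_lt(generics::glance(compare_counts(sim))$p.value, 0.05)

  # two-way design includes the interaction term
  tc <- tibble::tibble(
    group = rep(c("a", "b"), each = 8),
    timepoint = rep(c(0, 3), times = 8),
    count = c(rep(c(1, 2), 4), rep(c(3, 6), 4))
  )
  ct3 <- compare_counts(tc, design = "two_way")
  expect_true("group:timepoint" %in% ct3$anova$term)
  expect_error(compare_counts(tibble::tibble(group = "a", count = 1)),
               "two groups")
})
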