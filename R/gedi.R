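#' GEDI ratio of a cell
#'
#' The per-cell death-indicator ratio: mean green (GC150, calcium-dependent)
#' over mean red (mApple, constitutive) intensity. Cells whose red intensity
#' falls at or below `red_floor` are unmeasurable at that timepoint and get
#' `NA` — never a ratio of 0, which would mimic a healthy cell.
#'
#' The ratio is invariant to a common gain on both channels and scales
#' linearly with green-channel gain.
#'
#' @param mean_green,mean_red Per-cell mean channel intensities (vectorised).
#' @param red_floor Intensity floor below which the denominator is not
#'   trusted.
#' @return Numeric vector of ratios, `NA` where unmeasurable.
#' @export
#' @examples
#' gedi_ratio(c(500, 0, 176), c(500, 400, 100))
gedi_ratio <- function(mean_green, mean_red, red_floor = 0) {
  stopifnot(length(mean_green) == length(mean_red))
  out <- rep(NA_real_, length(mean_red))
  ok <- !is.na(mean_red) & !is.na(mean_green) & mean_red > red_floor
  out[ok] <- mean_green[ok] / mean_red[ok]
  out
}

#' Link segmented objects across timepoints into cell tracks
#'
#' Greedy nearest-centroid matching between consecutive timepoints: candidate
#' pairs are taken in order of increasing distance, each object matched at
#' most once, and no match is allowed beyond `max_displacement_px`. Objects
#' left unmatched at the earlier timepoint end their track (disappearance);
#' objects unmatched at the later timepoint open new tracks flagged
#' `de_novo = TRUE` — they were not at risk at baseline and are excluded from
#' survival analysis downstream.
#'
#' @param objects Tibble of per-timepoint objects with columns `t`, `id`,
#'   `row`, `col` and any measurement columns (e.g. `mean_red`,
#'   `mean_green`). `id` must be unique within each timepoint.
#' @param max_displacement_px Maximum allowed centroid displacement between
#'   consecutive timepoints.
#' @return Tibble of track observations: `track_id`, `t`, `present`
#'   (always `TRUE`; absence is encoded by the missing row), `row`, `col`,
#'   measurement columns, and `de_novo`.
#' @export
track_cells <- function(objects, max_displacement_px = 24) {
  stopifnot(is.data.frame(objects),
            all(c("t", "id", "row", "col") %in% names(objects)))
  dup <- objects |>
    dplyr::count(.data$t, .data$id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) abort("duplicate object ids within a timepoint")
  times <- sort(unique(objects$t))
  objects <- dplyr::arrange(objects, .data$t, .data$id)
  meta_cols <- setdiff(names(objects), c("t", "id"))

  first <- dplyr::filter(objects, .data$t == times[1])
  track_of <- setNames(paste0("trk", seq_len(nrow(first))), first$id)
  de_novo_of <- setNames(rep(FALSE, nrow(first)), names(track_of))
  next_track <- nrow(first) + 1L
  rows <- list(
    dplyr::mutate(first,
                  track_id = unname(track_of[as.character(first$id)]),
                  de_novo = FALSE, present = TRUE)
  )
  prev <- first
  prev_tracks <- track_of
  prev_denovo <- de_novo_of
  for (ti in seq_along(times)[-1]) {
    cur <- dplyr::filter(objects, .data$t == times[ti])
    cur_tracks <- character(nrow(cur))
    cur_denovo <- logical(nrow(cur))
    if (nrow(prev) > 0 && nrow(cur) > 0) {
      d2 <- outer(prev$row, cur$row, "-")^2 + outer(prev$col, cur$col, "-")^2
      cand <- which(d2 <= max_displacement_px^2, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        cand <- cand[order(d2[cand]), , drop = FALSE]
        used_prev <- logical(nrow(prev))
        used_cur <- logical(nrow(cur))
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]
          j <- cand[k, 2]
          if (!used_prev[i] && !used_cur[j]) {
            used_prev[i] <- TRUE
            used_cur[j] <- TRUE
            id_prev <- as.character(prev$id[i])
            cur_tracks[j] <- prev_tracks[[id_prev]]
            cur_denovo[j] <- prev_denovo[[id_prev]]
          }
        }
      }
    }
    for (j in which(cur_tracks == "")) {
      cur_tracks[j] <- paste0("trk", next_track)
      next_track <- next_track + 1L
      cur_denovo[j] <- TRUE
    }
    rows[[length(rows) + 1L]] <- dplyr::mutate(
      cur, track_id = cur_tracks, de_novo = cur_denovo, present = TRUE
    )
    prev <- cur
    prev_tracks <- setNames(cur_tracks, cur$id)
    prev_denovo <- setNames(cur_denovo, cur$id)
  }
  out <- dplyr::bind_rows(rows)
  dplyr::select(out, "track_id", "t", "present",
                dplyr::all_of(meta_cols), "de_novo")
}

#' Calibrate the GEDI death threshold from a lethal-dose experiment
#'
#' Given GEDI ratios measured at baseline and 24 h after a lethal (25 Gy)
#' radiation dose, finds the cut `theta` minimising total misclassification
#' (baseline cells called dead, i.e. ratio > theta, plus lethally irradiated
#' cells called alive, i.e. ratio <= theta) by exhaustive scan over candidate
#' cuts between consecutive sorted values. When several cuts tie, theta is
#' the midpoint of the tied range. If the best achievable misclassification
#' rate is not below 50% the two distributions are inseparable and
#' calibration fails with an error.
#'
#' @param ratios_baseline,ratios_post_lethal Non-empty numeric vectors of
#'   per-cell GEDI ratios.
#' @return Object of class `gedi_calibration`: list with `theta`,
#'   `misclassification_rate`, `n_baseline`, `n_lethal`.
#' @export
#' @examples
#' calibrate_threshold(rep(0.5, 20), rep(1.5, 20))$theta # 1.0
calibrate_threshold <- function(ratios_baseline, ratios_post_lethal) {
  b <- ratios_baseline[!is.na(ratios_baseline)]
  l <- ratios_post_lethal[!is.na(ratios_post_lethal)]
  if (length(b) == 0 || length(l) == 0) {
    abort("both ratio samples must be non-empty")
  }
  v <- sort(unique(c(b, l)))
  # candidate cuts: below the smallest value, between consecutive values,
  # above the largest
  cuts <- c(v[1] - 1, if (length(v) > 1) (head(v, -1) + tail(v, -1)) / 2,
            v[length(v)] + 1)
  errs <- vapply(cuts, function(th) sum(b > th) + sum(l <= th), numeric(1))
  best <- min(errs)
  rate <- best / (length(b) + length(l))
  if (rate >= 0.5) {
    abort("calibration failed: baseline and lethal distributions inseparable")
  }
  tied <- cuts[errs == best]
  structure(
    list(
      theta = (min(tied) + max(tied)) / 2,
      misclassification_rate = rate,
      n_baseline = length(b),
      n_lethal = length(l)
    ),
    class = "gedi_calibration"
  )
}

#' @export
print.gedi_calibration <- function(x, ...) {
  cat(sprintf(
    "<gedi_calibration> theta = %.4g (misclassification %.2f%%, n = %d + %d)\n",
    x$theta, 100 * x$misclassification_rate, x$n_baseline, x$n_lethal
  ))
  invisible(x)
}

#' Call single-cell fates from GEDI tracks
#'
#' Applies the two death criteria of the biosensor assay to each track:
#' a GEDI ratio crossing the threshold (`ratio > theta`, cause
#' `ratio_crossing`), and disappearance from the field of view (the first
#' scheduled timepoint at which a previously-present cell is absent, cause
#' `disappearance`). The event time is the earlier of the two; tracks still
#' present with ratio at or below theta at the final timepoint are censored
#' there (cause `none`). De-novo tracks (appearing after baseline) are
#' excluded: they were not at risk at time zero. Tracks with no measurable
#' timepoint are dropped with a warning.
#'
#' @param tracks Tibble of track observations (see [track_cells()] /
#'   [sim_fate_tracks()]): columns `track_id`, `t`, `mean_red`, `mean_green`,
#'   optionally `group` and `de_novo`.
#' @param theta Death threshold on the GEDI ratio. Defaults to the fixed
#'   rule `theta = 1`; pass `calibrate_threshold()$theta` to use a
#'   calibrated value.
#' @param schedule The scheduled imaging timepoints; absences are only
#'   meaningful relative to this schedule.
#' @param rule Which death criteria count as events: both (`"either"`,
#'   default), only ratio crossings, or only disappearances (the criterion
#'   not selected is ignored, and such cells remain at risk until the other
#'   fires or follow-up ends).
#' @param red_floor Passed to [gedi_ratio()].
#' @return Tibble of fate records: `track_id`, `group`, `time`, `status`
#'   (`"event"`/`"censored"`), `cause`
#'   (`"ratio_crossing"`/`"disappearance"`/`"none"`).
#' @export
call_fates <- function(tracks, theta = 1, schedule = c(0, 6, 12, 18),
                       rule = c("either", "ratio_only", "disappearance_only"),
                       red_floor = 0) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(tracks),
            all(c("track_id", "t", "mean_red", "mean_green") %in%
                  names(tracks)))
  if (theta <= 0) abort("`theta` must be positive")
  if (any(diff(schedule) <= 0)) abort("`schedule` must be strictly increasing")
  if (!"group" %in% names(tracks)) tracks$group <- "all"
  if ("de_novo" %in% names(tracks)) {
    tracks <- dplyr::filter(tracks, !.data$de_novo)
  }
  tracks <- dplyr::filter(tracks, .data$t %in% schedule)
  tracks$ratio <- gedi_ratio(tracks$mean_green, tracks$mean_red, red_floor)

  n_unmeasurable <- 0L
  out <- tracks |>
    dplyr::group_by(.data$track_id, .data$group) |>
    dplyr::group_map(function(d, key) {
      if (nrow(d) == 0) return(NULL)
      meas <- d[!is.na(d$ratio), ]
      if (nrow(meas) == 0) {
        n_unmeasurable <<- n_unmeasurable + 1L
        return(NULL)
      }
      t_cross <- Inf
      if (rule != "disappearance_only") {
        crossed <- meas$t[meas$ratio > theta]
        if (length(crossed) > 0) t_cross <- min(crossed)
      }
      t_gone <- Inf
      if (rule != "ratio_only") {
        first_present <- min(d$t)
        later <- schedule[schedule > first_present]
        absent <- later[!later %in% d$t]
        if (length(absent) > 0) t_gone <- min(absent)
      }
      t_event <- min(t_cross, t_gone)
      if (is.finite(t_event)) {
        tibble(
          track_id = key$track_id, group = key$group, time = t_event,
          status = "event",
          cause = if (t_cross <= t_gone) "ratio_crossing" else "disappearance"
        )
      } else {
        tibble(
          track_id = key$track_id, group = key$group,
          time = max(schedule), status = "censored", cause = "none"
        )
      }
    }) |>
    dplyr::bind_rows()
  if (n_unmeasurable > 0) {
    warn(sprintf("%d track(s) had no measurable timepoint and were excluded",
                 n_unmeasurable))
  }
  if (nrow(out) == 0) {
    out <- tibble(track_id = character(0), group = character(0),
                  time = numeric(0), status = character(0),
                  cause = character(0))
  }
  dplyr::arrange(out, .data$group, .data$track_id)
}

#' Mean GEDI ratio per group and timepoint
#'
#' Summaries of the per-cell ratio trajectories, both over all measurable
#' cells at a timepoint and restricted to cells still classified alive
#' (ratio at or below `theta` and not yet disappeared). Reported side by side
#' because published per-arm means do not always state which convention was
#' used.
#'
#' @inheritParams call_fates
#' @return Tibble: `group`, `t`, `n`, `mean_ratio_all`, `mean_ratio_alive`.
#' @export
summarise_ratios <- function(tracks, theta = 1, red_floor = 0) {
  stopifnot(is.data.frame(tracks))
  if (!"group" %in% names(tracks)) tracks$group <- "all"
  tracks$ratio <- gedi_ratio(tracks$mean_green, tracks$mean_red, red_floor)
  tracks |>
    dplyr::filter(!is.na(.data$ratio)) |>
    dplyr::group_by(.data$group, .data$t) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ratio_all = mean(.data$ratio),
      mean_ratio_alive = mean(.data$ratio[.data$ratio <= theta]),
      .groups = "drop"
    )
}
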