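#' Simulate single-cell GEDI tracks without rendering images
#'
#' Track-level counterpart of [sim_timelapse()]: draws per-cell death times
#' from group-specific exponential hazards and emits the per-timepoint
#' red/green mean intensities a perfect segmentation of the rendered images
#' would measure. Useful for studying the fate-calling and survival stages in
#' isolation (and much faster than rendering pixels).
#'
#' @param n_per_group Cells per treatment arm.
#' @param hazards Named vector of exponential death hazards (events/hour).
#' @param schedule Imaging timepoints, hours post-irradiation.
#' @param r_live,r_dead GEDI ratio before/after apoptotic commitment.
#' @param red_meanlog,red_sdlog Lognormal red-amplitude parameters.
#' @param intensity_cv Multiplicative measurement noise (coefficient of
#'   variation) applied independently to each channel at each timepoint.
#' @param detach_delay_h Hours from death to disappearance.
#' @param detach_prob Probability a dead cell detaches.
#' @param seed RNG seed.
#'
#' @return List with `tracks` (tibble: `track_id`, `group`, `t`, `present`,
#'   `mean_red`, `mean_green`) containing only rows where the cell is still
#'   visible, and `truth` (tibble: `track_id`, `group`, `death_time_h`,
#'   `detach_time_h`).
#' @export
#' @examples
#' sim <- sim_fate_tracks(50, c(control = 0.12, high = 0.04), seed = 1)
#' head(sim$tracks)
sim_fate_tracks <- function(n_per_group,
                            hazards = c(control = 0.12, high = 0.04),
                            schedule = c(0, 6, 12, 18),
                            r_live = 0.5,
                            r_dead = 1.8,
                            red_meanlog = log(2000),
                            red_sdlog = 0.25,
                            intensity_cv = 0.03,
                            detach_delay_h = 6,
                            detach_prob = 0.9,
                            seed = 1L) {
  stopifnot(n_per_group >= 0, all(hazards >= 0), !is.null(names(hazards)))
  if (any(diff(schedule) <= 0)) abort("`schedule` must be strictly increasing")
  with_rng_seed(seed, {
    truth <- purrr::map_dfr(names(hazards), function(g) {
      death <- draw_death_times(n_per_group, hazards[[g]], shape = 1)
      detaches <- runif(n_per_group) < detach_prob
      tibble(
        track_id = paste0(g, "_c", seq_len(n_per_group)),
        group = g,
        death_time_h = death,
        detach_time_h = ifelse(detaches & is.finite(death),
                               death + detach_delay_h, NA_real_),
        red_amplitude = rlnorm(n_per_group, red_meanlog, red_sdlog)
      )
    })
    tracks <- tidyr::expand_grid(
      truth[, c("track_id", "group", "death_time_h", "detach_time_h",
                "red_amplitude")],
      t = schedule
    )
    tracks <- dplyr::filter(
      tracks,
      is.na(.data$detach_time_h) | .data$t < .data$detach_time_h
    )
    n <- nrow(tracks)
    r_now <- ifelse(tracks$t < tracks$death_time_h, r_live, r_dead)
    red <- tracks$red_amplitude * exp(rnorm(n, sd = intensity_cv))
    green <- tracks$red_amplitude * r_now * exp(rnorm(n, sd = intensity_cv))
    tracks <- tibble(
      track_id = tracks$track_id,
      group = tracks$group,
      t = tracks$t,
      present = TRUE,
      mean_red = red,
      mean_green = green
    )
    list(
      tracks = tracks,
      truth = truth[, c("track_id", "group", "death_time_h", "detach_time_h")]
    )
  })
}
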