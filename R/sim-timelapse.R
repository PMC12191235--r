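#' Parameters for the synthetic GEDI time-lapse generator
#'
#' Bundles and validates the knobs of [sim_timelapse()]. Defaults encode the
#' study conditions the pipeline is designed for: sparse fields of
#' biosensor-expressing glioma cells imaged at 0/6/12/18 hours
#' post-irradiation, with dose-dependent protection expressed as decreasing
#' exponential death hazards across treatment arms.
#'
#' @param n_cells Cells per field (per group).
#' @param field_size Field dimensions `c(height, width)` in pixels.
#' @param cell_radius_px Mean cell radius (Gaussian blob sigma is half this).
#' @param cell_radius_sd Spread of per-cell radii.
#' @param red_meanlog,red_sdlog Lognormal parameters of the constitutive red
#'   (mApple) amplitude per cell, in arbitrary units.
#' @param r_live,r_dead Green/red intensity ratio before and after apoptotic
#'   commitment. Must satisfy `r_dead > r_live > 0`.
#' @param hazard_per_group Named vector of exponential death hazards
#'   (events/hour), one per treatment arm.
#' @param weibull_shape Shape of the Weibull death-time distribution; 1
#'   (default) gives the exponential model.
#' @param ramp_duration_h Duration of the live-to-dead ratio transition; 0
#'   (default) makes the transition a step, which keeps the ground truth
#'   unambiguous.
#' @param detach_delay_h Hours between apoptotic commitment and detachment
#'   (disappearance from the field of view).
#' @param detach_prob Probability a dead cell detaches at all.
#' @param background_level Background intensity added to every channel.
#' @param noise_sigma Gaussian read-noise standard deviation.
#' @param poisson_noise Add Poisson shot noise on pixel means?
#' @param jitter_px Per-frame centroid jitter (standard deviation, px).
#' @param timepoints_h Imaging schedule, hours post-irradiation, strictly
#'   increasing.
#' @param seed Integer RNG seed; identical parameters and seed reproduce the
#'   output exactly.
#'
#' @return A validated list of class `timelapse_params`.
#' @export
timelapse_params <- function(n_cells = 100,
                             field_size = c(512, 512),
                             cell_radius_px = 6,
                             cell_radius_sd = 1,
                             red_meanlog = log(2000),
                             red_sdlog = 0.25,
                             r_live = 0.5,
                             r_dead = 1.8,
                             hazard_per_group = c(control = 0.12, low = 0.08,
                                                  medium = 0.06, high = 0.04),
                             weibull_shape = 1,
                             ramp_duration_h = 0,
                             detach_delay_h = 6,
                             detach_prob = 0.9,
                             background_level = 100,
                             noise_sigma = 10,
                             poisson_noise = FALSE,
                             jitter_px = 1,
                             timepoints_h = c(0, 6, 12, 18),
                             seed = 1L) {
  p <- as.list(environment())
  if (p$n_cells < 0) abort("`n_cells` must be >= 0")
  if (length(p$field_size) != 2 || any(p$field_size <= 0)) {
    abort("`field_size` must be two positive dimensions")
  }
  if (!(p$r_dead > p$r_live && p$r_live > 0)) {
    abort("require r_dead > r_live > 0")
  }
  if (is.null(names(p$hazard_per_group)) || any(p$hazard_per_group < 0)) {
    abort("`hazard_per_group` must be a named vector of hazards >= 0")
  }
  if (length(p$timepoints_h) < 1 || any(diff(p$timepoints_h) <= 0)) {
    abort("`timepoints_h` must be strictly increasing")
  }
  if (p$detach_prob < 0 || p$detach_prob > 1) abort("`detach_prob` in [0,1]")
  if (p$weibull_shape <= 0) abort("`weibull_shape` must be > 0")
  if (p$ramp_duration_h < 0) abort("`ramp_duration_h` must be >= 0")
  structure(p, class = "timelapse_params")
}

# Green/red ratio of one cell at time t given its death time and the ratio
# model (step by default, optional linear ramp of length ramp_duration_h).
ratio_at <- function(t, death_time, r_live, r_dead, ramp = 0) {
  if (!is.finite(death_time) || t < death_time) return(r_live)
  if (ramp <= 0 || t >= death_time + ramp) return(r_dead)
  r_live + (r_dead - r_live) * (t - death_time) / ramp
}

# Death times for n cells: Weibull with given shape, scaled so the hazard
# matches `hazard` for shape 1 (exponential).  Shape != 1 keeps the same
# distribution scale parameter lambda^-1.
draw_death_times <- function(n, hazard, shape) {
  if (hazard <= 0) return(rep(Inf, n))
  rweibull(n, shape = shape, scale = 1 / hazard)
}

#' Simulate a GEDI biosensor time-lapse experiment
#'
#' Renders, for every treatment arm in `params$hazard_per_group`, one field of
#' view per scheduled timepoint: cells are isotropic Gaussian blobs with a
#' constant per-cell red (mApple) amplitude; the green (GC150) channel is the
#' red blob scaled by the cell's current GEDI ratio, which steps from
#' `r_live` to `r_dead` at the cell's sampled death time. Dead cells detach
#' (disappear from later frames) `detach_delay_h` hours after death with
#' probability `detach_prob`. Ground truth records every cell's centroid,
#' group, exact death time and detachment time.
#'
#' @param params A [timelapse_params()] object.
#'
#' @return A list with elements:
#' \describe{
#'   \item{frames}{Named list (one entry per group) of lists of
#'     [frame_stack()] objects, one per timepoint.}
#'   \item{truth}{Tibble with `cell_id`, `group`, `row`, `col`, `radius_px`,
#'     `red_amplitude`, `death_time_h` (`Inf` when the cell never dies) and
#'     `detach_time_h` (`NA` when the cell never detaches).}
#'   \item{params}{The parameter object, for provenance.}
#' }
#' @export
#' @examples
#' sim <- sim_timelapse(timelapse_params(
#'   n_cells = 10, field_size = c(128, 128),
#'   hazard_per_group = c(control = 0.12), seed = 7
#' ))
#' sim$truth
sim_timelapse <- function(params) {
  stopifnot(inherits(params, "timelapse_params"))
  p <- params
  with_rng_seed(p$seed, {
    groups <- names(p$hazard_per_group)
    truth_list <- list()
    frames <- list()
    for (g in groups) {
      centres <- sample_centres(
        p$n_cells, p$field_size,
        margin = 2 * p$cell_radius_px,
        min_sep = 4 * p$cell_radius_px
      )
      radii <- if (p$n_cells > 0) {
        pmax(2, rnorm(p$n_cells, p$cell_radius_px, p$cell_radius_sd))
      } else {
        numeric(0)
      }
      red_amp <- rlnorm(p$n_cells, p$red_meanlog, p$red_sdlog)
      death <- draw_death_times(p$n_cells, p$hazard_per_group[[g]],
                                p$weibull_shape)
      detaches <- runif(p$n_cells) < p$detach_prob
      detach_time <- ifelse(
        detaches & is.finite(death), death + p$detach_delay_h, NA_real_
      )
      truth_list[[g]] <- tibble(
        cell_id = if (p$n_cells > 0) {
          paste0(g, "_c", seq_len(p$n_cells))
        } else {
          character(0)
        },
        group = rep(g, p$n_cells),
        row = centres$row,
        col = centres$col,
        radius_px = radii,
        red_amplitude = red_amp,
        death_time_h = death,
        detach_time_h = detach_time
      )
      g_frames <- vector("list", length(p$timepoints_h))
      for (ti in seq_along(p$timepoints_h)) {
        t <- p$timepoints_h[ti]
        red <- matrix(p$background_level, p$field_size[1], p$field_size[2])
        green <- matrix(p$background_level, p$field_size[1], p$field_size[2])
        for (i in seq_len(p$n_cells)) {
          if (!is.na(detach_time[i]) && t >= detach_time[i]) next
          r_now <- ratio_at(t, death[i], p$r_live, p$r_dead,
                            p$ramp_duration_h)
          jr <- centres$row[i] + rnorm(1, sd = p$jitter_px)
          jc <- centres$col[i] + rnorm(1, sd = p$jitter_px)
          sigma <- radii[i] / 2
          red <- add_gaussian_blob(red, jr, jc, sigma, red_amp[i])
          green <- add_gaussian_blob(green, jr, jc, sigma,
                                     red_amp[i] * r_now)
        }
        red <- add_noise(red, p$noise_sigma, p$poisson_noise)
        green <- add_noise(green, p$noise_sigma, p$poisson_noise)
        g_frames[[ti]] <- frame_stack(
          list(red = red, green = green),
          timepoint = t, fov = paste0(g, "_f1")
        )
      }
      frames[[g]] <- g_frames
    }
    list(
      frames = frames,
      truth = dplyr::bind_rows(truth_list),
      params = p
    )
  })
}
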