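#' Simulate a DNA-damage foci field
#'
#' Renders one field of nuclei with Poisson-distributed bright puncta, the
#' synthetic counterpart of a gamma-H2AX immunofluorescence image (or, with
#' the same geometry, a 53BP1trunc-mApple live-cell frame). Each cell is a
#' soft-edged disc in the nuclear (`blue`) channel; the foci (`green`)
#' channel carries a per-cell diffuse level plus PSF-blurred spots whose peak
#' intensity is `foci_intensity_factor` times the cell's diffuse level — the
#' quantity the detection rule (an order of magnitude above per-cell
#' background) is calibrated against.
#'
#' @param n_cells Number of cells in the field.
#' @param lambda Mean foci per cell; a named vector assigns cells to groups
#'   round-robin (one value per group).
#' @param foci_intensity_factor Peak focus intensity as a multiple of the
#'   cell's diffuse in-mask level. Must exceed 1 — a focus at or below the
#'   cell background is undetectable by the contrast rule and is refused.
#' @param psf_sigma_px Gaussian point-spread sigma of a focus.
#' @param field_size Field `c(height, width)` in pixels.
#' @param nucleus_radius_px Nucleus radius.
#' @param cell_level_meanlog,cell_level_sdlog Lognormal parameters of the
#'   per-cell diffuse (background) green level.
#' @param background_level Off-cell background, both channels.
#' @param noise_sigma Gaussian read noise.
#' @param min_focus_sep_px Minimum separation between focus centres within a
#'   nucleus (keeps truth counts resolvable).
#' @param timepoint Hours post-irradiation stamped on the output.
#' @param seed RNG seed.
#'
#' @return List with `frame` (a [frame_stack()] with `blue` and `green`
#'   channels), `truth` (tibble: `cell_id`, `group`, `row`, `col`,
#'   `n_foci`, `cell_level`) and `foci` (tibble of true focus positions).
#' @export
sim_foci_stack <- function(n_cells = 50,
                           lambda = 5,
                           foci_intensity_factor = 20,
                           psf_sigma_px = 1.2,
                           field_size = c(640, 640),
                           nucleus_radius_px = 14,
                           cell_level_meanlog = log(200),
                           cell_level_sdlog = 0.2,
                           background_level = 20,
                           noise_sigma = 2,
                           min_focus_sep_px = 4,
                           timepoint = NA_real_,
                           seed = 1L) {
  if (any(lambda < 0)) abort("`lambda` must be >= 0")
  if (foci_intensity_factor <= 1) {
    abort(paste0(
      "`foci_intensity_factor` must be > 1: foci at or below the cell ",
      "background are undetectable by the contrast criterion"
    ))
  }
  groups <- names(lambda) %||% rep("g1", length(lambda))
  if (is.null(names(lambda))) names(lambda) <- groups <- "g1"
  with_rng_seed(seed, {
    centres <- sample_centres(
      n_cells, field_size,
      margin = 2 * nucleus_radius_px,
      min_sep = 2.6 * nucleus_radius_px
    )
    grp <- rep(names(lambda), length.out = max(n_cells, 1))[seq_len(n_cells)]
    lam <- unname(lambda[grp])
    cell_level <- rlnorm(n_cells, cell_level_meanlog, cell_level_sdlog)
    counts <- if (n_cells > 0) rpois(n_cells, lam) else integer(0)

    blue <- matrix(background_level, field_size[1], field_size[2])
    green <- matrix(background_level, field_size[1], field_size[2])
    foci_rows <- list()
    for (i in seq_len(n_cells)) {
      blue <- add_disc(blue, centres$row[i], centres$col[i],
                       nucleus_radius_px, amplitude = 300)
      green <- add_disc(green, centres$row[i], centres$col[i],
                        nucleus_radius_px, amplitude = cell_level[i])
      k <- counts[i]
      if (k == 0) next
      placed_r <- numeric(0)
      placed_c <- numeric(0)
      inner <- 0.7 * nucleus_radius_px
      for (f in seq_len(k)) {
        for (try in 1:500) {
          ang <- runif(1, 0, 2 * pi)
          rad <- inner * sqrt(runif(1))
          fr <- centres$row[i] + rad * sin(ang)
          fc <- centres$col[i] + rad * cos(ang)
          ok <- length(placed_r) == 0 ||
            min((placed_r - fr)^2 + (placed_c - fc)^2) >= min_focus_sep_px^2
          if (ok || try == 500L) break
        }
        placed_r <- c(placed_r, fr)
        placed_c <- c(placed_c, fc)
        # peak total = factor * diffuse level inside the nucleus
        green <- add_gaussian_blob(
          green, fr, fc, psf_sigma_px,
          (foci_intensity_factor - 1) * cell_level[i]
        )
        foci_rows[[length(foci_rows) + 1L]] <- tibble(
          cell_id = paste0("cell", i), row = fr, col = fc
        )
      }
    }
    if (noise_sigma > 0) {
      blue <- add_noise(blue, noise_sigma)
      green <- add_noise(green, noise_sigma)
    }
    list(
      frame = frame_stack(list(blue = blue, green = green),
                          timepoint = timepoint, fov = "foci_f1"),
      truth = tibble(
        cell_id = if (n_cells > 0) paste0("cell", seq_len(n_cells))
                  else character(0),
        group = grp,
        row = centres$row,
        col = centres$col,
        n_foci = counts,
        cell_level = cell_level
      ),
      foci = if (length(foci_rows)) dplyr::bind_rows(foci_rows)
             else tibble(cell_id = character(0), row = numeric(0),
                         col = numeric(0))
    )
  })
}
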