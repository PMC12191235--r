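#' Simulate a colony-formation assay image
#'
#' Renders disc-like colonies above a uniform background, as seen in
#' transmitted/fluorescence scans of neurosphere colony plates. By default
#' colonies are disjoint (centres rejection-sampled with a separation
#' buffer); with `allow_overlap = TRUE` colonies may touch, and the ground
#' truth flags every colony involved in an overlap (downstream counting
#' merges touching colonies and cannot recover them).
#'
#' @param n_colonies Number of colonies.
#' @param radius_range Uniform range of colony radii, px.
#' @param intensity Colony amplitude above background.
#' @param background Background level.
#' @param field_size Field `c(height, width)`, px.
#' @param allow_overlap Allow touching/overlapping colonies?
#' @param noise_sigma Gaussian noise sd.
#' @param seed RNG seed.
#'
#' @return List with `image` (matrix) and `truth` (tibble: `colony_id`,
#'   `row`, `col`, `radius_px`, `area_px` = pi r^2, `overlaps`).
#' @export
sim_colony_image <- function(n_colonies = 20,
                             radius_range = c(8, 20),
                             intensity = 500,
                             background = 50,
                             field_size = c(512, 512),
                             allow_overlap = FALSE,
                             noise_sigma = 5,
                             seed = 1L) {
  if (n_colonies < 0) abort("`n_colonies` must be >= 0")
  if (max(radius_range) * 2 >= min(field_size)) {
    abort("colony radii exceed the field")
  }
  with_rng_seed(seed, {
    radii <- if (n_colonies > 0) {
      runif(n_colonies, radius_range[1], radius_range[2])
    } else {
      numeric(0)
    }
    margin <- max(radius_range) + 4
    if (allow_overlap) {
      centres <- tibble(
        row = runif(n_colonies, margin, field_size[1] - margin),
        col = runif(n_colonies, margin, field_size[2] - margin)
      )
    } else {
      # buffer of 4 px beyond the sum of the two largest radii
      centres <- sample_centres(
        n_colonies, field_size, margin,
        min_sep = 2 * max(radius_range) + 4
      )
    }
    img <- matrix(background, field_size[1], field_size[2])
    for (i in seq_len(n_colonies)) {
      img <- add_disc(img, centres$row[i], centres$col[i], radii[i],
                      intensity)
    }
    if (noise_sigma > 0) img <- add_noise(img, noise_sigma)
    overlaps <- rep(FALSE, n_colonies)
    if (n_colonies > 1) {
      d <- as.matrix(stats::dist(cbind(centres$row, centres$col)))
      for (i in seq_len(n_colonies)) {
        others <- setdiff(seq_len(n_colonies), i)
        overlaps[i] <- any(d[i, others] <= radii[i] + radii[others] + 2)
      }
    }
    list(
      image = img,
      truth = tibble(
        colony_id = if (n_colonies > 0) paste0("col", seq_len(n_colonies))
                    else character(0),
        row = centres$row,
        col = centres$col,
        radius_px = radii,
        area_px = pi * radii^2,
        overlaps = overlaps
      )
    )
  })
}
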