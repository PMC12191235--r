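# Shift matrix rows (dim = 1) or columns (dim = 2) by d, padding with fill.
shift_mat <- function(m, d, fill, dim = 1L) {
  if (d == 0) return(m)
  h <- nrow(m)
  w <- ncol(m)
  if (dim == 1L) {
    if (abs(d) >= h) return(matrix(fill, h, w))
    if (d > 0) {
      rbind(m[(d + 1):h, , drop = FALSE], matrix(fill, d, w))
    } else {
      rbind(matrix(fill, -d, w), m[1:(h + d), , drop = FALSE])
    }
  } else {
    if (abs(d) >= w) return(matrix(fill, h, w))
    if (d > 0) {
      cbind(m[, (d + 1):w, drop = FALSE], matrix(fill, h, d))
    } else {
      cbind(matrix(fill, h, -d), m[, 1:(w + d), drop = FALSE])
    }
  }
}

# Centred running min (op = pmin, fill = Inf) or max (op = pmax,
# fill = -Inf) of window 2r+1 along one dimension, by doubling:
# O(log r) whole-matrix shifts.  The input is padded with the neutral fill
# so border windows are simply truncated.
run_extreme <- function(m, r, op, fill, dim = 1L) {
  w <- 2L * r + 1L
  ext <- if (dim == 1L) {
    rbind(matrix(fill, r, ncol(m)), m, matrix(fill, r, ncol(m)))
  } else {
    cbind(matrix(fill, nrow(m), r), m, matrix(fill, nrow(m), r))
  }
  cur <- ext
  p <- 1L
  while (2L * p <= w) {
    cur <- op(cur, shift_mat(cur, p, fill, dim))
    p <- 2L * p
  }
  if (w > p) cur <- op(cur, shift_mat(cur, w - p, fill, dim))
  if (dim == 1L) {
    cur[seq_len(nrow(m)), , drop = FALSE]
  } else {
    cur[, seq_len(ncol(m)), drop = FALSE]
  }
}

gray_erode <- function(m, r) {
  run_extreme(run_extreme(m, r, pmin, Inf, 1L), r, pmin, Inf, 2L)
}

gray_dilate <- function(m, r) {
  run_extreme(run_extreme(m, r, pmax, -Inf, 1L), r, pmax, -Inf, 2L)
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a fluorescence image by grayscale
#' morphological opening (erosion followed by dilation with a square window
#' of half-width `radius_px`, the separable approximation of the classical
#' rolling-ball estimate) and subtracts it. Structures smaller than the
#' window — cells, colonies, puncta — survive; smooth illumination and
#' constant offsets are removed. Output is clipped at zero.
#'
#' @param image Numeric matrix.
#' @param radius_px Ball radius in pixels; must be positive and smaller than
#'   the image.
#' @return Background-subtracted matrix, same dimensions, non-negative.
#' @export
#' @examples
#' img <- matrix(500, 64, 64)
#' max(abs(rolling_ball(img, 15))) # constant background removed
rolling_ball <- function(image, radius_px) {
  check_image(image)
  if (radius_px <= 0) abort("`radius_px` must be positive")
  if (2 * radius_px + 1 > min(dim(image))) {
    abort("`radius_px` larger than the image")
  }
  r <- as.integer(floor(radius_px))
  if (r < 1L) r <- 1L
  bg <- gray_dilate(gray_erode(image, r), r)
  pmax(image - bg, 0)
}

#' Approximate point-spread-function sharpening
#'
#' Contrast-enhancing approximate deconvolution by Gaussian unsharp masking:
#' `out = image + strength * (image - gaussian_blur(image, sigma))`, clipped
#' at zero. With `strength = 0` the image is returned unchanged. This is the
#' preprocessing role the Gen5 "point spread deconvolution" step plays ahead
#' of thresholding; no true PSF inversion is attempted.
#'
#' @param image Numeric matrix.
#' @param sigma_px Gaussian kernel sigma (> 0).
#' @param strength Non-negative sharpening weight.
#' @return Sharpened matrix, non-negative.
#' @export
sharpen_psf <- function(image, sigma_px, strength = 1) {
  check_image(image)
  if (sigma_px <= 0) abort("`sigma_px` must be positive")
  if (strength < 0) abort("`strength` must be >= 0")
  if (strength == 0) return(image)
  blurred <- EBImage::imageData(EBImage::gblur(image, sigma = sigma_px))
  pmax(image + strength * (image - blurred), 0)
}

#' Otsu threshold of an intensity image
#'
#' Exhaustive search over a 256-bin histogram for the cut maximizing the
#' between-class variance. Errors on a constant image (degenerate histogram:
#' no two classes to separate).
#'
#' @param image Numeric matrix.
#' @param n_bins Histogram resolution.
#' @return Threshold on the intensity scale of `image`.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  check_image(image)
  lo <- min(image)
  hi <- max(image)
  if (hi <= lo) abort("degenerate histogram: image is constant")
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- as.numeric(tabulate(
    pmin(pmax(findInterval(image, breaks, all.inside = TRUE), 1L), n_bins),
    nbins = n_bins
  ))
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  total <- w[n_bins]
  mu_t <- mu[n_bins]
  w0 <- w[-n_bins]
  w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu_t * w0[valid] / total - mu[-n_bins][valid])^2 /
    (w0[valid] * w1[valid])
  # ties (empty valley between modes gives a flat plateau): cut at the
  # middle of the tied range, as an exhaustive scan over sample values does
  mx <- max(bcv)
  ks <- which(bcv >= mx - 1e-9 * abs(mx))
  k <- as.integer(round(mean(range(ks))))
  breaks[k + 1L]
}

#' Binary mask by manual or Otsu thresholding
#'
#' @param image Numeric matrix.
#' @param mode `"manual"` (requires `value`) or `"otsu"`.
#' @param value Manual threshold; the mask is `TRUE` where intensity >=
#'   `value`.
#' @return Logical matrix.
#' @export
threshold_mask <- function(image, mode = c("otsu", "manual"), value = NULL) {
  check_image(image)
  mode <- match.arg(mode)
  thr <- switch(mode,
    manual = {
      if (is.null(value)) abort("manual mode requires `value`")
      value
    },
    otsu = otsu_threshold(image)
  )
  image >= thr
}

# Union-find over integer labels.
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# Merge 4-connected labels that touch diagonally, giving 8-connectivity.
merge_diagonal <- function(lab) {
  n <- max(lab)
  if (n < 2) return(lab)
  h <- nrow(lab)
  w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(n)
  for (i in seq_len(nrow(pairs))) {
    a <- uf_find(parent, pairs[i, 1])
    b <- uf_find(parent, pairs[i, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  new_id <- match(root, sort(unique(root)))
  lab[lab > 0] <- new_id[lab[lab > 0]]
  lab
}

#' Label connected objects in a binary mask
#'
#' 8-connected component labeling with a minimum-area filter. Labels are
#' renumbered consecutively (1, 2, ...) after filtering; per-object centroids
#' (1-based matrix row/col, pixel-centred) and areas are tabulated.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @param min_area_px Components smaller than this are discarded.
#' @return An object of class `labeled_objects`: a list with `labels`
#'   (integer matrix, 0 = background) and `objects` (tibble: `id`, `row`,
#'   `col`, `area`).
#' @export
label_objects <- function(mask, min_area_px = 20) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix")
  if (is.logical(mask)) mask <- mask * 1
  if (!all(mask %in% c(0, 1))) abort("`mask` must be binary")
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  storage.mode(lab) <- "integer"
  lab <- merge_diagonal(lab)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  lab[lab > 0] <- relab[lab[lab > 0]]
  objects <- if (length(keep) > 0) {
    idx <- which(lab > 0)
    l <- lab[idx]
    rr <- ((idx - 1L) %% nrow(lab)) + 1L
    cc <- ((idx - 1L) %/% nrow(lab)) + 1L
    tibble(
      id = seq_along(keep),
      row = as.numeric(tapply(rr, l, mean)),
      col = as.numeric(tapply(cc, l, mean)),
      area = as.integer(tabulate(l, nbins = length(keep)))
    )
  } else {
    tibble(id = integer(0), row = numeric(0), col = numeric(0),
           area = integer(0))
  }
  structure(list(labels = lab, objects = objects),
            class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("<labeled_objects> %d objects in a %d x %d field\n",
              nrow(x$objects), nrow(x$labels), ncol(x$labels)))
  print(x$objects, ...)
  invisible(x)
}

#' @export
as_tibble.labeled_objects <- function(x, ...) x$objects

# Mean intensity of each labeled object in each supplied channel matrix.
measure_channels <- function(objects, channels) {
  lab <- objects$labels
  idx <- which(lab > 0)
  if (length(idx) == 0 || nrow(objects$objects) == 0) {
    for (nm in names(channels)) {
      objects$objects[[paste0("mean_", nm)]] <- numeric(0)
    }
    return(objects)
  }
  l <- lab[idx]
  nb <- nrow(objects$objects)
  area <- tabulate(l, nbins = nb)
  for (nm in names(channels)) {
    sums <- as.numeric(rowsum(channels[[nm]][idx], l))
    objects$objects[[paste0("mean_", nm)]] <- sums / area
  }
  objects
}

# Automatic foreground mask with a sanity guard: on a field with no real
# objects, Otsu splits the noise distribution and the "foreground" covers a
# large share of the field.  Genuine sparse fluorescent objects cover a
# small fraction, so an implausibly large foreground is treated as empty.
auto_mask <- function(img, threshold, max_foreground_fraction) {
  mask <- if (is.numeric(threshold)) {
    threshold_mask(img, "manual", threshold)
  } else {
    threshold_mask(img, "otsu")
  }
  if (!is.numeric(threshold) &&
      mean(mask) > max_foreground_fraction) {
    mask[] <- FALSE
  }
  mask
}

# Shared preprocessing + segmentation chain on one channel.
segment_channel <- function(frame, channel, rolling_ball_radius, sharpen_sigma,
                            sharpen_strength, threshold, min_area_px,
                            max_foreground_fraction = 0.25,
                            measure = names(frame$channels)) {
  img <- get_channel(frame, channel)
  img <- rolling_ball(img, rolling_ball_radius)
  img <- sharpen_psf(img, sharpen_sigma, sharpen_strength)
  mask <- auto_mask(img, threshold, max_foreground_fraction)
  objects <- label_objects(mask, min_area_px)
  # intensities are measured on background-subtracted channels so that
  # downstream ratios reflect cell signal, not camera offset
  sub <- lapply(frame$channels[measure], rolling_ball,
                radius_px = rolling_ball_radius)
  measure_channels(objects, sub)
}

#' Segment cells from the red (mApple) channel
#'
#' The biosensor segmentation chain: rolling-ball background subtraction,
#' unsharp-mask sharpening, thresholding (Otsu by default, or a manual
#' value), and 8-connected labeling — masks are generated in the red channel
#' and then used to measure mean red and green intensity per cell on the
#' background-subtracted channels, the inputs of the GEDI ratio.
#'
#' @param frame A [frame_stack()] with a `red` channel.
#' @param rolling_ball_radius Background ball radius, px.
#' @param sharpen_sigma,sharpen_strength Unsharp-mask parameters.
#' @param threshold `"otsu"` or a numeric manual threshold (applied to the
#'   preprocessed image).
#' @param min_area_px Minimum object area.
#' @param max_foreground_fraction In Otsu mode, fields whose candidate
#'   foreground exceeds this fraction are treated as empty (a blank field
#'   has no bimodal histogram; Otsu would split the noise).
#' @return A `labeled_objects` whose `objects` tibble carries `mean_red` and
#'   `mean_green` columns (plus any other channels present).
#' @export
segment_cells_red <- function(frame,
                              rolling_ball_radius = 25,
                              sharpen_sigma = 2,
                              sharpen_strength = 1,
                              threshold = "otsu",
                              min_area_px = 20,
                              max_foreground_fraction = 0.25) {
  stopifnot(inherits(frame, "frame_stack"))
  segment_channel(frame, "red", rolling_ball_radius, sharpen_sigma,
                  sharpen_strength, threshold, min_area_px,
                  max_foreground_fraction)
}

#' Segment nuclei from the DAPI (blue) channel
#'
#' Same operator chain as [segment_cells_red()] applied to the `blue`
#' channel. Nuclei serve as per-cell compartments for gamma-H2AX foci
#' counting. Objects whose area exceeds `mean + 3 SD` of the field are
#' flagged (`flag_large`) as candidate merged nuclei; no splitting is
#' attempted.
#'
#' @inheritParams segment_cells_red
#' @return A `labeled_objects`; the `objects` tibble gains per-channel means
#'   and a logical `flag_large` column.
#' @export
segment_nuclei <- function(frame,
                           rolling_ball_radius = 25,
                           sharpen_sigma = 2,
                           sharpen_strength = 1,
                           threshold = "otsu",
                           min_area_px = 20,
                           max_foreground_fraction = 0.25) {
  stopifnot(inherits(frame, "frame_stack"))
  out <- segment_channel(frame, "blue", rolling_ball_radius, sharpen_sigma,
                         sharpen_strength, threshold, min_area_px,
                         max_foreground_fraction)
  a <- out$objects$area
  out$objects$flag_large <- if (length(a) >= 2) {
    a > mean(a) + 3 * sd(a)
  } else {
    rep(FALSE, length(a))
  }
  out
}
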