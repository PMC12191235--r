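# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG stream.
with_rng_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort(sprintf("`%s` must be a numeric matrix", arg))
  }
  if (any(!is.finite(image))) {
    abort(sprintf("`%s` contains non-finite pixels", arg))
  }
  invisible(image)
}

# Gaussian blob rendered into `field` (modified copy returned): additive,
# truncated to a local window of +/- 4 sigma for speed.
add_gaussian_blob <- function(field, row, col, sigma, amplitude) {
  h <- nrow(field)
  w <- ncol(field)
  r0 <- max(1L, floor(row - 4 * sigma))
  r1 <- min(h, ceiling(row + 4 * sigma))
  c0 <- max(1L, floor(col - 4 * sigma))
  c1 <- min(w, ceiling(col + 4 * sigma))
  if (r0 > r1 || c0 > c1) return(field)
  rr <- r0:r1
  cc <- c0:c1
  gr <- exp(-((rr - row)^2) / (2 * sigma^2))
  gc <- exp(-((cc - col)^2) / (2 * sigma^2))
  field[rr, cc] <- field[rr, cc] + amplitude * outer(gr, gc)
  field
}

# Sigmoid-edged disc (flat top, soft ~1 px edge), additive.
add_disc <- function(field, row, col, radius, amplitude, edge = 1) {
  h <- nrow(field)
  w <- ncol(field)
  r0 <- max(1L, floor(row - radius - 4 * edge))
  r1 <- min(h, ceiling(row + radius + 4 * edge))
  c0 <- max(1L, floor(col - radius - 4 * edge))
  c1 <- min(w, ceiling(col + radius + 4 * edge))
  if (r0 > r1 || c0 > c1) return(field)
  rr <- r0:r1
  cc <- c0:c1
  d <- sqrt(outer((rr - row)^2, (cc - col)^2, "+"))
  field[rr, cc] <- field[rr, cc] + amplitude / (1 + exp((d - radius) / edge))
  field
}

# Rejection-sample `n` centres inside a [margin, dim - margin] box with
# pairwise separation >= min_sep.  Errors when the field is too crowded.
sample_centres <- function(n, field_size, margin, min_sep, max_tries = 5000L) {
  if (n == 0) {
    return(tibble(row = numeric(0), col = numeric(0)))
  }
  lo_r <- margin
  hi_r <- field_size[1] - margin
  lo_c <- margin
  hi_c <- field_size[2] - margin
  if (hi_r <= lo_r || hi_c <= lo_c) {
    abort("field too small for the requested object size")
  }
  rows <- numeric(n)
  cols <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- runif(1, lo_r, hi_r)
      c <- runif(1, lo_c, hi_c)
      if (i == 1L ||
          min((rows[seq_len(i - 1)] - r)^2 + (cols[seq_len(i - 1)] - c)^2) >=
            min_sep^2) {
        rows[i] <- r
        cols[i] <- c
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort("could not place all objects without overlap; field too crowded")
    }
  }
  tibble(row = rows, col = cols)
}

add_noise <- function(image, gaussian_sigma = 0, poisson = FALSE) {
  if (isTRUE(poisson)) {
    image <- matrix(
      rpois(length(image), lambda = pmax(image, 0)),
      nrow = nrow(image)
    )
  }
  if (gaussian_sigma > 0) {
    image <- image + rnorm(length(image), sd = gaussian_sigma)
  }
  pmax(image, 0)
}
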