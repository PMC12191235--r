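#' Simulate a flow-cytometry event table
#'
#' Generates the CSV-export shape of an sEV-uptake experiment: a log-normal
#' unstained cell population, a stained population shifted `shift_factor`
#' fold in fluorescence (halved per completed cell division when
#' `division_peaks > 1`, the CFDA dye-dilution pattern), and a low-FSC/SSC
#' debris cluster. The matching unstained reference sample (for gate
#' placement) is the same table with `stained_fraction = 0`.
#'
#' @param n_events Number of events; must be positive.
#' @param stained_fraction Fraction of (non-debris) cells that carry dye.
#' @param shift_factor Multiplicative fluorescence shift of undivided stained
#'   cells relative to unstained; must exceed 1.
#' @param division_peaks Number of stained generations: peak `k` sits at
#'   `shift_factor / 2^(k-1)` (k = 1 .. division_peaks, equal proportions).
#' @param debris_fraction Fraction of events that are debris (low FSC/SSC,
#'   ~10% of cell forward scatter).
#' @param seed RNG seed.
#'
#' @return List with `events` (tibble: `fsc`, `ssc`, `fluor`) and `truth`
#'   (tibble: per-event `label` = debris/unstained/stained, `division`
#'   generation for stained events, plus attributes of the draw).
#' @export
sim_flow_events <- function(n_events = 10000,
                            stained_fraction = 0.5,
                            shift_factor = 100,
                            division_peaks = 1,
                            debris_fraction = 0.05,
                            seed = 1L) {
  if (n_events <= 0) abort("`n_events` must be positive")
  if (stained_fraction < 0 || stained_fraction > 1) {
    abort("`stained_fraction` must lie in [0, 1]")
  }
  if (shift_factor <= 1) abort("`shift_factor` must be > 1")
  if (division_peaks < 1) abort("`division_peaks` must be >= 1")
  with_rng_seed(seed, {
    is_debris <- runif(n_events) < debris_fraction
    n_cells <- sum(!is_debris)
    stained <- rep(FALSE, n_events)
    stained[!is_debris] <- runif(n_cells) < stained_fraction
    division <- rep(NA_integer_, n_events)
    division[stained] <- sample.int(division_peaks, sum(stained),
                                    replace = TRUE)
    base_fluor <- rlnorm(n_events, log(100), 0.35)
    fluor <- base_fluor
    fluor[stained] <- base_fluor[stained] *
      shift_factor / 2^(division[stained] - 1)
    fsc <- ifelse(is_debris,
                  rlnorm(n_events, log(5e3), 0.30),
                  rlnorm(n_events, log(5e4), 0.15))
    ssc <- ifelse(is_debris,
                  rlnorm(n_events, log(3e3), 0.30),
                  rlnorm(n_events, log(3e4), 0.20))
    list(
      events = tibble(fsc = fsc, ssc = ssc, fluor = fluor),
      truth = tibble(
        label = dplyr::case_when(
          is_debris ~ "debris",
          stained ~ "stained",
          TRUE ~ "unstained"
        ),
        division = division
      )
    )
  })
}
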