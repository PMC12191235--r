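#' Simulate a mitochondrial stress-test OCR trace
#'
#' Produces the four-phase oxygen-consumption-rate trace of a Seahorse-style
#' assay: basal measurements, then responses to sequential injections of
#' oligomycin (ATP-synthase inhibition), FCCP (uncoupling, maximal
#' respiration) and rotenone/antimycin A (non-mitochondrial floor). The
#' ground truth carries the noiseless respiration metrics that
#' [seahorse_metrics()] should recover.
#'
#' @param basal_ocr Basal OCR plateau (pmol/min).
#' @param oligo_ocr Post-oligomycin plateau.
#' @param fccp_max_ocr Post-FCCP (maximal) plateau; must be >= `basal_ocr`.
#' @param nonmito_ocr Post-rotenone/antimycin floor; `basal_ocr` must exceed
#'   it.
#' @param n_per_phase Measurements per phase (>= 1).
#' @param noise_sigma Gaussian measurement noise sd.
#' @param interval_min Minutes between measurements.
#' @param seed RNG seed.
#'
#' @return List with `trace` (tibble: `measurement`, `time_min`, `ocr`,
#'   `phase` in canonical order basal/oligomycin/fccp/rot_aa) and `truth`
#'   (tibble of the noiseless metrics: basal and maximal respiration above
#'   the non-mitochondrial floor, absolute spare capacity and spare capacity
#'   as percent of baseline).
#' @export
#' @examples
#' sim_ocr_trace(100, 40, 180, 20, noise_sigma = 0)$truth
sim_ocr_trace <- function(basal_ocr = 100,
                          oligo_ocr = 40,
                          fccp_max_ocr = 180,
                          nonmito_ocr = 20,
                          n_per_phase = 3,
                          noise_sigma = 3,
                          interval_min = 6.5,
                          seed = 1L) {
  if (!(basal_ocr > nonmito_ocr && nonmito_ocr >= 0)) {
    abort("require basal_ocr > nonmito_ocr >= 0")
  }
  if (fccp_max_ocr < basal_ocr) abort("require fccp_max_ocr >= basal_ocr")
  if (n_per_phase < 1) abort("need at least 1 measurement per phase")
  levels <- c(basal = basal_ocr, oligomycin = oligo_ocr,
              fccp = fccp_max_ocr, rot_aa = nonmito_ocr)
  with_rng_seed(seed, {
    phase <- rep(names(levels), each = n_per_phase)
    n <- length(phase)
    ocr <- rep(unname(levels), each = n_per_phase)
    if (noise_sigma > 0) ocr <- ocr + rnorm(n, sd = noise_sigma)
    basal_resp <- basal_ocr - nonmito_ocr
    maximal_resp <- fccp_max_ocr - nonmito_ocr
    spare <- maximal_resp - basal_resp
    list(
      trace = tibble(
        measurement = seq_len(n),
        time_min = (seq_len(n) - 1) * interval_min,
        ocr = ocr,
        phase = factor(phase, levels = names(levels))
      ),
      truth = tibble(
        basal_resp = basal_resp,
        maximal_resp = maximal_resp,
        spare_abs = spare,
        spare_pct = 100 * spare / basal_resp,
        nonmito = nonmito_ocr
      )
    )
  })
}
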