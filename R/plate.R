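#' Blank- and control-normalized viability
#'
#' Luminescence viability readout normalized to the unirradiated (0 Gy)
#' control after blank subtraction:
#' `100 * (treated - blank) / (zero_dose - blank)`. Replicate wells of each
#' role are averaged before normalization. The result is invariant to any
#' affine rescaling of the luminometer (gain and offset cancel).
#'
#' @param lum_treated Luminescence of the treated condition (replicates
#'   averaged).
#' @param lum_blank Media-only blank wells.
#' @param lum_zero_dose Unirradiated control wells.
#' @return Percent viability (scalar).
#' @export
#' @examples
#' normalize_viability(600, 100, 1100) # 50
normalize_viability <- function(lum_treated, lum_blank, lum_zero_dose) {
  treated <- mean(lum_treated)
  blank <- mean(lum_blank)
  zero <- mean(lum_zero_dose)
  if (!(zero > blank)) {
    abort("assay failed: zero-dose control does not exceed blank")
  }
  100 * (treated - blank) / (zero - blank)
}

#' Viability of every condition on a plate
#'
#' Applies [normalize_viability()] across a tidy plate table: replicates are
#' averaged within each group, the `blank` group supplies the blank, the
#' `reference` group the 0 Gy control.
#'
#' @param data Tibble with at least `group` and `lum` columns.
#' @param blank,reference Group labels of the blank and 0 Gy control wells.
#' @return Tibble: `group`, `n_wells`, `viability_pct` (blank and reference
#'   rows included; the reference is 100 by construction).
#' @export
viability_table <- function(data, blank = "blank", reference = "0Gy") {
  stopifnot(is.data.frame(data), all(c("group", "lum") %in% names(data)))
  if (!blank %in% data$group) abort("blank group not found")
  if (!reference %in% data$group) abort("reference group not found")
  lb <- data$lum[data$group == blank]
  lz <- data$lum[data$group == reference]
  data |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_wells = dplyr::n(), .lum = mean(.data$lum),
                     .groups = "drop") |>
    dplyr::mutate(
      viability_pct = purrr::map_dbl(.data$.lum, normalize_viability,
                                     lum_blank = lb, lum_zero_dose = lz)
    ) |>
    dplyr::select("group", "n_wells", "viability_pct")
}

#' Count and measure colonies in a plate scan
#'
#' Colony quantification chain: rolling-ball background subtraction,
#' thresholding (manual value, mirroring the original ImageJ workflow, or
#' Otsu as a reproducible default), 8-connected labeling with a colony-scale
#' area floor. Touching colonies are not split; objects whose pixel
#' footprint fills less than `merged_roundness` of their circumscribed
#' circle are flagged as likely merged.
#'
#' @param image Grayscale matrix.
#' @param rolling_ball_radius Background ball radius, px.
#' @param threshold `"otsu"` or a manual numeric threshold.
#' @param min_area_px Minimum colony area.
#' @param merged_roundness Fill-fraction below which an object is flagged.
#' @param pixel_size Optional micrometres per pixel; adds `area_um2`.
#' @param max_foreground_fraction In Otsu mode, a candidate foreground
#'   covering more than this fraction of the plate means there is nothing
#'   to threshold (blank plate); treated as zero colonies.
#' @return Tibble of colonies: `id`, `row`, `col`, `area_px`,
#'   (`area_um2`,) `roundness`, `flag_merged`. The colony count is the row
#'   count.
#' @export
quantify_colonies <- function(image,
                              rolling_ball_radius = 50,
                              threshold = "otsu",
                              min_area_px = 50,
                              merged_roundness = 0.75,
                              pixel_size = NA_real_,
                              max_foreground_fraction = 0.3) {
  check_image(image)
  sub <- rolling_ball(image, rolling_ball_radius)
  mask <- auto_mask(sub, threshold, max_foreground_fraction)
  objects <- label_objects(mask, min_area_px)
  obj <- objects$objects
  if (nrow(obj) == 0) {
    return(tibble(id = integer(0), row = numeric(0), col = numeric(0),
                  area_px = integer(0), roundness = numeric(0),
                  flag_merged = logical(0)))
  }
  lab <- objects$labels
  idx <- which(lab > 0)
  l <- lab[idx]
  rr <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  rmax2 <- vapply(obj$id, function(i) {
    sel <- l == i
    max((rr[sel] - obj$row[i])^2 + (cc[sel] - obj$col[i])^2)
  }, numeric(1))
  roundness <- obj$area / (pi * pmax(rmax2, 1))
  out <- tibble(
    id = obj$id, row = obj$row, col = obj$col, area_px = obj$area,
    roundness = roundness,
    flag_merged = roundness < merged_roundness
  )
  if (!is.na(pixel_size)) {
    out$area_um2 <- out$area_px * pixel_size^2
  }
  out
}

#' Remove debris events by a forward/side-scatter gate
#'
#' Rectangular singlet gate: events below the FSC or SSC minimum are treated
#' as debris and removed. Defaults match the debris cluster of
#' [sim_flow_events()] (debris sits near 10% of cell forward scatter).
#'
#' @param events Tibble with `fsc` and `ssc` columns.
#' @param fsc_min,ssc_min Lower gate bounds.
#' @return The gated events tibble.
#' @export
gate_singlets <- function(events, fsc_min = 15000, ssc_min = 8000) {
  stopifnot(is.data.frame(events),
            all(c("fsc", "ssc") %in% names(events)))
  if (nrow(events) == 0) abort("empty event table")
  dplyr::filter(events, .data$fsc >= fsc_min, .data$ssc >= ssc_min)
}

#' Gate fluorescence-positive events against an unstained reference
#'
#' The positivity gate is a high percentile (default 99th) of the unstained
#' reference sample's fluorescence; events above it are positive. Mean
#' fluorescence intensity (MFI) is reported for all events and for positives
#' only, as arithmetic mean by default (geometric available). The positive
#' fraction is invariant to a common multiplicative gain applied to both
#' events and reference.
#'
#' @param events Singlet-gated events tibble with a `fluor` column.
#' @param unstained_reference Singlet-gated unstained reference events.
#' @param percentile Reference percentile defining the gate.
#' @param mfi `"arithmetic"` or `"geometric"` mean.
#' @return One-row tibble: `gate`, `positive_fraction`, `mfi_all`,
#'   `mfi_positive`, `n_events`.
#' @export
gate_positive <- function(events, unstained_reference, percentile = 99,
                          mfi = c("arithmetic", "geometric")) {
  mfi <- match.arg(mfi)
  stopifnot(is.data.frame(events), "fluor" %in% names(events))
  if (nrow(events) == 0) abort("empty event table")
  if (!is.data.frame(unstained_reference) ||
      nrow(unstained_reference) == 0) {
    abort("empty unstained reference")
  }
  gate <- quantile(unstained_reference$fluor, percentile / 100,
                   names = FALSE)
  pos <- events$fluor > gate
  avg <- function(v) {
    if (length(v) == 0) return(NA_real_)
    if (mfi == "arithmetic") mean(v) else exp(mean(log(v)))
  }
  tibble(
    gate = gate,
    positive_fraction = mean(pos),
    mfi_all = avg(events$fluor),
    mfi_positive = avg(events$fluor[pos]),
    n_events = nrow(events)
  )
}

#' Extracellular-vesicle dose in particles per cell
#'
#' Functional sEV doses are expressed as particles per cell:
#' `concentration * volume / n_cells`. With `volume = 1` the first argument
#' is the total particle count.
#'
#' @param particle_concentration Particles per unit volume (or total
#'   particles when `volume = 1`).
#' @param volume Dosed volume.
#' @param n_cells Cells receiving the dose (> 0).
#' @return Particles per cell.
#' @export
#' @examples
#' sev_dose(1e8, 1, 2e4) # 5000
sev_dose <- function(particle_concentration, volume = 1, n_cells) {
  if (any(n_cells <= 0)) abort("`n_cells` must be positive")
  particle_concentration * volume / n_cells
}

#' Mitochondrial stress-test metrics from an OCR trace
#'
#' Respiration metrics of the four-phase mitochondrial stress test. The
#' non-mitochondrial floor is the mean of the rotenone/antimycin phase and
#' is subtracted from everything else; basal respiration uses the last
#' pre-injection (basal-phase) measurement; maximal respiration is the peak
#' of the FCCP phase; spare capacity is maximal minus basal, also expressed
#' as percent of basal.
#'
#' @param trace Tibble with `ocr` and `phase` columns; `phase` must contain
#'   the canonical phases `basal`, `oligomycin`, `fccp`, `rot_aa` in that
#'   order, each with at least one measurement.
#' @return One-row tibble: `nonmito`, `basal_resp`, `maximal_resp`,
#'   `spare_abs`, `spare_pct`.
#' @export
#' @examples
#' seahorse_metrics(sim_ocr_trace(100, 40, 180, 20, noise_sigma = 0)$trace)
seahorse_metrics <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("ocr", "phase") %in% names(trace)))
  canonical <- c("basal", "oligomycin", "fccp", "rot_aa")
  phase <- as.character(trace$phase)
  if (!all(canonical %in% phase)) {
    abort("all four phases (basal, oligomycin, fccp, rot_aa) are required")
  }
  first_idx <- vapply(canonical, function(p) min(which(phase == p)),
                      numeric(1))
  if (is.unsorted(first_idx)) {
    abort("phases must appear in canonical injection order")
  }
  nonmito <- mean(trace$ocr[phase == "rot_aa"])
  basal_last <- trace$ocr[max(which(phase == "basal"))]
  basal_resp <- basal_last - nonmito
  if (basal_resp <= 0) {
    abort("trace invalid: basal does not exceed the non-mitochondrial floor")
  }
  maximal_resp <- max(trace$ocr[phase == "fccp"]) - nonmito
  spare <- maximal_resp - basal_resp
  tibble(
    nonmito = nonmito,
    basal_resp = basal_resp,
    maximal_resp = maximal_resp,
    spare_abs = spare,
    spare_pct = 100 * spare / basal_resp
  )
}
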