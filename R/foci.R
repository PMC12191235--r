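#' Per-cell background of a foci image
#'
#' Robust per-compartment background: the median of in-mask pixel
#' intensities after excluding the brightest 5% (so a handful of bright
#' puncta cannot inflate the estimate). Computed per cell because reporter
#' expression varies from cell to cell.
#'
#' @param image Numeric matrix (the foci channel).
#' @param compartments A `labeled_objects` (from [segment_cells_red()] or
#'   [segment_nuclei()]) or an integer label matrix.
#' @return Tibble: `id`, `background`.
#' @export
estimate_background <- function(image, compartments) {
  check_image(image)
  lab <- if (inherits(compartments, "labeled_objects")) {
    compartments$labels
  } else {
    compartments
  }
  stopifnot(is.matrix(lab), identical(dim(lab), dim(image)))
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) abort("empty mask: no compartments")
  bg <- vapply(ids, function(i) {
    v <- image[lab == i]
    cut <- quantile(v, 0.95, names = FALSE)
    median(v[v <= cut])
  }, numeric(1))
  tibble(id = as.integer(ids), background = bg)
}

#' Detect DNA-damage foci within cell or nuclear compartments
#'
#' Candidate puncta are 8-connected components of pixels whose intensity is
#' at least `contrast_factor` times the background of their compartment
#' (default 10, the "order of magnitude above background" acceptance rule),
#' with area inside `[min_punctum_area_px, max_punctum_area_px]`. Each
#' punctum is assigned to the compartment holding the majority of its
#' pixels; pixels outside all compartments never seed a punctum. Because the
#' rule is a ratio to background, counts are invariant to a global gain on
#' the image.
#'
#' @param image Foci channel matrix.
#' @param compartments `labeled_objects` defining per-cell compartments
#'   (red-channel cell masks for 53BP1, DAPI nuclear masks for gamma-H2AX).
#' @param contrast_factor Intensity-to-background acceptance ratio (> 1).
#' @param min_punctum_area_px,max_punctum_area_px Punctum area bounds;
#'   components outside them are rejected (hot pixels, saturated nuclei).
#' @param marker,timepoint,group Metadata stamped onto the records.
#' @return Tibble of foci records, one row per compartment: `cell_id`,
#'   `marker`, `timepoint`, `group`, `count`, and `puncta` (a list-column of
#'   per-punctum tibbles: `row`, `col`, `area`, `peak`, `contrast`).
#' @export
detect_foci <- function(image, compartments, contrast_factor = 10,
                        min_punctum_area_px = 2, max_punctum_area_px = 50,
                        marker = "gH2AX", timepoint = NA_real_,
                        group = NA_character_) {
  check_image(image)
  if (contrast_factor <= 1) abort("`contrast_factor` must be > 1")
  lab <- if (inherits(compartments, "labeled_objects")) {
    compartments$labels
  } else {
    compartments
  }
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) abort("no compartments supplied")
  bg <- estimate_background(image, lab)
  thr_of <- setNames(contrast_factor * bg$background, bg$id)
  cand <- matrix(FALSE, nrow(image), ncol(image))
  inmask <- lab > 0
  cand[inmask] <- image[inmask] >= thr_of[as.character(lab[inmask])]
  comp <- label_objects(cand, min_area_px = max(1, min_punctum_area_px))
  puncta_by_cell <- setNames(
    vector("list", length(ids)), as.character(ids)
  )
  if (nrow(comp$objects) > 0) {
    pl <- comp$labels
    for (pid in comp$objects$id) {
      idx <- which(pl == pid)
      area <- length(idx)
      if (area > max_punctum_area_px) next
      owners <- lab[idx]
      owner <- as.integer(names(which.max(table(owners[owners > 0]))))
      peak <- max(image[idx])
      rr <- ((idx - 1L) %% nrow(pl)) + 1L
      cc <- ((idx - 1L) %/% nrow(pl)) + 1L
      rec <- tibble(
        row = mean(rr), col = mean(cc), area = area, peak = peak,
        contrast = peak / unname(thr_of[as.character(owner)]) *
          contrast_factor
      )
      key <- as.character(owner)
      puncta_by_cell[[key]] <- dplyr::bind_rows(puncta_by_cell[[key]], rec)
    }
  }
  empty <- tibble(row = numeric(0), col = numeric(0), area = integer(0),
                  peak = numeric(0), contrast = numeric(0))
  puncta <- lapply(puncta_by_cell, function(p) p %||% empty)
  tibble(
    cell_id = as.integer(ids),
    marker = marker,
    timepoint = timepoint,
    group = group,
    count = unname(vapply(puncta, nrow, integer(1))),
    puncta = unname(puncta)
  )
}

#' Summarise foci counts per group and timepoint
#'
#' Mean and standard error of puncta per cell in each (group, timepoint)
#' stratum. The SEM is reported as `NA` for strata with a single cell.
#' Summarisation preserves totals: the per-stratum `n * mean` values sum to
#' the total punctum count of the input.
#'
#' @param records Foci records ([detect_foci()] output, or any tibble with
#'   `group`, `timepoint`, `count`).
#' @param schedule Optional vector of expected timepoints; an error is
#'   raised if a scheduled timepoint has no records.
#' @return Tibble: `group`, `timepoint`, `n`, `mean_count`, `sem`.
#' @export
foci_timecourse <- function(records, schedule = NULL) {
  stopifnot(is.data.frame(records),
            all(c("group", "timepoint", "count") %in% names(records)))
  if (!is.null(schedule)) {
    missing <- setdiff(schedule, unique(records$timepoint))
    if (length(missing) > 0) {
      abort(sprintf("no records at scheduled timepoint(s): %s",
                    paste(missing, collapse = ", ")))
    }
  }
  records |>
    dplyr::group_by(.data$group, .data$timepoint) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_count = mean(.data$count),
      sem = if (dplyr::n() > 1) {
        sd(.data$count) / sqrt(dplyr::n())
      } else {
        NA_real_
      },
      .groups = "drop"
    )
}

#' Compare foci counts between treatment groups
#'
#' One-way ANOVA across groups at a single timepoint, or two-way ANOVA
#' (group x timepoint) for a timecourse, followed by Tukey HSD pairwise
#' comparisons — the group-comparison design of the foci assays. When the
#' between-group sum of squares is exactly zero (identical group means) the
#' F statistic is reported as 0 with p = 1: no between-group variation is no
#' evidence of a difference, even when the within-group variance is also
#' zero.
#'
#' @param records Foci records with `group`, `count` and (for `two_way`)
#'   `timepoint`.
#' @param design `"one_way"` or `"two_way"`.
#' @return Object of class `foci_tests`: list with `anova` (tibble of the
#'   ANOVA table) and `tukey` (tibble of Tukey HSD group contrasts).
#' @export
compare_counts <- function(records, design = c("one_way", "two_way")) {
  design <- match.arg(design)
  stopifnot(is.data.frame(records),
            all(c("group", "count") %in% names(records)))
  counts_by_group <- table(records$group)
  if (length(counts_by_group) < 2) abort("need at least two groups")
  if (any(counts_by_group < 2)) abort("need at least two cells per group")
  d <- records
  d$group <- factor(d$group)
  fit <- if (design == "one_way") {
    if ("timepoint" %in% names(d) &&
        length(unique(d$timepoint)) > 1) {
      abort("one_way design requires a single timepoint; use two_way")
    }
    aov(count ~ group, data = d)
  } else {
    if (!"timepoint" %in% names(d)) abort("two_way design needs `timepoint`")
    d$timepoint <- factor(d$timepoint)
    aov(count ~ group * timepoint, data = d)
  }
  tab <- summary(fit)[[1]]
  anova_tbl <- tibble(
    term = trimws(rownames(tab)),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p.value = tab$`Pr(>F)`
  )
  # zero between-group variation: define F = 0, p = 1 (0/0 otherwise);
  # assessed relative to the total SS so constant data count as zero
  tot_ss <- sum((d$count - mean(d$count))^2)
  degenerate <- !is.na(anova_tbl$sumsq) &
    anova_tbl$sumsq <= 1e-12 * max(tot_ss, 1) &
    anova_tbl$term != "Residuals"
  anova_tbl$statistic[degenerate] <- 0
  anova_tbl$p.value[degenerate] <- 1
  tukey <- tryCatch({
    tk <- TukeyHSD(fit, which = "group")$group
    tibble(
      contrast = rownames(tk),
      estimate = tk[, "diff"],
      conf.low = tk[, "lwr"],
      conf.high = tk[, "upr"],
      p.adjusted = tk[, "p adj"]
    )
  }, error = function(e) NULL)
  structure(list(anova = anova_tbl, tukey = tukey, design = design),
            class = "foci_tests")
}

#' @export
print.foci_tests <- function(x, ...) {
  cat(sprintf("<foci_tests> %s ANOVA\n", x$design))
  print(x$anova)
  if (!is.null(x$tukey)) {
    cat("Tukey HSD (group):\n")
    print(x$tukey)
  }
  invisible(x)
}

#' @rdname compare_counts
#' @param x A `foci_tests` object.
#' @param ... Unused.
#' @method tidy foci_tests
#' @export
tidy.foci_tests <- function(x, ...) x$anova

#' @rdname compare_counts
#' @method glance foci_tests
#' @export
glance.foci_tests <- function(x, ...) {
  g <- x$anova[x$anova$term == "group", ]
  tibble(statistic = g$statistic, df = g$df, p.value = g$p.value,
         design = x$design)
}
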