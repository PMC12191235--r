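#' Kaplan-Meier survival curves from fate records
#'
#' Product-limit estimator computed per group:
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`, where `d_i`
#' is the number of deaths at `t_i` and `n_i` the number of cells still at
#' risk. Censored cells leave the risk set after their censoring time. A
#' baseline row at time 0 with `S = 1` is included for each group.
#'
#' @param fates Tibble of fate records as returned by [call_fates()]:
#'   columns `time`, `status` (`"event"`/`"censored"`) and optionally
#'   `group`.
#' @return A tibble of class `km_curve`: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @export
#' @examples
#' fates <- tibble::tibble(
#'   time = c(6, 12, 18, 18),
#'   status = c("event", "event", "event", "censored")
#' )
#' km_curve(fates)
km_curve <- function(fates) {
  stopifnot(is.data.frame(fates),
            all(c("time", "status") %in% names(fates)))
  if (nrow(fates) == 0) abort("need at least one fate record")
  if (!all(fates$status %in% c("event", "censored"))) {
    abort("`status` must be 'event' or 'censored'")
  }
  if (!"group" %in% names(fates)) fates$group <- "all"
  out <- fates |>
    dplyr::group_by(.data$group) |>
    dplyr::group_map(function(d, key) {
      times <- sort(unique(d$time))
      n_risk <- integer(length(times))
      n_event <- integer(length(times))
      n_cens <- integer(length(times))
      at_risk <- nrow(d)
      surv <- numeric(length(times))
      s <- 1
      for (i in seq_along(times)) {
        ti <- times[i]
        d_i <- sum(d$time == ti & d$status == "event")
        c_i <- sum(d$time == ti & d$status == "censored")
        n_risk[i] <- at_risk
        n_event[i] <- d_i
        n_cens[i] <- c_i
        if (d_i > 0) s <- s * (1 - d_i / at_risk)
        surv[i] <- s
        at_risk <- at_risk - d_i - c_i
      }
      base <- if (!0 %in% times) {
        tibble(group = key$group, time = 0, n_risk = nrow(d),
               n_event = 0L, n_censor = 0L, survival = 1)
      } else {
        NULL
      }
      dplyr::bind_rows(base, tibble(
        group = key$group, time = times, n_risk = n_risk,
        n_event = n_event, n_censor = n_cens, survival = surv
      ))
    }) |>
    dplyr::bind_rows()
  class(out) <- c("km_curve", class(out))
  out
}

# Log-rank observed/expected/variance bookkeeping for a two-column
# (time, status) frame split by a group factor.  Returns the k-vector of
# observed and expected events and the (k x k) covariance matrix.
logrank_oe <- function(time, event, group) {
  groups <- sort(unique(group))
  k <- length(groups)
  ev_times <- sort(unique(time[event]))
  O <- setNames(numeric(k), groups)
  E <- setNames(numeric(k), groups)
  V <- matrix(0, k, k, dimnames = list(groups, groups))
  for (tj in ev_times) {
    at_risk <- time >= tj
    n_j <- sum(at_risk)
    d_j <- sum(event & time == tj)
    if (n_j == 0 || d_j == 0) next
    n_gj <- vapply(groups, function(g) sum(at_risk & group == g), numeric(1))
    d_gj <- vapply(groups, function(g) sum(event & time == tj & group == g),
                   numeric(1))
    O <- O + d_gj
    E <- E + d_j * n_gj / n_j
    if (n_j > 1) {
      # hypergeometric covariance with ties pooled at identical times
      f <- d_j * (n_j - d_j) / (n_j - 1)
      p <- n_gj / n_j
      V <- V + f * (diag(p, nrow = k) - outer(p, p))
    }
  }
  list(groups = groups, observed = O, expected = E, covariance = V)
}

logrank_stat <- function(time, event, group) {
  oe <- logrank_oe(time, event, group)
  k <- length(oe$groups)
  z <- (oe$observed - oe$expected)[-k]
  Vsub <- oe$covariance[-k, -k, drop = FALSE]
  stat <- tryCatch(
    drop(t(z) %*% solve(Vsub, z)),
    error = function(e) drop(t(z) %*% MASS::ginv(Vsub) %*% z)
  )
  list(statistic = stat, df = k - 1L, oe = oe)
}

# Exact conditional p for the two-group log-rank statistic: enumerate every
# assignment of group labels to subjects (fixed group sizes) and count how
# often the statistic reaches the observed one.  Only feasible for tiny
# cohorts; the chi-square approximation is poor exactly there.
logrank_exact_p <- function(time, event, group) {
  groups <- sort(unique(group))
  n <- length(time)
  n1 <- sum(group == groups[1])
  obs <- logrank_stat(time, event, group)$statistic
  sets <- utils::combn(n, n1)
  stats <- vapply(seq_len(ncol(sets)), function(j) {
    g <- rep(groups[2], n)
    g[sets[, j]] <- groups[1]
    logrank_stat(time, event, g)$statistic
  }, numeric(1))
  mean(stats >= obs - 1e-12)
}

#' Log-rank test between survival curves
#'
#' Standard log-rank test over the pooled distinct event times: at each event
#' time, the observed deaths per group are compared with the expectation
#' under a common hazard, with hypergeometric variance (ties pooled at
#' identical times). With more than two groups the statistic is the
#' quadratic form over the first `k - 1` groups. When `reference` is given,
#' pairwise tests of each other group against the reference are reported
#' both unadjusted and Bonferroni-adjusted.
#'
#' For tiny two-group cohorts the chi-square reference distribution is a
#' poor approximation, so by default (`exact = "auto"`) the p-value is then
#' computed exactly, by complete enumeration of the group-label assignments
#' conditional on the group sizes (the permutation null of the statistic);
#' `p.method` records which reference distribution produced the p-value.
#' The statistic itself is always the classical one.
#'
#' @param fates Fate records (see [km_curve()]) with a `group` column of at
#'   least two levels and at least one event overall.
#' @param reference Optional reference (control) group for pairwise dose
#'   comparisons.
#' @param exact `"auto"` (exact enumeration for two groups when the number
#'   of label assignments is at most `max_exact`), `"never"`, or
#'   `"always"` (error if infeasible).
#' @param max_exact Assignment-count ceiling for the exact mode (default
#'   5000, i.e. cohorts of about 14 cells).
#' @return Object of class `logrank_test`: `statistic`, `df`, `p.value`,
#'   `p.method` (`"chisq"` or `"exact"`), per-group observed/expected
#'   counts, and optionally `pairwise` (tibble: `group`, `statistic`,
#'   `p.value`, `p.adjusted`).
#' @export
logrank <- function(fates, reference = NULL,
                    exact = c("auto", "never", "always"),
                    max_exact = 5000) {
  exact <- match.arg(exact)
  stopifnot(is.data.frame(fates),
            all(c("time", "status", "group") %in% names(fates)))
  groups <- unique(fates$group)
  if (length(groups) < 2) abort("need at least two groups")
  event <- fates$status == "event"
  if (!any(event)) abort("no events; test undefined")
  res <- logrank_stat(fates$time, event, fates$group)
  n_assign <- if (length(groups) == 2) {
    choose(nrow(fates), sum(fates$group == groups[1]))
  } else {
    Inf
  }
  use_exact <- switch(exact,
    never = FALSE,
    always = {
      if (n_assign > max_exact) {
        abort("exact log-rank infeasible: too many label assignments")
      }
      TRUE
    },
    auto = n_assign <= max_exact
  )
  pairwise <- NULL
  if (!is.null(reference)) {
    if (!reference %in% groups) abort("`reference` is not a group level")
    others <- setdiff(groups, reference)
    pairwise <- purrr::map_dfr(others, function(g) {
      sub <- fates[fates$group %in% c(reference, g), ]
      r <- logrank_stat(sub$time, sub$status == "event", sub$group)
      tibble(group = g, statistic = r$statistic, df = r$df,
             p.value = pchisq(r$statistic, r$df, lower.tail = FALSE))
    })
    pairwise$p.adjusted <- pmin(1, pairwise$p.value * nrow(pairwise))
  }
  p.value <- if (use_exact) {
    logrank_exact_p(fates$time, event, fates$group)
  } else {
    pchisq(res$statistic, res$df, lower.tail = FALSE)
  }
  structure(
    list(
      statistic = res$statistic,
      df = res$df,
      p.value = p.value,
      p.method = if (use_exact) "exact" else "chisq",
      observed = res$oe$observed,
      expected = res$oe$expected,
      groups = res$oe$groups,
      pairwise = pairwise,
      n = nrow(fates),
      n_events = sum(event)
    ),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf(
    "Log-rank test: chi-square = %.4g on %d df, p = %.3g (n = %d, events = %d)\n",
    x$statistic, x$df, x$p.value, x$n, x$n_events
  ))
  tab <- tibble(group = x$groups, observed = unname(x$observed),
                expected = unname(x$expected))
  print(tab)
  if (!is.null(x$pairwise)) {
    cat("Pairwise vs reference:\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' @rdname logrank
#' @param x A `logrank_test` object.
#' @param ... Unused.
#' @method tidy logrank_test
#' @export
tidy.logrank_test <- function(x, ...) {
  if (!is.null(x$pairwise)) {
    x$pairwise
  } else {
    tibble(group = x$groups, observed = unname(x$observed),
           expected = unname(x$expected))
  }
}

#' @rdname logrank
#' @method glance logrank_test
#' @export
glance.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         p.method = x$p.method, n = x$n, n_events = x$n_events)
}
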