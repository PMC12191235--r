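# Independent oracles used to check the package's own implementations.
# These deliberately use brute force / enumeration, not the code paths they
# validate.

# Exhaustive-scan Otsu: maximise between-class variance over every midpoint
# between consecutive sorted unique pixel values.
oracle_otsu <- function(v) {
  u <- sort(unique(as.vector(v)))
  cuts <- (head(u, -1) + tail(u, -1)) / 2
  bcv <- vapply(cuts, function(th) {
    lo <- v[v < th]
    hi <- v[v >= th]
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  cuts[which.max(bcv)]
}

# Exhaustive-scan misclassification-minimising cut between two samples
# (dead called when ratio > theta), scanning every sample value as cut.
oracle_calibration_cut <- function(baseline, lethal) {
  cand <- sort(unique(c(baseline, lethal)))
  errs <- vapply(cand, function(th) {
    sum(baseline > th) + sum(lethal <= th)
  }, numeric(1))
  cand[which.min(errs)]
}

# Hand product-limit estimator on (time, event) pairs, no grouping.
oracle_km <- function(time, event, at) {
  ev_times <- sort(unique(time[event]))
  s <- 1
  for (tj in ev_times[ev_times <= at]) {
    n_j <- sum(time >= tj)
    d_j <- sum(event & time == tj)
    s <- s * (1 - d_j / n_j)
  }
  s
}

# Monte-Carlo permutation p-value for the two-group log-rank statistic:
# permute group labels, recompute the statistic with the package's own
# statistic function, compare to the analytic chi-square p.
oracle_logrank_perm_p <- function(fates, n_perm = 1e5, seed = 42) {
  obs <- radassay:::logrank_stat(
    fates$time, fates$status == "event", fates$group
  )$statistic
  withr::with_seed(seed, {
    ge <- replicate(n_perm, {
      g <- sample(fates$group)
      radassay:::logrank_stat(fates$time, fates$status == "event",
                              g)$statistic >= obs - 1e-12
    })
    mean(ge)
  })
}

# Greedy matching of detected object centroids to truth centroids within a
# tolerance radius; returns the truth row index per object (NA = unmatched).
match_to_truth <- function(obj_row, obj_col, truth_row, truth_col,
                           max_dist = 10) {
  vapply(seq_along(obj_row), function(i) {
    d2 <- (truth_row - obj_row[i])^2 + (truth_col - obj_col[i])^2
    j <- which.min(d2)
    if (d2[j] <= max_dist^2) j else NA_integer_
  }, integer(1))
}
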