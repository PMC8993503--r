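# Independent brute-force oracles and small fixture builders.

# Naive QRS cluster scanner: walk the sequence sample by sample, collect
# class-3 runs, then merge/filter with explicit loops. Deliberately written
# without rle() so it is independent of the implementation under test.
naive_qrs_oracle <- function(labels, fs, min_dur = 40, merge_gap = 20) {
  runs <- list()
  in_run <- FALSE
  start <- NA_integer_
  for (i in seq_along(labels)) {
    if (labels[i] == 3L && !in_run) {
      in_run <- TRUE
      start <- i - 1L
    } else if (labels[i] != 3L && in_run) {
      runs[[length(runs) + 1L]] <- c(start, i - 1L)
      in_run <- FALSE
    }
  }
  if (in_run) runs[[length(runs) + 1L]] <- c(start, length(labels))
  if (length(runs) == 0) {
    return(data.frame(onset = integer(0), offset = integer(0)))
  }
  gap <- merge_gap / 1000 * fs
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] < gap) {
      merged[[length(merged)]] <- c(last[1], r[2])
    } else {
      merged[[length(merged) + 1L]] <- r
    }
  }
  min_len <- min_dur / 1000 * fs
  keep <- Filter(function(r) (r[2] - r[1]) >= min_len, merged)
  if (length(keep) == 0) {
    return(data.frame(onset = integer(0), offset = integer(0)))
  }
  data.frame(onset = sapply(keep, `[`, 1), offset = sapply(keep, `[`, 2))
}

# Full-grid enumeration of the threshold search, computed from raw counts
# with explicit loops (independent of fit_thresholds()).
naive_grid_enumeration <- function(feats, x_grid, y_grid) {
  out <- expand.grid(y = y_grid, x = x_grid)[, c("x", "y")]
  out$f1 <- NA_real_
  row <- 1L
  for (x in x_grid) {
    for (y in y_grid) {
      tp <- fp <- fn <- 0L
      for (i in seq_len(nrow(feats))) {
        call_af <- feats$p_fraction[i] < x && feats$rr_sd[i] > y
        if (call_af && feats$truth[i] == "AF") tp <- tp + 1L
        if (call_af && feats$truth[i] == "SR") fp <- fp + 1L
        if (!call_af && feats$truth[i] == "AF") fn <- fn + 1L
      }
      out$f1[row] <- if (tp == 0) 0 else {
        s <- tp / (tp + fn)
        p <- tp / (tp + fp)
        2 * s * p / (s + p)
      }
      row <- row + 1L
    }
  }
  out
}

# Random wave-class label sequence with QRS-like runs.
random_label_sequence <- function(n = 2000) {
  labs <- sample(c(0L, 1L, 4L, 5L, 6L), n, replace = TRUE,
                 prob = c(0.4, 0.1, 0.1, 0.2, 0.2))
  n_runs <- sample(0:8, 1)
  for (k in seq_len(n_runs)) {
    start <- sample(n - 80L, 1)
    len <- sample(3:60, 1)
    labs[start:(start + len - 1L)] <- 3L
  }
  labs
}

# Longest-window box of a lead (mirrors the box choice readback makes).
lead_box_for_test <- function(layout, lead) {
  boxes <- layout$leads[layout$leads$lead == lead, ]
  boxes[which.max(boxes$win_s), ]
}

# Minimal hand-built ecg_signal (for render tests that need exact control).
manual_signal <- function(samples, labels, fs = 500) {
  structure(
    list(
      samples = samples, labels = labels,
      config = sample_config(1, overrides = list(
        sampling_rate = fs, duration = ncol(samples) / fs
      )),
      schedule = NULL, rhythm = "SR", phenotype = "NORMAL", clean = TRUE
    ),
    class = "ecg_signal"
  )
}

# Per-beat temporal-ordering check, via the adjacency the class semantics
# imply: each (non-truncated) QRS run is immediately preceded by a P-R run
# which is immediately preceded by a P (or T/P overlap) run under SR, and is
# followed by an ST run and then a T run. This makes the first-sample
# indices of classes 1,2,3,4,5 strictly increasing within the beat.
beat_ordering_ok <- function(lab, rhythm) {
  n <- length(lab)
  ons <- which(diff(c(0L, lab == 3L)) == 1L)
  offs <- which(diff(c(lab == 3L, 0L)) == -1L)
  for (k in seq_along(ons)) {
    q <- ons[k]; qe <- offs[k]
    if (rhythm == "SR" && q > 1L) {
      if (lab[q - 1L] != 2L) return(FALSE)
      s2 <- q - 1L
      while (s2 > 1L && lab[s2 - 1L] == 2L) s2 <- s2 - 1L
      if (s2 > 1L && !lab[s2 - 1L] %in% c(1L, 7L)) return(FALSE)
    }
    if (qe + 1L <= n && lab[qe + 1L] != 4L) return(FALSE)
    s4 <- qe + 1L
    while (s4 < n && lab[s4 + 1L] == 4L) s4 <- s4 + 1L
    # a very early next beat may truncate the T away entirely
    if (s4 + 1L <= n && !lab[s4 + 1L] %in% c(5L, 3L)) return(FALSE)
  }
  TRUE
}
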