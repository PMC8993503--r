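# Rule-based AF vs SR classification from wave-class label sequences:
# QRS cluster detection, R-R dispersion, P-wave search in the pre-QRS
# window, and brute-force threshold fitting on a validation set.

#' Find QRS clusters in a label sequence
#'
#' Scans for maximal runs of the QRS class (code 3), merges runs separated by
#' gaps shorter than `merge_gap` (fragmented complexes in predicted masks),
#' and discards runs shorter than `min_dur` (speckle).
#'
#' @param labels Integer label sequence (codes 0-7).
#' @param fs Sampling rate of the sequence, Hz.
#' @param min_dur Minimum cluster duration, ms (default 40).
#' @param merge_gap Merge runs separated by less than this, ms (default 20).
#' @return Tibble of half-open 0-based clusters: `onset`, `offset`, sorted by
#'   onset (possibly zero rows).
#' @export
#' @examples
#' labs <- rep(0L, 1000); labs[101:140] <- 3L; labs[601:645] <- 3L
#' find_qrs_clusters(labs, fs = 500)
find_qrs_clusters <- function(labels, fs, min_dur = 40, merge_gap = 20) {
  if (any(labels < 0L | labels > 7L)) {
    stop_ecgforge("Labels must be wave-class codes 0-7.", "ecgforge_invalid_argument")
  }
  runs <- label_runs(as.integer(labels), CLASS_QRS)
  if (nrow(runs) == 0) {
    return(tibble::tibble(onset = integer(0), offset = integer(0)))
  }
  gap_samples <- merge_gap / 1000 * fs
  min_samples <- min_dur / 1000 * fs

  onsets <- runs[, "onset"]
  offsets <- runs[, "offset"]
  if (nrow(runs) > 1) {
    keep_on <- c(TRUE, (onsets[-1] - offsets[-length(offsets)]) >= gap_samples)
    group <- cumsum(keep_on)
    onsets <- tapply(onsets, group, min)
    offsets <- tapply(offsets, group, max)
  }
  long_enough <- (offsets - onsets) >= min_samples
  tibble::tibble(onset = as.integer(onsets[long_enough]),
                 offset = as.integer(offsets[long_enough]))
}

#' R-R interval standard deviation
#'
#' Population standard deviation of the successive onset-to-onset intervals
#' of the QRS clusters, in ms. Onset-to-onset is used because segmentation
#' masks delimit the QRS support but do not localise the R peak.
#'
#' @param clusters Tibble from [find_qrs_clusters()] (>= 3 clusters, i.e. at
#'   least two intervals; otherwise an error of class
#'   `ecgforge_insufficient_beats`).
#' @param fs Sampling rate, Hz.
#' @return Standard deviation in ms.
#' @export
rr_sd <- function(clusters, fs) {
  if (nrow(clusters) < 3) {
    stop_ecgforge("Fewer than 3 QRS clusters: R-R dispersion is undefined.",
                  "ecgforge_insufficient_beats")
  }
  rr <- diff(clusters$onset) / fs * 1000
  sqrt(mean((rr - mean(rr))^2))
}

#' Fraction of QRS complexes preceded by a P wave
#'
#' For each QRS cluster, the window `[onset - window, onset)` is searched for
#' a P-wave (class 1) run of at least `min_p_dur`. The first cluster is
#' skipped when its window reaches before the start of the recording.
#'
#' @param labels Integer label sequence.
#' @param clusters [find_qrs_clusters()] output (>= 1 cluster with a full
#'   window; otherwise an error of class `ecgforge_no_eligible_clusters`).
#' @param fs Sampling rate, Hz.
#' @param window Search window before each QRS onset, ms (default 250).
#' @param min_p_dur Minimum qualifying P run, ms (default 20).
#' @return Fraction in `[0, 1]`.
#' @export
p_preceded_fraction <- function(labels, clusters, fs, window = 250,
                                min_p_dur = 20) {
  win_samples <- round(window / 1000 * fs)
  min_p_samples <- min_p_dur / 1000 * fs
  eligible <- clusters$onset - win_samples >= 0L
  if (nrow(clusters) == 0 || !any(eligible)) {
    stop_ecgforge("No QRS cluster has a full pre-QRS search window.",
                  "ecgforge_no_eligible_clusters")
  }
  labels <- as.integer(labels)
  hits <- vapply(clusters$onset[eligible], function(q) {
    seg <- labels[(q - win_samples + 1L):q]
    runs <- label_runs(seg, CLASS_P)
    nrow(runs) > 0 && any(runs[, "offset"] - runs[, "onset"] >= min_p_samples)
  }, logical(1))
  mean(hits)
}

#' Fitted AF decision thresholds
#'
#' Container for the two thresholds of the rule: X, the minimum fraction of
#' QRS complexes preceded by a P wave below which atrial activity is deemed
#' absent, and Y, the R-R standard deviation (ms) above which the rhythm is
#' deemed irregular.
#'
#' @param x_min_p_fraction Threshold X in `[0, 1]`.
#' @param y_rr_sd Threshold Y in ms (>= 0).
#' @return An `af_thresholds` object.
#' @export
af_thresholds <- function(x_min_p_fraction, y_rr_sd) {
  check_number(x_min_p_fraction, "x_min_p_fraction", lower = 0, upper = 1)
  check_number(y_rr_sd, "y_rr_sd", lower = 0)
  structure(list(x_min_p_fraction = x_min_p_fraction, y_rr_sd = y_rr_sd),
            class = "af_thresholds")
}

#' Classify rhythm from the two rule features
#'
#' AF if and only if `p_fraction < X` **and** `rr_sd > Y` (strict
#' inequalities, conjunction); otherwise SR. Vectorised over the features.
#'
#' @param p_fraction Fraction of QRS complexes preceded by a P wave.
#' @param rr_sd_val R-R standard deviation, ms.
#' @param thresholds An [af_thresholds()] object.
#' @return Character vector of `"AF"` / `"SR"` calls.
#' @export
classify_rhythm <- function(p_fraction, rr_sd_val, thresholds) {
  stopifnot(inherits(thresholds, "af_thresholds"))
  ifelse(p_fraction < thresholds$x_min_p_fraction &
           rr_sd_val > thresholds$y_rr_sd, "AF", "SR")
}

#' Extract the rule features from a label sequence
#'
#' Convenience wrapper running [find_qrs_clusters()], [rr_sd()] and
#' [p_preceded_fraction()] on one sequence.
#'
#' @inheritParams find_qrs_clusters
#' @inheritParams p_preceded_fraction
#' @return One-row tibble: `p_fraction`, `rr_sd`, `n_qrs`.
#' @export
extract_rhythm_features <- function(labels, fs, min_dur = 40, merge_gap = 20,
                                    window = 250, min_p_dur = 20) {
  clusters <- find_qrs_clusters(labels, fs, min_dur = min_dur,
                                merge_gap = merge_gap)
  tibble::tibble(
    p_fraction = p_preceded_fraction(labels, clusters, fs, window = window,
                                     min_p_dur = min_p_dur),
    rr_sd = rr_sd(clusters, fs),
    n_qrs = nrow(clusters)
  )
}

#' Full rule-based rhythm call on a label sequence
#'
#' @inheritParams extract_rhythm_features
#' @param thresholds An [af_thresholds()] object.
#' @return One-row tibble: `call` (`"AF"`/`"SR"`), `p_fraction`, `rr_sd`,
#'   `n_qrs`.
#' @export
detect_af <- function(labels, fs, thresholds, min_dur = 40, merge_gap = 20,
                      window = 250, min_p_dur = 20) {
  feats <- extract_rhythm_features(labels, fs, min_dur = min_dur,
                                   merge_gap = merge_gap, window = window,
                                   min_p_dur = min_p_dur)
  dplyr::mutate(feats,
                call = classify_rhythm(.data$p_fraction, .data$rr_sd, thresholds),
                .before = 1)
}

#' Fit the AF thresholds by brute-force search
#'
#' Exhaustively evaluates X in `{0, 0.05, ..., 1}` crossed with Y in
#' `{0, 10, ..., 300}` ms (651 cells) on a validation set of
#' (`p_fraction`, `rr_sd`, truth) rows and returns the pair maximising the F1
#' score with respect to the AF class. Ties are broken towards smaller X,
#' then smaller Y, making the fit fully deterministic.
#'
#' @param validation Data frame with columns `p_fraction`, `rr_sd` and
#'   `truth` (`"AF"`/`"SR"`; both classes must be present).
#' @param x_grid,y_grid Candidate threshold lattices.
#' @return A fitted `af_thresholds` with extra fields `f1` (achieved F1 on
#'   the validation set), `n` and `grid` (tibble of every cell's F1); works
#'   with [generics::tidy()], [generics::glance()] and `autoplot()`.
#' @export
fit_thresholds <- function(validation,
                           x_grid = seq(0, 1, by = 0.05),
                           y_grid = seq(0, 300, by = 10)) {
  validation <- tibble::as_tibble(validation)
  stopifnot(all(c("p_fraction", "rr_sd", "truth") %in% names(validation)))
  truth_af <- validation$truth == "AF"
  if (!any(truth_af) || all(truth_af)) {
    stop_ecgforge("Validation set must contain both AF and SR records.",
                  "ecgforge_invalid_argument")
  }

  grid <- tidyr::expand_grid(x = x_grid, y = y_grid)
  grid$f1 <- purrr::map2_dbl(grid$x, grid$y, function(x, y) {
    pred_af <- validation$p_fraction < x & validation$rr_sd > y
    tp <- sum(pred_af & truth_af)
    fp <- sum(pred_af & !truth_af)
    fn <- sum(!pred_af & truth_af)
    if (tp == 0) return(0)
    sens <- tp / (tp + fn)
    ppv_v <- tp / (tp + fp)
    2 * sens * ppv_v / (sens + ppv_v)
  })

  # argmax with deterministic tie-break: smaller X, then smaller Y
  # (expand_grid enumerates in exactly that order)
  best <- grid[which(grid$f1 >= max(grid$f1) - 1e-15)[1], ]

  out <- af_thresholds(best$x, best$y)
  out$f1 <- best$f1
  out$n <- nrow(validation)
  out$grid <- grid
  out
}

#' @export
print.af_thresholds <- function(x, ...) {
  cat(sprintf("<af_thresholds> AF iff p_fraction < %.2f and rr_sd > %g ms",
              x$x_min_p_fraction, x$y_rr_sd))
  if (!is.null(x$f1)) cat(sprintf("  (validation F1 %.3f, n = %d)", x$f1, x$n))
  cat("\n")
  invisible(x)
}

#' Tidy / summarise a fitted threshold object
#'
#' @param x An [fit_thresholds()] result.
#' @param ... Unused.
#' @return `tidy()`: one row per threshold with `term` and `estimate`;
#'   `glance()`: one row with `f1`, `n_validation`, `n_grid`.
#' @importFrom generics tidy
#' @export
tidy.af_thresholds <- function(x, ...) {
  tibble::tibble(
    term = c("x_min_p_fraction", "y_rr_sd"),
    estimate = c(x$x_min_p_fraction, x$y_rr_sd),
    unit = c("fraction", "ms")
  )
}

#' @rdname tidy.af_thresholds
#' @importFrom generics glance
#' @export
glance.af_thresholds <- function(x, ...) {
  tibble::tibble(
    f1 = x$f1 %||% NA_real_,
    n_validation = x$n %||% NA_integer_,
    n_grid = if (is.null(x$grid)) NA_integer_ else nrow(x$grid)
  )
}
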