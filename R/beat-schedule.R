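# Beat scheduling: where each QRS complex starts, how irregular the R-R
# series is, and whether each beat carries a P wave.

#' Generate the beat schedule for one record
#'
#' Draws the sequence of QRS onset times for a configuration. Under sinus
#' rhythm the R-R intervals are near-regular (truncated Gaussian around the
#' mean R-R with coefficient of variation `rr_jitter`, at most 0.05 by
#' default) and every beat carries a P wave. Under atrial fibrillation the
#' R-R intervals are drawn from a gamma distribution whose coefficient of
#' variation equals `rr_jitter` (at least 0.15 by default) and no beat
#' carries a P wave — the irregularly irregular rhythm with absent atrial
#' activity that defines AF on the surface ECG.
#'
#' The first onset is placed so a full P + P-R complex fits before it; the
#' final beat may have its T wave truncated by the end of the record (the
#' labels stay consistent with the truncation).
#'
#' @param config A [sample_config()] object.
#' @return A `beat_schedule` tibble with one row per beat: `beat` (1-based),
#'   `qrs_onset` (0-based sample index, strictly increasing), `rr_ms`
#'   (interval to the next onset in ms, `NA` for the last beat) and
#'   `has_p_wave`. Sampling rate and rhythm are carried as attributes.
#' @export
#' @examples
#' cfg <- sample_config(1, overrides = list(rhythm = "SR", mean_heart_rate = 60,
#'                                          rr_jitter = 0))
#' generate_beat_schedule(cfg)
generate_beat_schedule <- function(config) {
  validate_simulation_config(config)
  fs <- config$sampling_rate
  n <- round(fs * config$duration)
  mean_rr_s <- 60 / config$mean_heart_rate
  wp <- config$wave_params

  # room for a full P + P-R segment ahead of the first QRS
  lead_in_s <- (wp$p_dur_ms + wp$pr_seg_ms) / 1000 + 0.08

  onsets_s <- withr::with_seed(as.integer(derive_seed(config$seed, 1L)), {
    n_max <- ceiling(config$duration / mean_rr_s) + 10L
    rr <- if (identical(config$rhythm, "AF")) {
      cv <- max(config$rr_jitter, 1e-9)
      shape <- 1 / cv^2
      stats::rgamma(n_max, shape = shape, scale = mean_rr_s / shape)
    } else {
      mean_rr_s * (1 + config$rr_jitter * pmax(pmin(stats::rnorm(n_max), 2.5), -2.5))
    }
    rr <- pmax(rr, 0.25)
    first <- lead_in_s + stats::runif(1, 0, 0.5 * mean_rr_s)
    cumsum(c(first, rr[-n_max]))
  })
  qrs_onsets <- round(onsets_s * fs)
  qrs_onsets <- qrs_onsets[qrs_onsets < n]
  if (length(qrs_onsets) < 2L) {
    stop_ecgforge(
      "Heart rate and duration admit fewer than 2 beats; R-R statistics are undefined.",
      "ecgforge_too_few_beats"
    )
  }

  rr_ms <- c(diff(qrs_onsets) / fs * 1000, NA_real_)
  out <- tibble::tibble(
    beat = seq_along(qrs_onsets),
    qrs_onset = as.integer(qrs_onsets),
    rr_ms = rr_ms,
    has_p_wave = !identical(config$rhythm, "AF")
  )
  attr(out, "sampling_rate") <- fs
  attr(out, "rhythm") <- config$rhythm
  class(out) <- c("beat_schedule", class(out))
  out
}
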