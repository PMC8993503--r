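# Signal synthesis: place parameterised wave templates on the beat schedule,
# assign per-sample wave-class labels, then (separately) add noise, baseline
# wander and random voltage scaling.

#' Synthesize a clean labelled 12-lead ECG
#'
#' Renders the configuration into a noise-free 12-lead signal plus a
#' per-sample wave-class label matrix. Each beat is composed of smooth,
#' compactly-supported wave templates (raised-cosine bumps; the QRS from
#' three signed sub-bumps giving Q/R/S deflections) whose supports are
#' exactly the labelled intervals, placed per the beat schedule. Phenotypes
#' modify the per-lead tables: frontal axis shift for LAHB/LPHB, QRS duration
#' >= 120 ms with discordant T waves for LBBB, and anterior ST elevation
#' (concave for HIGH_TAKEOFF, convex with reciprocal inferior depression for
#' ANTERIOR_STE). Under AF a low-amplitude 4-9 Hz fibrillatory oscillation
#' fills the inter-beat baseline, labelled as T-P segment (the class scheme
#' has no f-wave class).
#'
#' Labels follow the precedence QRS > T > P > segments on collisions; samples
#' covered by both a T wave and the following beat's P wave get the T/P
#' overlap class 7. The function is a pure function of `config` (identical
#' config, identical output).
#'
#' @param config A [sample_config()] object.
#' @return An `ecg_signal` object: list with `samples` (12 x N matrix, mV,
#'   lead order [ecg_leads()]), `labels` (12 x N integer matrix of
#'   [wave_classes()] codes), `config`, `schedule`, `rhythm`, `phenotype`,
#'   and `clean = TRUE`.
#' @seealso [add_noise_and_wander()], [generate_beat_schedule()]
#' @export
#' @examples
#' sig <- synthesize_ecg(sample_config(1, overrides = list(rhythm = "SR")))
#' table(sig$labels[1, ])
synthesize_ecg <- function(config) {
  validate_simulation_config(config)
  schedule <- generate_beat_schedule(config)
  fs <- config$sampling_rate
  n <- round(fs * config$duration)
  wp <- config$wave_params

  ms <- function(x) max(1L, round(x / 1000 * fs))
  p_len <- ms(wp$p_dur_ms)
  pr_len <- ms(wp$pr_seg_ms)
  qrs_len <- ms(wp$qrs_dur_ms)
  st_len <- ms(wp$st_dur_ms)
  t_len <- ms(wp$t_dur_ms)

  onsets <- schedule$qrs_onset
  sr <- !identical(config$rhythm, "AF")

  # ---- labels (shared across leads; timing is identical in every lead) ----
  lab <- rep.int(CLASS_TP, n)
  clip <- function(start, len) {
    lo <- max(0, start)
    hi <- min(n, start + len)
    if (hi <= lo) return(integer(0))
    seq.int(lo, hi - 1L)
  }
  for (q in onsets) lab[clip(q, qrs_len) + 1L] <- CLASS_QRS
  for (b in seq_along(onsets)) {
    q <- onsets[b]
    # repolarisation labels never spill past the next beat's QRS onset
    bound <- if (b < length(onsets)) onsets[b + 1L] else n
    st_idx <- clip(q + qrs_len, min(st_len, bound - q - qrs_len)) + 1L
    lab[st_idx[lab[st_idx] == CLASS_TP]] <- CLASS_ST
    t_idx <- clip(q + qrs_len + st_len,
                  min(t_len, bound - q - qrs_len - st_len)) + 1L
    lab[t_idx[lab[t_idx] == CLASS_TP]] <- CLASS_T
  }
  if (sr) {
    for (q in onsets) {
      p_idx <- clip(q - pr_len - p_len, p_len) + 1L
      lab[p_idx[lab[p_idx] == CLASS_T]] <- CLASS_TP_OVERLAP
      lab[p_idx[lab[p_idx] == CLASS_TP]] <- CLASS_P
      pr_idx <- clip(q - pr_len, pr_len) + 1L
      lab[pr_idx[lab[pr_idx] == CLASS_TP]] <- CLASS_PR
    }
  }

  # ---- per-lead waveforms ----
  amp <- lead_wave_amplitudes(config)
  leads <- ecg_leads()
  samples <- matrix(0, nrow = 12L, ncol = n, dimnames = list(leads, NULL))

  add_wave <- function(start, len, shape_fun, amps) {
    idx <- clip(start, len)
    if (length(idx) == 0) return(invisible())
    u <- (idx - start) / len
    samples[, idx + 1L] <<- samples[, idx + 1L] + outer(amps, shape_fun(u))
    invisible()
  }

  st_shape <- if (identical(config$phenotype, "ANTERIOR_STE")) "convex" else "concave"
  for (q in onsets) {
    if (sr) add_wave(q - pr_len - p_len, p_len, bump_raised_cosine, amp$p)
    add_wave(q, qrs_len, qrs_shape, amp$qrs)
    if (any(amp$st_offset != 0)) {
      add_wave(q + qrs_len, st_len, function(u) st_profile(u, st_shape),
               amp$st_offset)
      # decay the ST offset through the T support so the trace is continuous
      add_wave(q + qrs_len + st_len, t_len, function(u) 1 - u, amp$st_offset)
    }
    add_wave(q + qrs_len + st_len, t_len, bump_t_wave, amp$t)
  }

  if (!sr) {
    # fibrillatory baseline in the inter-beat (T-P labelled) regions,
    # most prominent in V1, as on real AF traces
    phase <- withr::with_seed(as.integer(derive_seed(config$seed, 3L)),
                              stats::runif(1, 0, 2 * pi))
    tt <- (seq_len(n) - 1L) / fs
    fib <- wp$fib_amp_mv * sin(2 * pi * wp$fib_freq_hz * tt + phase) *
      (1 + 0.3 * sin(2 * pi * 0.7 * tt))
    fib_lead <- stats::setNames(
      c(rep(0.6, 6), 1.0, 0.7, 0.5, 0.5, 0.5, 0.5), leads
    )
    in_tp <- lab == CLASS_TP
    samples[, in_tp] <- samples[, in_tp] + outer(fib_lead, fib[in_tp])
  }

  labels <- matrix(rep(lab, each = 12L), nrow = 12L,
                   dimnames = list(leads, NULL))
  storage.mode(labels) <- "integer"

  structure(
    list(
      samples = samples, labels = labels, config = config,
      schedule = schedule, rhythm = config$rhythm,
      phenotype = config$phenotype, clean = TRUE
    ),
    class = "ecg_signal"
  )
}

#' Add noise, baseline wander and voltage scaling
#'
#' Applies the record's stochastic artefact model to a clean signal:
#' `output = voltage_scale * (signal + Gaussian noise + wander)`, where the
#' wander is a per-lead sinusoid at `wander_freq` plus a smoothed random
#' walk, both bounded by `wander_amplitude`. Labels are never changed —
#' they describe the cardiac waves, not the artefact, so masks remain ground
#' truth for segmentation. Deterministic given the config seed.
#'
#' @param signal An `ecg_signal` from [synthesize_ecg()].
#' @param config Configuration supplying `noise_sd` (mV), `wander_amplitude`
#'   (mV), `wander_freq` (Hz) and `voltage_scale`; defaults to the signal's
#'   own config.
#' @return An `ecg_signal` with noisy `samples`, identical `labels`, and
#'   `clean = FALSE`.
#' @export
add_noise_and_wander <- function(signal, config = signal$config) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (!is.numeric(config$noise_sd) || config$noise_sd < 0) {
    stop_ecgforge("`noise_sd` must be non-negative.", "ecgforge_invalid_argument")
  }
  fs <- config$sampling_rate
  n <- ncol(signal$samples)
  out <- signal$samples

  withr::with_seed(as.integer(derive_seed(config$seed, 2L)), {
    if (config$noise_sd > 0) {
      out <- out + matrix(stats::rnorm(12L * n, 0, config$noise_sd), nrow = 12L)
    }
    if (config$wander_amplitude > 0) {
      tt <- (seq_len(n) - 1L) / fs
      for (l in seq_len(12L)) {
        phase <- stats::runif(1, 0, 2 * pi)
        walk <- cumsum(stats::rnorm(n))
        k <- max(3L, round(fs / max(config$wander_freq, 0.05) / 2))
        walk <- as.numeric(stats::filter(walk, rep(1 / k, k), sides = 2))
        walk[is.na(walk)] <- 0
        if (max(abs(walk)) > 0) walk <- walk / max(abs(walk))
        out[l, ] <- out[l, ] +
          config$wander_amplitude * (0.7 * sin(2 * pi * config$wander_freq * tt + phase) +
                                       0.3 * walk)
      }
    }
  })

  signal$samples <- config$voltage_scale * out
  signal$clean <- FALSE
  signal
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf(
    "<ecg_signal> %s / %s, 12 x %d samples @ %g Hz (%s), %d beats\n",
    x$rhythm, x$phenotype, ncol(x$samples), x$config$sampling_rate,
    if (isTRUE(x$clean)) "clean" else "with artefact", nrow(x$schedule)
  ))
  invisible(x)
}

#' Long-format view of a labelled signal
#'
#' @param x An `ecg_signal`.
#' @param ... Unused.
#' @return A tibble with columns `lead`, `time` (s), `mv` and `label`
#'   (integer wave-class code), 12 x N rows.
#' @importFrom tibble as_tibble
#' @export
as_tibble.ecg_signal <- function(x, ...) {
  n <- ncol(x$samples)
  fs <- x$config$sampling_rate
  tibble::tibble(
    lead = factor(rep(ecg_leads(), each = n), levels = ecg_leads()),
    time = rep((seq_len(n) - 1L) / fs, times = 12L),
    mv = as.vector(t(x$samples)),
    label = as.vector(t(x$labels))
  )
}
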