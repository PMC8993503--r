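# Randomised simulation configuration: every free parameter of one synthetic
# ECG is drawn from a documented range so that each record is unique, and the
# whole record is a pure function of its seed.

#' Draw a randomised simulation configuration
#'
#' Samples the full parameterisation of one synthetic 12-lead ECG from
#' documented ranges, using a generator seeded by `seed` so the draw is
#' reproducible. Any field may be pinned via `overrides`; overridden values
#' are taken verbatim and validated.
#'
#' Sampled ranges (uniform unless stated):
#' * `rhythm`: `"SR"` or `"AF"`, equal probability; `phenotype`: one of the
#'   six values of [ecg_phenotypes()], equal probability.
#' * `mean_heart_rate`: 55-110 bpm.
#' * `rr_jitter` (coefficient of variation of the R-R intervals): 0.010-0.035
#'   under SR, 0.20-0.30 under AF. This is the one field resolved from the
#'   final rhythm, since sinus rhythm is near-regular while atrial
#'   fibrillation is irregularly irregular.
#' * Wave timing (ms): P 80-110, P-R segment 40-80, QRS 70-100 (120-160 under
#'   LBBB), ST 80-120, T 140-200.
#' * Amplitudes (mV): P 0.10-0.20, QRS 0.8-1.6, T 0.20-0.45; anterior ST
#'   take-off 0.10-0.25 (HIGH_TAKEOFF) or 0.20-0.45 (ANTERIOR_STE).
#' * Axes (degrees, frontal plane): QRS 0-60 normal, -75 to -45 LAHB, 100-140
#'   LPHB; T = QRS axis + (-20, 20); P 40-60.
#' * Fibrillatory baseline (AF): amplitude 0.03-0.08 mV at 4-9 Hz.
#' * Artefact: `noise_sd` 0.01-0.05 mV, `wander_amplitude` 0.02-0.15 mV,
#'   `wander_freq` 0.10-0.50 Hz, `voltage_scale` 0.8-1.2.
#'
#' `sampling_rate` (500 Hz) and `duration` (10 s) are fixed defaults chosen
#' for interoperability with common digital ECG archives; override to change.
#'
#' @param seed Non-negative integer seed.
#' @param overrides Named list of fields to pin. Top-level fields and entries
#'   of `wave_params` (supplied as `wave_params = list(...)`) are accepted;
#'   an unknown name or out-of-range value is rejected with a message naming
#'   the field.
#' @return A `simulation_config` object (named list) with fields `seed`,
#'   `sampling_rate`, `duration`, `rhythm`, `phenotype`, `mean_heart_rate`,
#'   `rr_jitter`, `wave_params` (per-wave durations, amplitudes, axes),
#'   `noise_sd`, `wander_amplitude`, `wander_freq`, `voltage_scale`.
#' @export
#' @examples
#' cfg <- sample_config(7)
#' cfg$rhythm
#' sample_config(7, overrides = list(rhythm = "AF"))$rhythm
sample_config <- function(seed, overrides = list()) {
  if (!is.numeric(seed) || length(seed) != 1L || seed < 0 || seed != floor(seed)) {
    stop_ecgforge("`seed` must be a single non-negative integer.",
                  "ecgforge_invalid_argument")
  }
  draws <- withr::with_seed(as.integer(seed %% 2147483647), {
    list(
      rhythm = sample(ecg_rhythms(), 1L),
      phenotype = sample(ecg_phenotypes(), 1L),
      mean_heart_rate = stats::runif(1, 55, 110),
      rr_jitter_sr = stats::runif(1, 0.010, 0.035),
      rr_jitter_af = stats::runif(1, 0.20, 0.30),
      p_dur_ms = stats::runif(1, 80, 110),
      pr_seg_ms = stats::runif(1, 40, 80),
      qrs_dur_normal_ms = stats::runif(1, 70, 100),
      qrs_dur_lbbb_ms = stats::runif(1, 120, 160),
      st_dur_ms = stats::runif(1, 80, 120),
      t_dur_ms = stats::runif(1, 140, 200),
      p_amp_mv = stats::runif(1, 0.10, 0.20),
      qrs_amp_mv = stats::runif(1, 0.8, 1.6),
      t_amp_mv = stats::runif(1, 0.20, 0.45),
      qrs_axis_normal = stats::runif(1, 0, 60),
      qrs_axis_lahb = stats::runif(1, -75, -45),
      qrs_axis_lphb = stats::runif(1, 100, 140),
      t_axis_offset = stats::runif(1, -20, 20),
      p_axis_deg = stats::runif(1, 40, 60),
      st_offset_ht = stats::runif(1, 0.10, 0.25),
      st_offset_ste = stats::runif(1, 0.20, 0.45),
      fib_amp_mv = stats::runif(1, 0.03, 0.08),
      fib_freq_hz = stats::runif(1, 4, 9),
      noise_sd = stats::runif(1, 0.01, 0.05),
      wander_amplitude = stats::runif(1, 0.02, 0.15),
      wander_freq = stats::runif(1, 0.10, 0.50),
      voltage_scale = stats::runif(1, 0.8, 1.2)
    )
  })

  top_fields <- c(
    "sampling_rate", "duration", "rhythm", "phenotype", "mean_heart_rate",
    "rr_jitter", "noise_sd", "wander_amplitude", "wander_freq",
    "voltage_scale", "wave_params"
  )
  bad <- setdiff(names(overrides), top_fields)
  if (length(bad) > 0) {
    stop_ecgforge(
      sprintf("Unknown configuration field(s) in `overrides`: %s.",
              paste0("'", bad, "'", collapse = ", ")),
      "ecgforge_invalid_argument"
    )
  }

  rhythm <- overrides$rhythm %||% draws$rhythm
  phenotype <- overrides$phenotype %||% draws$phenotype

  wave_params <- list(
    p_dur_ms = draws$p_dur_ms,
    pr_seg_ms = draws$pr_seg_ms,
    qrs_dur_ms = if (identical(phenotype, "LBBB")) draws$qrs_dur_lbbb_ms else draws$qrs_dur_normal_ms,
    st_dur_ms = draws$st_dur_ms,
    t_dur_ms = draws$t_dur_ms,
    p_amp_mv = draws$p_amp_mv,
    qrs_amp_mv = draws$qrs_amp_mv,
    t_amp_mv = draws$t_amp_mv,
    qrs_axis_deg = switch(phenotype,
      LAHB = draws$qrs_axis_lahb,
      LPHB = draws$qrs_axis_lphb,
      draws$qrs_axis_normal
    ),
    t_axis_offset_deg = draws$t_axis_offset,
    p_axis_deg = draws$p_axis_deg,
    st_offset_mv = switch(phenotype,
      HIGH_TAKEOFF = draws$st_offset_ht,
      ANTERIOR_STE = draws$st_offset_ste,
      0
    ),
    fib_amp_mv = draws$fib_amp_mv,
    fib_freq_hz = draws$fib_freq_hz
  )
  if (!is.null(overrides$wave_params)) {
    bad_wp <- setdiff(names(overrides$wave_params), names(wave_params))
    if (length(bad_wp) > 0) {
      stop_ecgforge(
        sprintf("Unknown `wave_params` field(s): %s.",
                paste0("'", bad_wp, "'", collapse = ", ")),
        "ecgforge_invalid_argument"
      )
    }
    wave_params[names(overrides$wave_params)] <- overrides$wave_params
  }

  config <- structure(
    list(
      seed = as.integer(seed %% 2147483647),
      sampling_rate = overrides$sampling_rate %||% 500,
      duration = overrides$duration %||% 10,
      rhythm = rhythm,
      phenotype = phenotype,
      mean_heart_rate = overrides$mean_heart_rate %||% draws$mean_heart_rate,
      rr_jitter = overrides$rr_jitter %||%
        (if (identical(rhythm, "AF")) draws$rr_jitter_af else draws$rr_jitter_sr),
      wave_params = wave_params,
      noise_sd = overrides$noise_sd %||% draws$noise_sd,
      wander_amplitude = overrides$wander_amplitude %||% draws$wander_amplitude,
      wander_freq = overrides$wander_freq %||% draws$wander_freq,
      voltage_scale = overrides$voltage_scale %||% draws$voltage_scale
    ),
    class = "simulation_config"
  )
  validate_simulation_config(config)
  config
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants of a [sample_config()] object: positive
#' sampling rate and duration, heart rate within 20-250 bpm, non-negative
#' noise and jitter, positive voltage scale, and rhythm/phenotype drawn from
#' the closed vocabularies.
#'
#' @param config A `simulation_config`.
#' @return `config`, invisibly; errors (class `ecgforge_invalid_argument`)
#'   name the offending field.
#' @export
validate_simulation_config <- function(config) {
  check_number(config$sampling_rate, "sampling_rate", lower = 1e-9)
  check_number(config$duration, "duration", lower = 1e-9)
  check_number(config$mean_heart_rate, "mean_heart_rate", lower = 20, upper = 250)
  check_number(config$rr_jitter, "rr_jitter", lower = 0)
  check_number(config$noise_sd, "noise_sd", lower = 0)
  check_number(config$wander_amplitude, "wander_amplitude", lower = 0)
  check_number(config$wander_freq, "wander_freq", lower = 0)
  check_number(config$voltage_scale, "voltage_scale", lower = 1e-12)
  check_choice(config$rhythm, "rhythm", ecg_rhythms())
  check_choice(config$phenotype, "phenotype", ecg_phenotypes())
  wp <- config$wave_params
  for (f in c("p_dur_ms", "pr_seg_ms", "qrs_dur_ms", "st_dur_ms", "t_dur_ms")) {
    check_number(wp[[f]], paste0("wave_params$", f), lower = 1)
  }
  for (f in c("p_amp_mv", "qrs_amp_mv", "t_amp_mv", "fib_amp_mv", "fib_freq_hz")) {
    check_number(wp[[f]], paste0("wave_params$", f), lower = 0)
  }
  invisible(config)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> seed %d: %s / %s, %.0f bpm (R-R CV %.3f), %g Hz x %g s\n",
    x$seed, x$rhythm, x$phenotype, x$mean_heart_rate, x$rr_jitter,
    x$sampling_rate, x$duration
  ))
  cat(sprintf(
    "  noise %.3f mV, wander %.3f mV @ %.2f Hz, voltage scale %.2f\n",
    x$noise_sd, x$wander_amplitude, x$wander_freq, x$voltage_scale
  ))
  invisible(x)
}
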