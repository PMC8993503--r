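# Per-lead wave morphology. Leads are modelled with per-lead amplitude /
# polarity tables rather than a biophysical dipole: limb leads project a
# frontal-plane wave axis onto the standard lead angles, chest leads use
# fixed precordial progression factors. This is the simplest mechanism that
# reproduces phenotype-specific lead patterns (axis deviation, LBBB
# discordance, anterior ST shifts).

# Frontal-plane angles of the six limb leads, degrees.
LIMB_ANGLES <- c(I = 0, II = 60, III = 120, aVR = -150, aVL = -30, aVF = 90)

# Precordial factors (V1..V6), relative to the wave's base amplitude.
CHEST_QRS_NORMAL <- c(-0.50, -0.30, 0.20, 0.80, 1.00, 0.85)
CHEST_QRS_LBBB <- c(-1.00, -0.90, -0.50, 0.20, 0.80, 1.00)
CHEST_P <- c(0.25, 0.35, 0.40, 0.40, 0.35, 0.30)
CHEST_T <- c(0.15, 0.50, 0.80, 1.00, 0.90, 0.70)

# Project a frontal-plane axis (degrees) onto the limb leads.
limb_projection <- function(axis_deg) {
  cos((axis_deg - LIMB_ANGLES) * pi / 180)
}

# Per-lead signed amplitudes (mV) for each wave of one record.
# Returns list(p, qrs, t, st_offset), each a named 12-vector in lead order.
lead_wave_amplitudes <- function(config) {
  wp <- config$wave_params
  lbbb <- identical(config$phenotype, "LBBB")
  chest_qrs <- if (lbbb) CHEST_QRS_LBBB else CHEST_QRS_NORMAL

  qrs <- wp$qrs_amp_mv * c(limb_projection(wp$qrs_axis_deg), chest_qrs)
  p <- wp$p_amp_mv * c(limb_projection(wp$p_axis_deg), CHEST_P)

  if (lbbb) {
    # Discordant repolarisation: T polarity opposite the main QRS deflection.
    t_amp <- wp$t_amp_mv * c(
      limb_projection(wp$qrs_axis_deg + 180),
      -0.8 * chest_qrs
    )
  } else {
    t_amp <- wp$t_amp_mv * c(
      limb_projection(wp$qrs_axis_deg + wp$t_axis_offset_deg),
      CHEST_T
    )
  }

  st <- stats::setNames(numeric(12), ecg_leads())
  if (identical(config$phenotype, "HIGH_TAKEOFF")) {
    st[c("V2", "V3", "V4")] <- wp$st_offset_mv
  } else if (identical(config$phenotype, "ANTERIOR_STE")) {
    st[c("V1", "V2", "V3", "V4")] <- wp$st_offset_mv
    # reciprocal depression in the inferior leads
    st[c("II", "III", "aVF")] <- -0.3 * wp$st_offset_mv
  }

  lapply(list(p = p, qrs = qrs, t = t_amp, st_offset = st),
         stats::setNames, ecg_leads())
}

# Smooth compactly-supported bumps on u in [0, 1): zero at both support
# boundaries so the labelled support is exact.
bump_raised_cosine <- function(u) 0.5 * (1 - cos(2 * pi * u))

# Mildly asymmetric T bump (peak past midpoint).
bump_t_wave <- function(u) sin(pi * pmin(pmax(u, 0), 1)^1.3)^2

# QRS built from three signed sub-bumps (Q, R, S deflections) over the
# labelled support; a negative per-lead amplitude mirrors this into an rS
# pattern.
qrs_shape <- function(u) {
  v <- numeric(length(u))
  in_q <- u >= 0 & u < 0.30
  in_r <- u >= 0.15 & u < 0.75
  in_s <- u >= 0.60 & u < 1
  v[in_q] <- v[in_q] - 0.12 * bump_raised_cosine(u[in_q] / 0.30)
  v[in_r] <- v[in_r] + 1.00 * bump_raised_cosine((u[in_r] - 0.15) / 0.60)
  v[in_s] <- v[in_s] - 0.22 * bump_raised_cosine((u[in_s] - 0.60) / 0.40)
  v
}

# ST-segment elevation profile on u in [0, 1): concave (benign take-off)
# rises late, convex (infarct pattern) rises early and plateaus. Both start
# at 0 (the J point) and end at 1, where the T-support decay takes over.
st_profile <- function(u, shape = c("concave", "convex")) {
  shape <- match.arg(shape)
  if (shape == "concave") u^1.8 else 1 - (1 - u)^2
}
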