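test_that("sinus labelling places P and P-R runs ahead of every QRS", {
  sig <- synthesize_ecg(sample_config(11, overrides = list(
    rhythm = "SR", phenotype = "NORMAL")))
  lab <- sig$labels[1, ]
  fs <- sig$config$sampling_rate
  ons <- which(diff(c(0L, lab == 3L)) == 1L)
  for (q in ons) {
    # class 2 immediately before the QRS onset
    expect_identical(lab[q - 1L], 2L)
    # and a class-1 run starting within 300 ms of the onset
    win <- lab[max(1L, q - round(0.3 * fs)):(q - 1L)]
    expect_true(any(win == 1L))
    pr_start <- q - 1L
    while (pr_start > 1L && lab[pr_start - 1L] == 2L) pr_start <- pr_start - 1L
    expect_true(lab[pr_start - 1L] %in% c(1L, 7L))
  }
})

test_that("AF records carry no P-wave or P-R labels", {
  for (seed in c(21, 22, 23)) {
    sig <- synthesize_ecg(sample_config(seed, overrides = list(rhythm = "AF")))
    expect_identical(sum(sig$labels %in% c(1L, 2L)), 0L)
  }
})

test_that("QRS label-run durations separate LBBB from normal conduction", {
  run_ms <- function(sig) {
    r <- rle(sig$labels[1, ] == 3L)
    stats::median(r$lengths[r$values]) / sig$config$sampling_rate * 1000
  }
  lbbb <- synthesize_ecg(sample_config(31, overrides = list(phenotype = "LBBB")))
  norm <- synthesize_ecg(sample_config(31, overrides = list(phenotype = "NORMAL")))
  expect_gte(run_ms(lbbb), 120)
  expect_lte(run_ms(norm), 110)
})

test_that("synthesis is a pure function of the configuration", {
  cfg <- sample_config(41)
  a <- synthesize_ecg(cfg)
  b <- synthesize_ecg(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$labels, b$labels)
})

test_that("labels and samples share shape, labels stay in 0..7, ordering holds", {
  for (seed in 1:20) {
    sig <- synthesize_ecg(sample_config(seed))
    expect_identical(dim(sig$samples), dim(sig$labels))
    expect_identical(ncol(sig$samples),
                     as.integer(round(sig$config$sampling_rate * sig$config$duration)))
    expect_true(all(sig$labels >= 0L & sig$labels <= 7L))
    expect_true(beat_ordering_ok(sig$labels[1, ], sig$rhythm))
  }
})

test_that("T/P overlap gets class 7 when the waves collide at high rates", {
  sig <- synthesize_ecg(sample_config(51, overrides = list(
    rhythm = "SR", mean_heart_rate = 150,
    wave_params = list(t_dur_ms = 250, p_dur_ms = 110))))
  lab <- sig$labels[1, ]
  expect_gt(sum(lab == 7L), 0)
  # overlap runs sit between a T run and a P-R (or QRS) run
  runs <- rle(lab)
  idx7 <- which(runs$values == 7L)
  idx7 <- idx7[idx7 > 1 & idx7 < length(runs$values)]
  expect_true(all(runs$values[idx7 - 1L] == 5L))
  # after the overlap: rest of the P (1), P-R (2), the QRS itself (3), or the
  # tail of the T when the P support ends first (5)
  expect_true(all(runs$values[idx7 + 1L] %in% c(1L, 2L, 3L, 5L)))
})

test_that("phenotype morphology shows where it should", {
  # anterior ST elevation raises the ST-segment samples in V2-V4
  ste <- synthesize_ecg(sample_config(61, overrides = list(
    rhythm = "SR", phenotype = "ANTERIOR_STE")))
  lab <- ste$labels[1, ]
  st_mean <- mean(ste$samples["V3", lab == 4L])
  norm <- synthesize_ecg(sample_config(61, overrides = list(
    rhythm = "SR", phenotype = "NORMAL")))
  st_mean_norm <- mean(norm$samples["V3", norm$labels[1, ] == 4L])
  expect_gt(st_mean, st_mean_norm + 0.05)

  # LBBB T waves are discordant: opposite sign to the main QRS deflection
  lbbb <- synthesize_ecg(sample_config(62, overrides = list(phenotype = "LBBB")))
  lab <- lbbb$labels[1, ]
  for (lead in c("V1", "V6")) {
    qrs_peak <- lbbb$samples[lead, lab == 3L]
    t_peak <- lbbb$samples[lead, lab == 5L]
    expect_lt(sign(qrs_peak[which.max(abs(qrs_peak))]) *
                sign(t_peak[which.max(abs(t_peak))]), 0)
  }
})

test_that("noise and wander leave labels alone and obey the identity cases", {
  cfg <- sample_config(71, overrides = list(
    noise_sd = 0, wander_amplitude = 0, voltage_scale = 1))
  sig <- synthesize_ecg(cfg)
  out <- add_noise_and_wander(sig)
  expect_identical(out$samples, sig$samples)
  expect_identical(out$labels, sig$labels)

  cfg2 <- sample_config(71, overrides = list(
    noise_sd = 0, wander_amplitude = 0, voltage_scale = 2))
  sig2 <- synthesize_ecg(cfg2)
  out2 <- add_noise_and_wander(sig2)
  expect_equal(out2$samples, 2 * sig2$samples)
})

test_that("added noise matches its generating distribution", {
  cfg <- sample_config(72, overrides = list(
    noise_sd = 0.05, wander_amplitude = 0, voltage_scale = 1))
  sig <- synthesize_ecg(cfg)
  out <- add_noise_and_wander(sig)
  resid <- as.vector(out$samples - sig$samples)
  expect_lt(abs(mean(resid)), 0.005)
  expect_lt(abs(stats::sd(resid) - 0.05) / 0.05, 0.10)
})

test_that("negative noise is rejected", {
  sig <- synthesize_ecg(sample_config(1))
  bad <- sig$config
  bad$noise_sd <- -0.1
  expect_error(add_noise_and_wander(sig, bad), class = "ecgforge_invalid_argument")
})
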