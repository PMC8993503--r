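test_that("grid calibration is recovered from rendered images", {
  sig <- synthesize_ecg(sample_config(3))
  for (ppm in c(6, 10)) {
    r <- render_ecg(sig, render_config(px_per_mm = ppm))
    est <- estimate_grid(r$image)$px_per_mm_est
    expect_lte(abs(est - ppm) / ppm, 0.02)
  }
  white <- array(255L, dim = c(60, 60, 3))
  expect_error(estimate_grid(white), class = "ecgforge_uncalibratable")
})

test_that("label sequences come back from mask columns", {
  lay <- build_layout(render_config(px_per_mm = 4), duration = 10)
  mask <- matrix(0L, lay$height, lay$width)
  box <- lay$leads[lay$leads$lead == "I", ]

  # all-background box reads back as all zero
  expect_true(all(mask_to_label_sequence(mask, lay, "I") == 0L))
  expect_length(mask_to_label_sequence(mask, lay, "I", fs_out = 500),
                round(box$win_s * 500))

  # columns holding only class-3 pixels map to class 3 samples
  mask[(box$y0 + 5):(box$y0 + 8), (box$x0 + 1):(box$x0 + 100)] <- 3L
  seq_out <- mask_to_label_sequence(mask, lay, "I", fs_out = 500)
  cols_per_sample <- lay$px_per_second / 500
  n_hit <- floor(100 / cols_per_sample)
  expect_true(all(seq_out[1:n_hit] == 3L))
})

test_that("voltages read back through the layout geometry", {
  # flatline at baseline -> zero mV
  n <- 5000
  leads <- ecg_leads()
  flat <- manual_signal(matrix(0, 12, n, dimnames = list(leads, NULL)),
                        matrix(6L, 12, n, dimnames = list(leads, NULL)))
  r <- render_ecg(flat, render_config(px_per_mm = 10))
  ex <- readback_signal(r$mask, r$layout)
  expect_lt(max(abs(ex$mv)), 1e-9)

  # 1 mV square deflection recovers its plateau within one pixel equivalent
  samples <- matrix(0, 12, n, dimnames = list(leads, NULL))
  samples["I", 251:500] <- 1
  square <- manual_signal(samples,
                          matrix(6L, 12, n, dimnames = list(leads, NULL)))
  r2 <- render_ecg(square, render_config(px_per_mm = 10))
  ex2 <- readback_signal(r2$mask, r2$layout)
  plateau <- ex2$mv[ex2$lead == "I" & ex2$time > 0.55 & ex2$time < 0.95]
  expect_lt(max(abs(plateau - 1)), 0.01 + 1e-9)
})

test_that("a clean rendered ECG reads back faithfully", {
  sig <- synthesize_ecg(sample_config(19, overrides = list(
    rhythm = "SR", phenotype = "NORMAL")))
  r <- render_ecg(sig, render_config(px_per_mm = 6, layout = "GRID_3x4_RHYTHM"))
  ex <- readback_signal(r$mask, r$layout)

  orig <- sig$samples["II", ]
  rb <- ex$mv[ex$lead == "II"]
  n <- min(length(orig), length(rb))
  expect_gte(stats::cor(orig[1:n], rb[1:n]), 0.95)

  labs <- mask_to_label_sequence(r$mask, r$layout, "II")
  expect_gte(mean(labs[1:n] == sig$labels["II", 1:n]), 0.95)
})

test_that("calibration-only readback treats the mask as a standard strip", {
  sig <- synthesize_ecg(sample_config(23, overrides = list(rhythm = "SR")))
  r <- render_ecg(sig, render_config(px_per_mm = 6, layout = "GRID_3x4_RHYTHM"))
  cal <- estimate_grid(r$image)
  expect_lte(abs(cal$px_per_mm_est - 6) / 6, 0.02)

  # crop the rhythm-strip rows/columns and read them back as a bare strip
  box <- r$layout$leads[r$layout$leads$box_id == 13L, ]
  strip <- r$mask[(box$y0 + 1):box$y1, (box$x0 + 1):box$x1]
  ex <- readback_signal(strip, cal)
  expect_identical(unique(ex$lead), "strip")
  expect_true(all(is.finite(ex$mv)))

  orig <- sig$samples["II", ]
  n <- min(length(orig), nrow(ex))
  expect_gte(stats::cor(orig[1:n], ex$mv[1:n]), 0.90)
})

test_that("sparse masks are flagged low-confidence", {
  lay <- build_layout(render_config(px_per_mm = 4), duration = 10)
  mask <- matrix(0L, lay$height, lay$width)
  box <- lay$leads[lay$leads$lead == "I", ]
  mask[box$baseline_row, (box$x0 + 1):(box$x0 + 30)] <- 6L
  expect_warning(readback_signal(mask, lay), class = "ecgforge_low_confidence")
})
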