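# Rendering a labelled signal into a calibrated ECG paper image plus a
# pixel-aligned class mask. The mask is rasterised by the same line-drawing
# routine as the trace (class codes instead of colour) and anti-aliasing is
# deliberately absent, so mask/trace correspondence is exact by construction.

#' Rendering configuration
#'
#' Geometry and colours for ECG paper rendering. Defaults follow clinical
#' convention: 25 mm/s paper speed, 10 mm/mV gain, red 1 mm minor / 5 mm
#' major grid on white, black trace.
#'
#' @param px_per_mm Pixels per millimetre of paper (> 0).
#' @param paper_speed mm per second (default 25).
#' @param gain mm per mV (default 10).
#' @param layout `"GRID_3x4"` (four 2.5 s columns x three rows, conventional
#'   column order I,II,III | aVR,aVL,aVF | V1-V3 | V4-V6) or
#'   `"GRID_3x4_RHYTHM"` (plus a full-duration lead II rhythm strip).
#' @param trace_width Trace thickness in pixels (>= 1).
#' @param grid Draw the calibration grid.
#' @param bg,grid_minor,grid_major,trace RGB colours (integer 0-255 triples).
#' @return A `render_config` list.
#' @export
render_config <- function(px_per_mm = 8, paper_speed = 25, gain = 10,
                          layout = c("GRID_3x4", "GRID_3x4_RHYTHM"),
                          trace_width = 1, grid = TRUE,
                          bg = c(255, 255, 255),
                          grid_minor = c(255, 208, 208),
                          grid_major = c(255, 160, 160),
                          trace = c(0, 0, 0)) {
  layout <- match.arg(layout)
  check_number(px_per_mm, "px_per_mm", lower = 1e-9)
  check_number(paper_speed, "paper_speed", lower = 1e-9)
  check_number(gain, "gain", lower = 1e-9)
  check_number(trace_width, "trace_width", lower = 1)
  structure(
    list(px_per_mm = px_per_mm, paper_speed = paper_speed, gain = gain,
         layout = layout, trace_width = as.integer(trace_width),
         grid = isTRUE(grid), bg = bg, grid_minor = grid_minor,
         grid_major = grid_major, trace = trace),
    class = "render_config"
  )
}

# Lead arrangement for the 3x4 grid, column-major.
GRID_3X4_ORDER <- c("I", "II", "III", "aVR", "aVL", "aVF",
                    "V1", "V2", "V3", "V4", "V5", "V6")

MARGIN_MM <- 4
ROW_H_MM <- 30
COLUMN_S <- 2.5

#' Build the layout metadata for a render
#'
#' @param config A [render_config()].
#' @param duration Signal duration in seconds (used for the rhythm strip).
#' @return An `ecg_layout`: list with scalars `px_per_mm`, `px_per_second`,
#'   `px_per_mv`, `width`, `height`, `trace_width`, and a `leads` tibble of
#'   half-open 0-based pixel boxes (`box_id`, `lead`, `x0`, `x1`, `y0`, `y1`,
#'   `t0` seconds, `win_s`, `baseline_row`).
#' @export
build_layout <- function(config, duration) {
  ppm <- config$px_per_mm
  pps <- config$paper_speed * ppm
  ppmv <- config$gain * ppm
  col_w_mm <- COLUMN_S * config$paper_speed
  n_rows <- if (config$layout == "GRID_3x4_RHYTHM") 4L else 3L

  width <- round((2 * MARGIN_MM + 4 * col_w_mm) * ppm)
  height <- round((2 * MARGIN_MM + n_rows * ROW_H_MM) * ppm)

  boxes <- purrr::map_dfr(0:11, function(k) {
    col <- k %/% 3L
    row <- k %% 3L
    tibble::tibble(
      box_id = k + 1L, lead = GRID_3X4_ORDER[k + 1L],
      x0 = round((MARGIN_MM + col * col_w_mm) * ppm),
      x1 = round((MARGIN_MM + (col + 1) * col_w_mm) * ppm),
      y0 = round((MARGIN_MM + row * ROW_H_MM) * ppm),
      y1 = round((MARGIN_MM + (row + 1) * ROW_H_MM) * ppm),
      t0 = col * COLUMN_S, win_s = COLUMN_S
    )
  })
  if (n_rows == 4L) {
    boxes <- dplyr::bind_rows(boxes, tibble::tibble(
      box_id = 13L, lead = "II",
      x0 = round(MARGIN_MM * ppm), x1 = round((MARGIN_MM + 4 * col_w_mm) * ppm),
      y0 = round((MARGIN_MM + 3 * ROW_H_MM) * ppm),
      y1 = round((MARGIN_MM + 4 * ROW_H_MM) * ppm),
      t0 = 0, win_s = duration
    ))
  }
  boxes$baseline_row <- boxes$y0 + round(ROW_H_MM / 2 * ppm)

  structure(
    list(px_per_mm = ppm, px_per_second = pps, px_per_mv = ppmv,
         width = as.integer(width), height = as.integer(height),
         trace_width = config$trace_width, leads = boxes),
    class = "ecg_layout"
  )
}

#' Render a labelled signal into an ECG image and pixel mask
#'
#' Draws the signal onto calibrated ECG paper as connected vertical-fill line
#' segments of width `trace_width`, and rasterises the segmentation mask with
#' the same routine, writing each sample's wave-class code wherever its trace
#' pixels land. The grid never enters the mask.
#'
#' @param signal An `ecg_signal`.
#' @param config A [render_config()].
#' @return An `ecg_render`: list with `image` (H x W x 3 integer array,
#'   0-255), `mask` (H x W integer matrix of class codes) and `layout`
#'   ([build_layout()] metadata).
#' @export
#' @examples
#' sig <- synthesize_ecg(sample_config(1))
#' r <- render_ecg(sig, render_config(px_per_mm = 4))
#' dim(r$image)
render_ecg <- function(signal, config = render_config()) {
  stopifnot(inherits(signal, "ecg_signal"))
  fs <- signal$config$sampling_rate
  duration <- ncol(signal$samples) / fs
  if (duration < 4 * COLUMN_S - 1e-9) {
    stop_ecgforge(
      sprintf("Signal duration %.2f s is shorter than the %g s the layout displays.",
              duration, 4 * COLUMN_S),
      "ecgforge_invalid_argument"
    )
  }
  layout <- build_layout(config, duration)
  h <- layout$height
  w <- layout$width

  image <- array(0L, dim = c(h, w, 3L))
  for (ch in 1:3) image[, , ch] <- config$bg[ch]
  mask <- matrix(0L, nrow = h, ncol = w)

  if (config$grid) image <- draw_grid(image, config, layout)

  hw <- (config$trace_width - 1L) %/% 2L
  for (b in seq_len(nrow(layout$leads))) {
    box <- layout$leads[b, ]
    lead_i <- match(box$lead, ecg_leads())
    k0 <- ceiling(box$t0 * fs)
    k1 <- min(ncol(signal$samples), floor((box$t0 + box$win_s) * fs))
    ks <- seq.int(k0, k1 - 1L)
    tt <- ks / fs
    cols <- box$x0 + floor((tt - box$t0) * layout$px_per_second)
    cols <- pmin(pmax(cols, box$x0), box$x1 - 1L)
    rows <- box$baseline_row - round(signal$samples[lead_i, ks + 1L] * layout$px_per_mv)
    rows <- pmin(pmax(rows, box$y0), box$y1 - 1L)
    labs <- signal$labels[lead_i, ks + 1L]

    prev_row <- rows[1]
    for (s in seq_along(ks)) {
      r0 <- min(prev_row, rows[s]) - hw
      r1 <- max(prev_row, rows[s]) + hw
      r0 <- max(r0, box$y0); r1 <- min(r1, box$y1 - 1L)
      c0 <- max(cols[s] - hw, box$x0); c1 <- min(cols[s] + hw, box$x1 - 1L)
      rr <- (r0:r1) + 1L
      cc <- (c0:c1) + 1L
      image[rr, cc, 1L] <- config$trace[1]
      image[rr, cc, 2L] <- config$trace[2]
      image[rr, cc, 3L] <- config$trace[3]
      mask[rr, cc] <- labs[s]
      prev_row <- rows[s]
    }
  }

  structure(list(image = image, mask = mask, layout = layout),
            class = "ecg_render")
}

# 1 mm minor / 5 mm major calibration grid across the plotting area.
draw_grid <- function(image, config, layout) {
  ppm <- layout$px_per_mm
  x_lo <- round(MARGIN_MM * ppm); x_hi <- layout$width - round(MARGIN_MM * ppm)
  y_lo <- round(MARGIN_MM * ppm); y_hi <- layout$height - round(MARGIN_MM * ppm)

  n_x <- floor((x_hi - x_lo) / ppm)
  n_y <- floor((y_hi - y_lo) / ppm)
  xs <- x_lo + round((0:n_x) * ppm)
  ys <- y_lo + round((0:n_y) * ppm)
  x_major <- (0:n_x) %% 5L == 0L
  y_major <- (0:n_y) %% 5L == 0L

  yy <- (y_lo:y_hi)[(y_lo:y_hi) < layout$height] + 1L
  xx <- (x_lo:x_hi)[(x_lo:x_hi) < layout$width] + 1L
  for (ch in 1:3) {
    image[yy, xs[!x_major] + 1L, ch] <- config$grid_minor[ch]
    image[ys[!y_major] + 1L, xx, ch] <- config$grid_minor[ch]
    image[yy, xs[x_major] + 1L, ch] <- config$grid_major[ch]
    image[ys[y_major] + 1L, xx, ch] <- config$grid_major[ch]
  }
  image
}

#' Map (lead, time, voltage) to a pixel
#'
#' `col = x0 + round((t - t0) * px_per_second)`;
#' `row = baseline - round(v * px_per_mv)`. The inverse ([time_voltage_of()])
#' recovers `(t, v)` to within one pixel of quantisation.
#'
#' @param layout An `ecg_layout`.
#' @param lead Lead name; when the lead appears in several boxes (rhythm
#'   strip) the box whose window contains `t` with the longest window wins.
#' @param t Time in seconds (must fall in a displayed window).
#' @param v Voltage in mV.
#' @return Integer `c(row, col)`, 0-based.
#' @export
pixel_of <- function(layout, lead, t, v) {
  t <- as.numeric(t); v <- as.numeric(v)
  box <- lead_box(layout, lead, t)
  c(row = as.integer(box$baseline_row - round(v * layout$px_per_mv)),
    col = as.integer(box$x0 + round((t - box$t0) * layout$px_per_second)))
}

#' @rdname pixel_of
#' @param row,col 0-based pixel coordinates.
#' @return For `time_voltage_of`: `c(t, v)`.
#' @export
time_voltage_of <- function(layout, lead, row, col) {
  row <- as.numeric(row); col <- as.numeric(col)
  boxes <- layout$leads[layout$leads$lead == lead, ]
  boxes <- boxes[boxes$x0 <= col & col < boxes$x1, ]
  if (nrow(boxes) == 0) {
    stop_ecgforge("Pixel column outside the lead's boxes.", "ecgforge_invalid_argument")
  }
  box <- boxes[which.max(boxes$win_s), ]
  c(t = box$t0 + (col - box$x0) / layout$px_per_second,
    v = (box$baseline_row - row) / layout$px_per_mv)
}

lead_box <- function(layout, lead, t = NULL) {
  boxes <- layout$leads[layout$leads$lead == lead, ]
  if (nrow(boxes) == 0) {
    stop_ecgforge(sprintf("Unknown lead '%s'.", lead), "ecgforge_invalid_argument")
  }
  if (!is.null(t)) {
    boxes <- boxes[boxes$t0 - 1e-9 <= t & t < boxes$t0 + boxes$win_s + 1e-9, ]
    if (nrow(boxes) == 0) {
      stop_ecgforge(sprintf("t = %g s outside the displayed window of lead %s.",
                            t, lead), "ecgforge_invalid_argument")
    }
  }
  boxes[which.max(boxes$win_s), ]
}

#' @export
print.ecg_render <- function(x, ...) {
  cat(sprintf("<ecg_render> %d x %d px, %g px/mm, %d lead boxes, %d mask classes\n",
              x$layout$height, x$layout$width, x$layout$px_per_mm,
              nrow(x$layout$leads), length(setdiff(unique(as.vector(x$mask)), 0L))))
  invisible(x)
}
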