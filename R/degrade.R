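# Synthetic image degradation: a light-weight stand-in for the artefact seen
# on printed/photographed ECGs (small rotation, blur, uneven lighting,
# stains). Operates on the image only — masks are never modified.

#' Degrade a rendered ECG image with synthetic artefact
#'
#' Applies the requested artefacts in a fixed order (rotation, blur,
#' brightness gradient, blotches), deterministically for a given seed. The
#' paired pixel mask is deliberately untouched: degradation emulates
#' acquisition artefact, not changed wave semantics.
#'
#' @param image H x W x 3 integer array (0-255).
#' @param artefact Named list drawn from: `rotation` (degrees, |angle| <= 5,
#'   bilinear resampling, white fill), `blur_sigma` (pixels, separable
#'   Gaussian), `brightness` (relative amplitude of a horizontal lighting
#'   ramp, e.g. 0.3), `blotches` (count of random dark elliptical stains).
#'   An empty list returns the image unchanged.
#' @param seed Integer seed for the random elements.
#' @return Degraded image, same dimensions.
#' @export
#' @examples
#' img <- array(255L, dim = c(40, 40, 3))
#' out <- degrade_image(img, list(rotation = 2, blur_sigma = 1), seed = 1)
#' dim(out)
degrade_image <- function(image, artefact = list(), seed = 0L) {
  known <- c("rotation", "blur_sigma", "brightness", "blotches")
  bad <- setdiff(names(artefact), known)
  if (length(bad) > 0) {
    stop_ecgforge(sprintf("Unknown artefact(s): %s.",
                          paste0("'", bad, "'", collapse = ", ")),
                  "ecgforge_invalid_argument")
  }
  if (length(artefact) == 0) return(image)
  out <- image

  withr::with_seed(as.integer(derive_seed(seed, 11L)), {
    if (!is.null(artefact$rotation)) {
      check_number(artefact$rotation, "rotation", lower = -5, upper = 5)
      out <- rotate_bilinear(out, artefact$rotation)
    }
    if (!is.null(artefact$blur_sigma)) {
      check_number(artefact$blur_sigma, "blur_sigma", lower = 0)
      if (artefact$blur_sigma > 0) out <- gaussian_blur(out, artefact$blur_sigma)
    }
    if (!is.null(artefact$brightness)) {
      check_number(artefact$brightness, "brightness", lower = 0, upper = 1)
      w <- dim(out)[2]
      ramp <- 1 - artefact$brightness * (seq_len(w) - 1) / (w - 1)
      for (ch in 1:3) out[, , ch] <- sweep(out[, , ch], 2, ramp, `*`)
    }
    if (!is.null(artefact$blotches)) {
      out <- add_blotches(out, as.integer(artefact$blotches))
    }
  })
  arr <- round(out)
  arr[arr < 0] <- 0L
  arr[arr > 255] <- 255L
  storage.mode(arr) <- "integer"
  arr
}

# Rotate about the image centre with bilinear interpolation, white fill.
rotate_bilinear <- function(image, degrees) {
  h <- dim(image)[1]; w <- dim(image)[2]
  th <- degrees * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ri <- rep(seq_len(h), times = w) - cy
  ci <- rep(seq_len(w), each = h) - cx
  # inverse map: source coordinates of each destination pixel
  sr <- cos(th) * ri + sin(th) * ci + cy
  sc <- -sin(th) * ri + cos(th) * ci + cx
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  inside <- r0 >= 1 & r0 < h & c0 >= 1 & c0 < w
  out <- array(255, dim = dim(image))
  idx <- function(r, c) cbind(r[inside], c[inside])
  for (ch in 1:3) {
    m <- image[, , ch]
    v <- (1 - fr[inside]) * (1 - fc[inside]) * m[idx(r0, c0)] +
      (1 - fr[inside]) * fc[inside] * m[idx(r0, c0 + 1)] +
      fr[inside] * (1 - fc[inside]) * m[idx(r0 + 1, c0)] +
      fr[inside] * fc[inside] * m[idx(r0 + 1, c0 + 1)]
    plane <- rep(255, h * w)
    plane[inside] <- v
    out[, , ch] <- plane
  }
  out
}

# Separable Gaussian blur via stats::filter on rows then columns.
gaussian_blur <- function(image, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  out <- image
  for (ch in 1:3) {
    m <- image[, , ch]
    m <- apply(m, 2, function(col) pad_filter(col, k))
    m <- t(apply(m, 1, function(row) pad_filter(row, k)))
    out[, , ch] <- m
  }
  out
}

pad_filter <- function(x, k) {
  half <- (length(k) - 1L) %/% 2L
  padded <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(padded, k, sides = 2))[(half + 1):(half + length(x))]
}

# Random dark elliptical stains.
add_blotches <- function(image, n_blotches) {
  h <- dim(image)[1]; w <- dim(image)[2]
  for (i in seq_len(n_blotches)) {
    cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
    ry <- stats::runif(1, 0.01, 0.04) * h; rx <- stats::runif(1, 0.01, 0.04) * w
    shade <- stats::runif(1, 0.2, 0.6)
    rows <- max(1, floor(cy - ry)):min(h, ceiling(cy + ry))
    cols <- max(1, floor(cx - rx)):min(w, ceiling(cx + rx))
    d <- outer(((rows - cy) / ry)^2, ((cols - cx) / rx)^2, `+`)
    hit <- d <= 1
    for (ch in 1:3) {
      patch <- image[rows, cols, ch]
      patch[hit] <- patch[hit] * shade
      image[rows, cols, ch] <- patch
    }
  }
  image
}
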