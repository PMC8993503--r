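# Dataset generation and the on-disk record format: little-endian float32
# sample arrays + uint8 label arrays + JSON sidecars, listed by a JSON-lines
# manifest. Everything is reproducible from (n, seed, class_spec).

#' Default rhythm-by-phenotype composition
#'
#' Equal proportions over the 2 rhythms x 6 phenotypes grid.
#'
#' @return A tibble with columns `rhythm`, `phenotype`, `prop` (sums to 1).
#' @export
default_class_spec <- function() {
  grid <- tidyr::expand_grid(rhythm = ecg_rhythms(), phenotype = ecg_phenotypes())
  dplyr::mutate(grid, prop = 1 / nrow(grid))
}

# Largest-remainder apportionment of n into round(n * prop) counts.
apportion <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a reproducible labelled ECG dataset
#'
#' Synthesises `n` records whose rhythm/phenotype composition follows
#' `class_spec`, each from its own derived seed
#' (`record seed = (seed * 48271 + index * 1009) mod (2^31 - 1)`) so any
#' record can be regenerated independently. Class counts match the requested
#' proportions to within rounding (largest-remainder apportionment); record
#' order is a seeded shuffle of the class assignments.
#'
#' With `out_dir` set, each record is written as a flat little-endian 32-bit
#' float sample array (12 x N, lead-major), a uint8 label array, and a JSON
#' sidecar with the full configuration, plus a JSON-lines `manifest.jsonl`;
#' the same call is byte-reproducible. Without `out_dir` the signals are
#' returned in-memory in a list-column.
#'
#' @param n Number of records (>= 1).
#' @param seed Dataset seed.
#' @param class_spec Tibble with columns `rhythm`, `phenotype`, `prop`
#'   (proportions summing to 1 within 1e-9). Default: [default_class_spec()].
#' @param out_dir Output directory (created if needed), or `NULL` to keep
#'   records in memory.
#' @param noise Apply [add_noise_and_wander()] to each record (default TRUE).
#' @param overrides Extra [sample_config()] overrides applied to every record
#'   (e.g. a common `mean_heart_rate`).
#' @return The manifest tibble: `id`, `seed`, `rhythm`, `phenotype`, and
#'   either file path columns (`signal`, `labels`, `sidecar`) or a `record`
#'   list-column of `ecg_signal` objects.
#' @export
#' @examples
#' m <- generate_dataset(4, seed = 1,
#'   class_spec = tibble::tibble(rhythm = c("SR", "AF"),
#'                               phenotype = "NORMAL", prop = c(0.5, 0.5)))
#' dplyr::count(m, rhythm)
generate_dataset <- function(n, seed, class_spec = default_class_spec(),
                             out_dir = NULL, noise = TRUE, overrides = list()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    stop_ecgforge("`n` must be a positive integer.", "ecgforge_invalid_argument")
  }
  class_spec <- tibble::as_tibble(class_spec)
  if (!all(c("rhythm", "phenotype", "prop") %in% names(class_spec))) {
    stop_ecgforge("`class_spec` needs columns rhythm, phenotype, prop.",
                  "ecgforge_invalid_argument")
  }
  if (abs(sum(class_spec$prop) - 1) > 1e-9) {
    stop_ecgforge("`class_spec$prop` must sum to 1.", "ecgforge_invalid_argument")
  }

  counts <- apportion(n, class_spec$prop)
  assignment <- class_spec[rep(seq_len(nrow(class_spec)), counts),
                           c("rhythm", "phenotype")]
  shuffle <- withr::with_seed(as.integer(derive_seed(seed, 97L)),
                              sample.int(n))
  assignment <- assignment[shuffle, ]

  manifest <- tibble::tibble(
    id = sprintf("rec_%06d", seq_len(n)),
    seed = vapply(seq_len(n), function(i) record_seed(seed, i), integer(1)),
    rhythm = assignment$rhythm,
    phenotype = assignment$phenotype
  )

  make_record <- function(i) {
    cfg <- sample_config(
      manifest$seed[i],
      overrides = c(list(rhythm = manifest$rhythm[i],
                         phenotype = manifest$phenotype[i]),
                    overrides)
    )
    sig <- synthesize_ecg(cfg)
    if (noise) sig <- add_noise_and_wander(sig) else sig
  }

  if (is.null(out_dir)) {
    manifest$record <- lapply(seq_len(n), make_record)
    return(manifest)
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop_ecgforge(sprintf("Cannot create output directory '%s'.", out_dir),
                  "ecgforge_io_error")
  }
  paths <- purrr::map(seq_len(n), function(i) {
    write_signal_record(make_record(i), out_dir, manifest$id[i])
  })
  manifest$signal <- purrr::map_chr(paths, "signal")
  manifest$labels <- purrr::map_chr(paths, "labels")
  manifest$sidecar <- purrr::map_chr(paths, "sidecar")

  lines <- vapply(seq_len(n), function(i) {
    jsonlite::toJSON(list(
      id = manifest$id[i], seed = manifest$seed[i],
      rhythm = manifest$rhythm[i], phenotype = manifest$phenotype[i],
      signal = basename(manifest$signal[i]),
      labels = basename(manifest$labels[i]),
      sidecar = basename(manifest$sidecar[i])
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, file.path(out_dir, "manifest.jsonl"))
  manifest
}

#' Write one labelled signal record to disk
#'
#' @param signal An `ecg_signal`.
#' @param out_dir Directory.
#' @param id Record id used as the filename stem.
#' @return Named list of the paths written (`signal`, `labels`, `sidecar`).
#' @export
write_signal_record <- function(signal, out_dir, id) {
  stopifnot(inherits(signal, "ecg_signal"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sig_path <- file.path(out_dir, paste0(id, ".f32"))
  lab_path <- file.path(out_dir, paste0(id, ".u8"))
  meta_path <- file.path(out_dir, paste0(id, ".json"))

  con <- file(sig_path, "wb")
  writeBin(as.vector(t(signal$samples)), con, size = 4L, endian = "little")
  close(con)
  con <- file(lab_path, "wb")
  writeBin(as.raw(as.vector(t(signal$labels))), con)
  close(con)

  cfg <- signal$config
  meta <- list(
    id = id,
    n_leads = 12L, n_samples = ncol(signal$samples),
    sampling_rate = cfg$sampling_rate,
    rhythm = signal$rhythm, phenotype = signal$phenotype,
    clean = isTRUE(signal$clean),
    signal_file = basename(sig_path), labels_file = basename(lab_path),
    config = unclass(cfg)
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), meta_path)
  list(signal = sig_path, labels = lab_path, sidecar = meta_path)
}

#' Read a record written by [write_signal_record()]
#'
#' @param sidecar Path to the record's JSON sidecar.
#' @return An `ecg_signal` (schedule omitted; regenerate from the embedded
#'   config if needed).
#' @export
read_signal_record <- function(sidecar) {
  meta <- jsonlite::fromJSON(sidecar)
  dir <- dirname(sidecar)
  n <- meta$n_samples
  con <- file(file.path(dir, meta$signal_file), "rb")
  raw_sig <- readBin(con, what = "numeric", n = 12L * n, size = 4L,
                     endian = "little")
  close(con)
  con <- file(file.path(dir, meta$labels_file), "rb")
  raw_lab <- as.integer(readBin(con, what = "raw", n = 12L * n))
  close(con)

  cfg <- meta$config
  cfg$wave_params <- as.list(cfg$wave_params)
  class(cfg) <- "simulation_config"
  structure(
    list(
      samples = matrix(raw_sig, nrow = 12L, byrow = TRUE,
                       dimnames = list(ecg_leads(), NULL)),
      labels = matrix(raw_lab, nrow = 12L, byrow = TRUE,
                      dimnames = list(ecg_leads(), NULL)),
      config = cfg, schedule = NULL,
      rhythm = meta$rhythm, phenotype = meta$phenotype,
      clean = isTRUE(meta$clean)
    ),
    class = "ecg_signal"
  )
}

#' Read a JSON-lines dataset manifest
#'
#' @param path Path to `manifest.jsonl` (or its directory).
#' @return Manifest tibble with absolute file path columns.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.jsonl")
  rows <- purrr::map(readLines(path), jsonlite::fromJSON)
  dir <- dirname(path)
  tibble::tibble(
    id = purrr::map_chr(rows, "id"),
    seed = purrr::map_int(rows, ~ as.integer(.x$seed)),
    rhythm = purrr::map_chr(rows, "rhythm"),
    phenotype = purrr::map_chr(rows, "phenotype"),
    signal = file.path(dir, purrr::map_chr(rows, "signal")),
    labels = file.path(dir, purrr::map_chr(rows, "labels")),
    sidecar = file.path(dir, purrr::map_chr(rows, "sidecar"))
  )
}
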