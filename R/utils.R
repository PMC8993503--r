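# Internal helpers: seed derivation, run-length scanning, input checks.

# Derive a child seed from a parent seed and a stream index, keeping the
# result a valid 32-bit integer. Used so that every randomised stage
# (config sampling, beat scheduling, noise, artefact) draws from its own
# reproducible stream.
derive_seed <- function(seed, stream) {
  ((as.numeric(seed) %% 2147483647) * 48271 + as.numeric(stream) * 1009) %%
    2147483647
}

# Per-record seed in a dataset: documented splitting rule so each record is
# independently reproducible from (dataset seed, record index).
record_seed <- function(dataset_seed, index) {
  as.integer(derive_seed(dataset_seed, index))
}

# Maximal runs of `value` in an integer vector, as half-open [onset, offset)
# 0-based sample indices. Returns a two-column matrix.
label_runs <- function(x, value) {
  r <- rle(x == value)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  cbind(onset = starts[keep], offset = ends[keep])
}

stop_ecgforge <- function(message, class) {
  rlang::abort(message, class = c(class, "ecgforge_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_ecgforge(
      sprintf("`%s` must be a single finite number in [%s, %s], got %s.",
              name, format(lower), format(upper),
              paste(format(x), collapse = ", ")),
      "ecgforge_invalid_argument"
    )
  }
  invisible(x)
}

check_choice <- function(x, name, choices) {
  if (!is.character(x) || length(x) != 1L || !x %in% choices) {
    stop_ecgforge(
      sprintf("`%s` must be one of %s.", name,
              paste0("'", choices, "'", collapse = ", ")),
      "ecgforge_invalid_argument"
    )
  }
  invisible(x)
}
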