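# Classification metrics, segmentation overlap scores, and deterministic
# stratified dataset splitting.

#' Build confusion counts from paired calls
#'
#' @param pred,truth Character vectors of class calls.
#' @param positive The positive class label (e.g. `"AF"`).
#' @return One-row tibble `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth, positive) {
  stopifnot(length(pred) == length(truth))
  p <- pred == positive
  t <- truth == positive
  tibble::tibble(
    tp = sum(p & t), fp = sum(p & !t), tn = sum(!p & !t), fn = sum(!p & t)
  )
}

metric_from_counts <- function(num, den, name) {
  if (den == 0) {
    stop_ecgforge(sprintf("%s is undefined: zero denominator.", name),
                  "ecgforge_undefined_metric")
  }
  num / den
}

#' Sensitivity, specificity and positive predictive value
#'
#' `tp/(tp+fn)`, `tn/(tn+fp)` and `tp/(tp+fp)` respectively. A zero
#' denominator raises an error of class `ecgforge_undefined_metric`.
#'
#' @param counts A [confusion_counts()] row (or any list with `tp`, `fp`,
#'   `tn`, `fn`).
#' @return A single number.
#' @export
sensitivity <- function(counts) {
  metric_from_counts(counts$tp, counts$tp + counts$fn, "Sensitivity")
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  metric_from_counts(counts$tn, counts$tn + counts$fp, "Specificity")
}

#' @rdname sensitivity
#' @export
ppv <- function(counts) {
  metric_from_counts(counts$tp, counts$tp + counts$fp, "PPV")
}

#' F1 score from sensitivity and PPV
#'
#' The harmonic mean `2 * sens * ppv / (sens + ppv)`. Defined as 0 when both
#' inputs are 0 (the degenerate all-negative predictor).
#'
#' @param sens Sensitivity (recall) in `[0, 1]`.
#' @param ppv_val Positive predictive value (precision) in `[0, 1]`.
#' @return F1 in `[0, 1]`. Vectorised.
#' @export
#' @examples
#' f1_score(0.9, 0.75)
f1_score <- function(sens, ppv_val) {
  stopifnot(all(sens >= 0 & sens <= 1), all(ppv_val >= 0 & ppv_val <= 1))
  ifelse(sens + ppv_val == 0, 0, 2 * sens * ppv_val / (sens + ppv_val))
}

#' Summarise a prediction set in the standard metric table
#'
#' @param pred,truth Class call vectors.
#' @param positive Positive class.
#' @return Tibble with columns `metric` (`Sensitivity`, `Specificity`,
#'   `PPV`, `F1`) and `value`.
#' @export
classification_report <- function(pred, truth, positive) {
  c_ <- confusion_counts(pred, truth, positive)
  sens <- if (c_$tp + c_$fn > 0) c_$tp / (c_$tp + c_$fn) else NA_real_
  spec <- if (c_$tn + c_$fp > 0) c_$tn / (c_$tn + c_$fp) else NA_real_
  ppv_v <- if (c_$tp + c_$fp > 0) c_$tp / (c_$tp + c_$fp) else 0
  f1 <- if (is.na(sens)) NA_real_ else f1_score(sens, max(ppv_v, 0, na.rm = TRUE))
  tibble::tibble(
    metric = c("Sensitivity", "Specificity", "PPV", "F1"),
    value = c(sens, spec, ppv_v, f1)
  )
}

#' Dice and Jaccard overlap for segmentation masks
#'
#' For each class, binarises both masks and computes the smoothed Dice
#' coefficient `(2|A∩B| + s) / (|A| + |B| + s)` and Jaccard index (IoU)
#' `(|A∩B| + s) / (|A∪B| + s)`. Smoothing (default 1) stabilises classes
#' absent from both masks.
#'
#' @param pred_mask,truth_mask Integer class arrays of identical shape.
#' @param class_id Classes to score (default 1-7, i.e. all wave classes).
#' @param smooth Smoothing constant added to numerator and denominator.
#' @return Tibble with one row per class (`class`, `dice`, `iou`) plus the
#'   macro average over the requested classes as attribute `macro` (named
#'   vector `dice`, `iou`).
#' @export
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(1, 0, 0, 0), 2)
#' dice_jaccard(a, b, class_id = 1, smooth = 0)
dice_jaccard <- function(pred_mask, truth_mask, class_id = 1:7, smooth = 1) {
  if (!identical(dim(pred_mask), dim(truth_mask)) ||
      length(pred_mask) != length(truth_mask)) {
    stop_ecgforge("Prediction and truth masks must have identical shape.",
                  "ecgforge_invalid_argument")
  }
  out <- purrr::map_dfr(class_id, function(k) {
    a <- pred_mask == k
    b <- truth_mask == k
    inter <- sum(a & b)
    na <- sum(a); nb <- sum(b)
    tibble::tibble(
      class = k,
      dice = (2 * inter + smooth) / (na + nb + smooth),
      iou = (inter + smooth) / (na + nb - inter + smooth)
    )
  })
  attr(out, "macro") <- c(dice = mean(out$dice), iou = mean(out$iou))
  out
}

#' Deterministic stratified train/validation/test split
#'
#' Seeded shuffle followed by a 60:20:20 partition (by default). The split
#' is stratified: within each stratum records are apportioned so that every
#' stratum's proportions track the global ones (cumulative rounding keeps
#' the overall sizes exact to within one record), which keeps minority-class
#' test folds non-empty at small n. With `group_by`, whole groups (e.g.
#' subjects contributing several records) are assigned to a single fold.
#'
#' @param manifest Data frame with an `id` column (and the stratum/group
#'   columns, if used). At least 5 records.
#' @param seed Integer seed.
#' @param props Named numeric proportions summing to 1
#'   (default `c(train = .6, val = .2, test = .2)`).
#' @param stratify_by Column name to stratify on (e.g. `"rhythm"`), or
#'   `NULL`.
#' @param group_by Column name whose groups must not straddle folds, or
#'   `NULL` (default; record-level splitting).
#' @return Tibble `id`, `split` (factor train/val/test), one row per record.
#' @export
split_dataset <- function(manifest, seed,
                          props = c(train = 0.6, val = 0.2, test = 0.2),
                          stratify_by = NULL, group_by = NULL) {
  manifest <- tibble::as_tibble(manifest)
  if (nrow(manifest) < 5) {
    stop_ecgforge("At least 5 records are required for a 60:20:20 split.",
                  "ecgforge_invalid_argument")
  }
  if (abs(sum(props) - 1) > 1e-9) {
    stop_ecgforge("`props` must sum to 1.", "ecgforge_invalid_argument")
  }
  splits <- names(props)

  unit <- if (is.null(group_by)) {
    tibble::tibble(key = manifest$id,
                   stratum = if (is.null(stratify_by)) "all" else
                     as.character(manifest[[stratify_by]]))
  } else {
    manifest |>
      dplyr::group_by(key = .data[[group_by]]) |>
      dplyr::summarise(stratum = if (is.null(stratify_by)) "all" else
        as.character(dplyr::first(.data[[stratify_by]])), .groups = "drop")
  }

  unit <- withr::with_seed(as.integer(derive_seed(seed, 7L)), {
    unit[sample.int(nrow(unit)), ]
  })
  unit <- unit[order(unit$stratum, method = "radix"), ]

  # allocate per stratum with cumulative rounding so overall sizes are exact
  allocated <- stats::setNames(numeric(length(props)), splits)
  target_cum <- stats::setNames(numeric(length(props)), splits)
  unit$split <- NA_character_
  for (s in unique(unit$stratum)) {
    idx <- which(unit$stratum == s)
    n_s <- length(idx)
    target_cum <- target_cum + n_s * props
    take <- round(target_cum) - allocated
    # guard rounding interplay: total must equal n_s
    while (sum(take) > n_s) take[which.max(take)] <- take[which.max(take)] - 1
    while (sum(take) < n_s) take[which.min(take)] <- take[which.min(take)] + 1
    unit$split[idx] <- rep(splits, times = take)
    allocated <- allocated + take
  }

  assignment <- if (is.null(group_by)) {
    dplyr::left_join(tibble::tibble(id = manifest$id),
                     dplyr::select(unit, id = "key", "split"), by = "id")
  } else {
    dplyr::left_join(
      tibble::tibble(id = manifest$id, key = as.character(manifest[[group_by]])),
      dplyr::select(unit, "key", "split"), by = "key"
    ) |> dplyr::select("id", "split")
  }
  dplyr::mutate(assignment, split = factor(.data$split, levels = splits))
}

#' Published operating points bundled for worked examples
#'
#' Sensitivity/PPV operating points of several reference ECG classifiers
#' (1D and 2D, AF and MI tasks), shipped as a plain CSV. Used in the worked
#' examples and the acceptance script to demonstrate that [f1_score()]
#' reproduces the corresponding published F1 values.
#'
#' @return Tibble with columns `task`, `model`, `sensitivity`, `ppv`,
#'   `f1_published`.
#' @export
reference_operating_points <- function() {
  path <- system.file("extdata", "reference_operating_points.csv",
                      package = "ecgforge", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
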