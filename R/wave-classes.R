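# Wave-class codes shared by every mask and label sequence in the package.

#' Wave segmentation classes
#'
#' Every per-sample label and every mask pixel emitted anywhere in ecgforge is
#' one of eight integer codes: 0 background, 1 P wave, 2 P-R interval, 3 QRS
#' complex, 4 ST segment, 5 T wave, 6 T-P segment, 7 T/P overlap (samples
#' covered by both a T wave and the following beat's P wave).
#'
#' @return A tibble with columns `code` (integer 0-7), `class` (short name)
#'   and `description`.
#' @export
#' @examples
#' wave_classes()
wave_classes <- function() {
  tibble::tibble(
    code = 0:7,
    class = c("background", "P", "PR", "QRS", "ST", "T", "TP", "TP_overlap"),
    description = c(
      "background / no wave", "P wave", "P-R interval", "QRS complex",
      "ST segment", "T wave", "T-P segment", "T/P overlap"
    )
  )
}

# Integer codes used internally.
CLASS_BG <- 0L
CLASS_P <- 1L
CLASS_PR <- 2L
CLASS_QRS <- 3L
CLASS_ST <- 4L
CLASS_T <- 5L
CLASS_TP <- 6L
CLASS_TP_OVERLAP <- 7L

#' Standard 12-lead names in package order
#'
#' Lead order used for every 12 x N sample or label matrix: I, II, III, aVR,
#' aVL, aVF, V1-V6.
#'
#' @return Character vector of length 12.
#' @export
ecg_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF", "V1", "V2", "V3", "V4", "V5", "V6")
}

#' @export
#' @rdname ecg_rhythms
ecg_rhythms <- function() c("SR", "AF")

#' Closed rhythm and phenotype vocabularies
#'
#' The simulator emits either sinus rhythm (`SR`) or atrial fibrillation
#' (`AF`), and one of six morphological phenotypes: `NORMAL`, `LAHB` (left
#' anterior hemiblock), `LPHB` (left posterior hemiblock), `HIGH_TAKEOFF`
#' (benign anterior ST take-off), `LBBB` (left bundle branch block) and
#' `ANTERIOR_STE` (anterior ST-elevation infarct pattern).
#'
#' @return Character vector of the allowed values.
#' @name ecg_rhythms
#' @export
ecg_phenotypes <- function() {
  c("NORMAL", "LAHB", "LPHB", "HIGH_TAKEOFF", "LBBB", "ANTERIOR_STE")
}
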