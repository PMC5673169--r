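#' Per-animal measurement record
#'
#' Bundles one animal's longitudinal palpated tumor volumes, necropsy data and
#' qPCR counts. Volumes are palpated sizes in cm^3; CTC counts are per 20 ng
#' blood-DNA template and DTC counts per 60 ng tissue-DNA template.
#'
#' @param mouse_id Character scalar identifier.
#' @param group One of `"control"`, `"chemo"`, `"radio"`.
#' @param days Numeric vector of measurement days, strictly increasing,
#'   non-negative. Day 0 is the first palpated measurement used in regression.
#' @param palpated_volumes Numeric vector of volumes (cm^3) aligned to `days`.
#' @param necropsy_weight Tumor mass at necropsy (g), positive.
#' @param necropsy_day Day of necropsy, at or after the last measurement.
#' @param ctc_count CTC count per 20 ng template (non-negative).
#' @param dtc_counts Named numeric vector, organ -> count per 60 ng template.
#' @param treatment_start_day First treatment day; required for treated
#'   groups, must be absent (`NULL`) for controls.
#'
#' @return An object of class `mouse_record`.
#' @export
mouse_record <- function(mouse_id, group = c("control", "chemo", "radio"),
                         days, palpated_volumes,
                         necropsy_weight, necropsy_day,
                         ctc_count = NA_real_, dtc_counts = numeric(),
                         treatment_start_day = NULL) {
  group <- match.arg(group)
  days <- as.numeric(days)
  palpated_volumes <- as.numeric(palpated_volumes)
  if (length(days) == 0L || length(days) != length(palpated_volumes))
    stopf("mouse %s: days and volumes must be non-empty and aligned", mouse_id)
  if (any(days < 0)) stopf("mouse %s: negative measurement day", mouse_id)
  if (any(diff(days) <= 0)) stopf("mouse %s: days must be strictly increasing", mouse_id)
  if (any(palpated_volumes < 0)) stopf("mouse %s: negative volume", mouse_id)
  if (!is_number(necropsy_weight) || necropsy_weight <= 0)
    stopf("mouse %s: necropsy weight must be > 0", mouse_id)
  if (!is_number(necropsy_day) || necropsy_day < max(days))
    stopf("mouse %s: necropsy day before last measurement", mouse_id)
  if (!is.na(ctc_count) && ctc_count < 0) stopf("mouse %s: negative CTC count", mouse_id)
  if (length(dtc_counts) && any(dtc_counts < 0)) stopf("mouse %s: negative DTC count", mouse_id)
  if (group == "control" && !is.null(treatment_start_day))
    stopf("mouse %s: control animals cannot have a treatment start day", mouse_id)
  if (group != "control" && is.null(treatment_start_day))
    stopf("mouse %s: treated animals need a treatment start day", mouse_id)
  structure(list(
    mouse_id = as.character(mouse_id), group = group,
    days = days, palpated_volumes = palpated_volumes,
    necropsy_weight = necropsy_weight, necropsy_day = necropsy_day,
    ctc_count = ctc_count, dtc_counts = dtc_counts,
    treatment_start_day = treatment_start_day,
    correction_factor = NA_real_
  ), class = "mouse_record")
}

#' @export
print.mouse_record <- function(x, ...) {
  cat(sprintf("<mouse_record %s> group=%s, %d measurements over days [%g, %g]\n",
              x$mouse_id, x$group, length(x$days), min(x$days), max(x$days)))
  cat(sprintf("  necropsy: %.3g g on day %g; CTC/20ng: %s; DTC organs: %s\n",
              x$necropsy_weight, x$necropsy_day,
              format(x$ctc_count), paste(names(x$dtc_counts), collapse = ",")))
  invisible(x)
}

#' Convert tumor volume to cell number and back
#'
#' A tumor of volume 1 cm^3 is taken to contain 1e9 cells.
#'
#' @param volume Tumor volume(s), cm^3, non-negative.
#' @return Number of cells.
#' @export
volume_to_cells <- function(volume) {
  if (any(volume < 0)) stopf("volume must be non-negative")
  volume * CELLS_PER_CM3
}

#' @rdname volume_to_cells
#' @param cells Cell number(s), non-negative.
#' @export
cells_to_volume <- function(cells) {
  if (any(cells < 0)) stopf("cell count must be non-negative")
  cells / CELLS_PER_CM3
}

#' Necropsy weight to tumor volume
#'
#' Tumor tissue is assumed to have unit density (1 g/cm^3, approximately
#' water), so weight in grams maps one-to-one to volume in cm^3.
#'
#' @param weight_g Mass in grams.
#' @return Volume in cm^3.
#' @export
weight_to_volume <- function(weight_g) {
  if (any(weight_g < 0)) stopf("weight must be non-negative")
  weight_g / TUMOR_DENSITY_G_PER_CM3
}

#' Correct a palpated volume series against the necropsy weight
#'
#' Palpation against comparison spheres carries a systematic scale error; the
#' excised tumor's weight is the more precise measurement. The whole series is
#' rescaled by a single multiplicative factor
#' `f = (necropsy weight / 1 g cm^-3) / last palpated volume`
#' so that the corrected final volume equals the necropsy-derived volume.
#' The factor is stored in `$correction_factor`. The operation is idempotent:
#' after correction `f = 1`.
#'
#' @param record A [mouse_record()].
#' @return The record with corrected volumes and the factor recorded.
#' @export
correct_palpation_series <- function(record) {
  stopifnot(inherits(record, "mouse_record"))
  last_vol <- record$palpated_volumes[length(record$palpated_volumes)]
  if (last_vol <= 0)
    stopf("mouse %s: last palpated volume is zero; correction undefined", record$mouse_id)
  f <- weight_to_volume(record$necropsy_weight) / last_vol
  record$palpated_volumes <- record$palpated_volumes * f
  record$correction_factor <- f
  record
}
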