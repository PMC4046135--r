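#' Normalize raw viability readouts to percent growth inhibition
#'
#' Converts raw plate readouts (e.g. luminescence from a viability assay) into
#' relative growth inhibition percentages using the per-plate negative control
#' (DMSO, defining 0% inhibition) and positive control (benzethonium chloride,
#' defining 100% inhibition):
#' `100 * (negative_mean - raw) / (negative_mean - positive_mean)`,
#' clipped to \[0, 100\]. Readouts above the negative control (apparent growth
#' stimulation) therefore map to 0% inhibition.
#'
#' @param raw Numeric vector of raw readouts.
#' @param negative_mean Mean readout of the negative (DMSO) control wells.
#' @param positive_mean Mean readout of the positive (full-kill) control wells.
#' @return Numeric vector of percent inhibition values in \[0, 100\].
#' @examples
#' normalize_viability(c(1000, 550, 100), negative_mean = 1000, positive_mean = 100)
#' @export
normalize_viability <- function(raw, negative_mean, positive_mean) {
  if (!is.numeric(raw)) {
    stop_dsskit("raw readouts must be numeric", "dsskit_error_bad_input")
  }
  if (any(negative_mean == positive_mean)) {
    stop_dsskit(
      "degenerate plate controls: negative_mean equals positive_mean, plate is unusable",
      "dsskit_error_degenerate_controls"
    )
  }
  clip(100 * (negative_mean - raw) / (negative_mean - positive_mean), 0, 100)
}

#' Normalize a long dose-response table against plate controls
#'
#' Data-frame-first wrapper around [normalize_viability()]. When `data` has a
#' `plate_id` column and `controls` has one row per plate, controls are joined
#' by plate; otherwise `controls` must be a single row applied to every row of
#' `data`.
#'
#' @param data Long table with at least a `response` column holding raw
#'   readouts (plus whatever identifier columns you carry, e.g. `sample_id`,
#'   `drug_id`, `concentration_nM`, optionally `plate_id`).
#' @param controls Data frame with columns `negative_mean`, `positive_mean`
#'   and, when joining by plate, `plate_id`.
#' @return `data` with `response` replaced by percent inhibition in \[0, 100\].
#' @export
normalize_responses <- function(data, controls) {
  check_columns(data, "response", "dose-response table")
  check_columns(controls, c("negative_mean", "positive_mean"), "controls table")
  if ("plate_id" %in% names(data) && "plate_id" %in% names(controls)) {
    joined <- dplyr::left_join(data, controls[, c("plate_id", "negative_mean", "positive_mean")],
                               by = "plate_id")
    if (anyNA(joined$negative_mean)) {
      stop_dsskit("some plates in the data have no matching controls",
                  "dsskit_error_missing_controls")
    }
  } else {
    if (nrow(controls) != 1) {
      stop_dsskit("without a plate_id column, controls must be a single row",
                  "dsskit_error_missing_controls")
    }
    joined <- dplyr::mutate(data,
                            negative_mean = controls$negative_mean,
                            positive_mean = controls$positive_mean)
  }
  joined$response <- normalize_viability(joined$response,
                                         joined$negative_mean,
                                         joined$positive_mean)
  as_tibble(joined[, names(data), drop = FALSE])
}

#' Collapse technical replicates to per-dose medians
#'
#' Within each (sample, drug, concentration) cell the median response over
#' replicates is taken, and points are sorted by ascending concentration.
#' The operation is idempotent: applying it to already-collapsed data returns
#' the data unchanged.
#'
#' @param data Long dose-response table with columns `sample_id`, `drug_id`,
#'   `concentration_nM`, `response` (and optionally `replicate`).
#' @return Tibble with one row per (sample, drug, concentration), responses
#'   replaced by replicate medians.
#' @export
collapse_replicates <- function(data) {
  check_columns(data, c("sample_id", "drug_id", "concentration_nM", "response"),
                "dose-response table")
  data |>
    dplyr::group_by(.data$sample_id, .data$drug_id, .data$concentration_nM) |>
    dplyr::summarise(response = median(.data$response), .groups = "drop") |>
    dplyr::arrange(.data$sample_id, .data$drug_id, .data$concentration_nM)
}
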