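#' Quantify one imaging field: segment, detect spots, call positives
#'
#' Runs the per-field measurement cascade: nuclei from the nuclear
#' channel, cell regions from the actin channel, spot detection in the
#' AChR and marker channels, per-cell summed spot fluorescence, and
#' positivity calls by thresholding the sums.
#'
#' @param field An `image_field`.
#' @param achr_threshold,marker_threshold Positivity thresholds for the
#'   two readouts: a number, or `"otsu"` for the automatic log1p-Otsu
#'   split over this field's cells (a plate-level threshold computed from
#'   a control well can be passed as a number).
#' @param spot_sigma Spot scale in pixels passed to [detect_spots()].
#' @param min_response LoG detection threshold (see [detect_spots()]).
#' @return A list with `cells` (the `cell_label_map`), `records`
#'   (tibble: `cell_id`, `achr_sum`, `marker_sum`, `achr_pos`,
#'   `marker_pos`), `spots` (combined spot table) and `thresholds`
#'   (the numeric thresholds actually applied).
#' @export
quantify_field <- function(field, achr_threshold = "otsu",
                           marker_threshold = "otsu", spot_sigma = 1.6,
                           min_response = NULL) {
  stopifnot(inherits(field, "image_field"))
  nuclei <- detect_nuclei(field)
  cells <- segment_cells(field, nuclei)
  spots_achr <- detect_spots(field, cells, "achr", spot_sigma = spot_sigma,
                             min_response = min_response)
  spots_marker <- detect_spots(field, cells, "marker",
                               spot_sigma = spot_sigma,
                               min_response = min_response)
  achr <- per_cell_spot_sum(spots_achr, cells)
  marker <- per_cell_spot_sum(spots_marker, cells)

  thr_achr <- if (identical(achr_threshold, "otsu")) {
    otsu_log1p_threshold(achr$spot_sum)
  } else achr_threshold
  thr_marker <- if (identical(marker_threshold, "otsu")) {
    otsu_log1p_threshold(marker$spot_sum)
  } else marker_threshold

  records <- achr |>
    dplyr::rename(achr_sum = "spot_sum") |>
    dplyr::left_join(dplyr::rename(marker, marker_sum = "spot_sum"),
                     by = "cell_id") |>
    dplyr::mutate(
      achr_pos = call_positive(.data$achr_sum, thr_achr),
      marker_pos = call_positive(.data$marker_sum, thr_marker)
    )
  list(
    cells = cells,
    records = records,
    spots = dplyr::bind_rows(spots_achr, spots_marker),
    thresholds = c(achr = thr_achr, marker = thr_marker)
  )
}

#' Aggregate per-cell records into a well measurement
#'
#' For a complement-assay field (marker role `MAC`) reports the percent
#' AChR-positive cells and the percent MAC-positive cells within the
#' AChR-positive population. For a binding-assay field (marker role
#' `IgG`) reports the percent immunoglobulin-positive cells overall,
#' within the AChR-negative population (the background-correction
#' subtrahend) and within the AChR-positive population.
#'
#' @param quant Output of [quantify_field()].
#' @param field The `image_field` the records came from (supplies the
#'   marker role, arm and well id).
#' @return One-row tibble of well-level readouts.
#' @export
measure_well <- function(quant, field) {
  rec <- quant$records
  base <- tibble(
    well_id = field$well_id,
    arm = field$arm,
    n_cells = nrow(rec)
  )
  if (identical(field$marker_role, "MAC")) {
    dplyr::mutate(
      base,
      pct_achr_pos = percent_positive(rec$achr_pos),
      pct_mac_pos_in_achr_pos = mac_within_achr_pos(
        tibble(achr_pos = rec$achr_pos, mac_pos = rec$marker_pos)),
      pct_ig_pos = NA_real_,
      pct_ig_pos_in_achr_neg = NA_real_,
      pct_ig_pos_in_achr_pos = NA_real_
    )
  } else {
    neg <- rec$marker_pos[!rec$achr_pos]
    pos <- rec$marker_pos[rec$achr_pos]
    dplyr::mutate(
      base,
      pct_achr_pos = percent_positive(rec$achr_pos),
      pct_mac_pos_in_achr_pos = NA_real_,
      pct_ig_pos = percent_positive(rec$marker_pos),
      pct_ig_pos_in_achr_neg = if (length(neg)) percent_positive(neg) else NA_real_,
      pct_ig_pos_in_achr_pos = if (length(pos)) percent_positive(pos) else NA_real_
    )
  }
}
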