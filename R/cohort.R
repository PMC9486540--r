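#' Turn per-well measurements into per-patient readouts and categories
#'
#' Implements the full stratification stage: per-plate fold-change
#' normalization of the AChR and MAC readouts against the NHS-only control
#' well, background correction of immunoglobulin binding, averaging over
#' independent experiments (plates), ordinal classification of each
#' readout, anti-C7 blockade assessment and four-way category assignment.
#'
#' Expected columns of `wells`: `patient_id`, `arm` (see
#' [treatment_arms()]), `plate_id`, and the readouts `pct_achr_pos`,
#' `pct_mac_pos_in_achr_pos`, `pct_ig_pos`, `pct_ig_pos_in_achr_neg`
#' (percentages in \[0, 100\]; missing readouts may be `NA`). Replicate
#' wells within a plate are averaged first; fold changes are computed
#' within each plate against that plate's NHS-only well and then averaged
#' across plates (experiments) per patient, mirroring a mean-of-n-
#' experiments design. Classification happens after averaging.
#'
#' @param wells Data frame of per-well measurements (one row per well).
#' @param ig_minuend Population supplying the uncorrected Ig-binding
#'   percentage: `"all"` (default; % Ig-positive among all cells) or
#'   `"achr_pos"` (% Ig-positive within the AChR-positive population,
#'   requires a `pct_ig_pos_in_achr_pos` column).
#' @return A tibble with one row per patient: `patient_id`,
#'   `igg_binding_pct` (background-corrected mean), `igg_class`,
#'   `achr_fold`, `mac_fold`, `achr_class`, `mac_class`, `blockade`,
#'   `category`.
#' @export
#' @examples
#' wells <- simulate_cohort_wells(c(cat1 = 2, cat4 = 1), seed = 1)
#' stratify_cohort(wells)
stratify_cohort <- function(wells, ig_minuend = c("all", "achr_pos")) {
  ig_minuend <- match.arg(ig_minuend)
  wells <- as_tibble(wells)
  required <- c("patient_id", "arm", "plate_id", "pct_achr_pos",
                "pct_mac_pos_in_achr_pos", "pct_ig_pos",
                "pct_ig_pos_in_achr_neg")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols)) {
    abort(paste0("wells is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_arm <- setdiff(unique(wells$arm), ARM_LEVELS)
  if (length(bad_arm)) {
    abort(paste0("unknown treatment arm(s): ", paste(bad_arm, collapse = ", ")))
  }
  if (ig_minuend == "achr_pos" && !"pct_ig_pos_in_achr_pos" %in% names(wells)) {
    abort("ig_minuend = \"achr_pos\" requires a pct_ig_pos_in_achr_pos column")
  }

  ig_col <- if (ig_minuend == "all") "pct_ig_pos" else "pct_ig_pos_in_achr_pos"

  ## replicate wells -> per plate x arm means
  per_plate <- wells |>
    dplyr::group_by(.data$patient_id, .data$plate_id, .data$arm) |>
    dplyr::summarise(
      pct_achr_pos = mean(.data$pct_achr_pos, na.rm = TRUE),
      pct_mac_pos_in_achr_pos = mean(.data$pct_mac_pos_in_achr_pos, na.rm = TRUE),
      ig_uncorrected = mean(.data[[ig_col]], na.rm = TRUE),
      pct_ig_pos_in_achr_neg = mean(.data$pct_ig_pos_in_achr_neg, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(dplyr::across(
      c("pct_achr_pos", "pct_mac_pos_in_achr_pos", "ig_uncorrected",
        "pct_ig_pos_in_achr_neg"),
      \(v) ifelse(is.nan(v), NA_real_, v)
    ))

  ## per-plate fold changes against the plate's NHS-only well
  nhs <- per_plate |>
    dplyr::filter(.data$arm == "NHS_only") |>
    dplyr::select("patient_id", "plate_id",
                  nhs_achr = "pct_achr_pos",
                  nhs_mac = "pct_mac_pos_in_achr_pos")
  no_ctrl <- per_plate |>
    dplyr::distinct(.data$patient_id, .data$plate_id) |>
    dplyr::anti_join(nhs, by = c("patient_id", "plate_id"))
  if (nrow(no_ctrl)) {
    abort(paste0(
      "plate(s) without an NHS_only control well (fold change undefined): ",
      paste(paste(no_ctrl$patient_id, no_ctrl$plate_id, sep = "/"),
            collapse = ", ")
    ))
  }

  folds <- per_plate |>
    dplyr::filter(.data$arm != "NHS_only") |>
    dplyr::inner_join(nhs, by = c("patient_id", "plate_id")) |>
    dplyr::mutate(
      achr_fold = fold_change(.data$pct_achr_pos, .data$nhs_achr),
      mac_fold = fold_change(.data$pct_mac_pos_in_achr_pos, .data$nhs_mac)
    ) |>
    dplyr::group_by(.data$patient_id, .data$arm) |>
    dplyr::summarise(
      achr_fold = mean(.data$achr_fold, na.rm = TRUE),
      mac_fold = mean(.data$mac_fold, na.rm = TRUE),
      .groups = "drop"
    )

  fold_of <- function(arm_label, col) {
    folds |>
      dplyr::filter(.data$arm == arm_label) |>
      dplyr::select("patient_id", dplyr::all_of(col))
  }

  igg <- per_plate |>
    dplyr::mutate(
      igg_corrected = background_correct_ig(.data$ig_uncorrected,
                                            .data$pct_ig_pos_in_achr_neg)
    ) |>
    dplyr::filter(!is.na(.data$igg_corrected)) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(igg_binding_pct = mean(.data$igg_corrected),
                     .groups = "drop")

  out <- tibble(patient_id = unique(wells$patient_id)) |>
    dplyr::left_join(
      fold_of("plasma_NHS", c(achr_fold = "achr_fold", mac_fold = "mac_fold")),
      by = "patient_id") |>
    dplyr::left_join(
      fold_of("plasma_NHS_antiC7", c(achr_fold_antiC7 = "achr_fold")),
      by = "patient_id") |>
    dplyr::left_join(
      fold_of("plasma_NHS_isotype", c(achr_fold_isotype = "achr_fold")),
      by = "patient_id") |>
    dplyr::left_join(igg, by = "patient_id") |>
    dplyr::mutate(
      achr_class = classify_achr_fold(.data$achr_fold),
      mac_class = classify_mac_fold(.data$mac_fold),
      igg_class = classify_igg_binding(.data$igg_binding_pct),
      blockade = assess_blockade(.data$achr_fold, .data$achr_fold_antiC7,
                                 .data$achr_fold_isotype),
      category = assign_category(.data$achr_class, .data$blockade,
                                 .data$mac_class, .data$igg_class)
    ) |>
    dplyr::select("patient_id", "igg_binding_pct", "igg_class", "achr_fold",
                  "mac_fold", "achr_class", "mac_class", "blockade",
                  "category")
  out
}
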