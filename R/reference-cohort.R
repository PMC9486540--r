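#' Published reference cohort of 19 anti-AChR positive MG patients
#'
#' Per-patient ordinal readout classes for a published cohort of 19
#' anti-nicotinic-AChR antibody positive Myasthenia Gravis patients tested
#' in the cell-based stratification assay, used for examples and for
#' validating [assign_category()]. Columns: `patient_id`; `achr_class`
#' (AChR-loss class, scale capped at `++`); `blockade` (whether the loss
#' was blocked by an anti-C7 antibody; `NA` where there was no loss to
#' block); `mac_class` (MAC-deposition class); `igg_class` (IgG
#' cell-binding class); `titre_nmol_l` (anti-AChR autoantibody titre,
#' `NA` where below the detection range); `category` (the published
#' category assignment, 1-4).
#'
#' The pooled healthy-donor control plasma (all readouts `-`, no category)
#' is included only when `include_control = TRUE`; it maps to no patient
#' category.
#'
#' @param include_control Append the pooled-control-plasma row
#'   (`category = NA`)? Default `FALSE`.
#' @return A tibble with one row per patient (19 rows, or 20 with the
#'   control).
#' @export
#' @examples
#' ref <- mg_reference_cohort()
#' all(assign_category(ref$achr_class, ref$blockade,
#'                     ref$mac_class, ref$igg_class) == ref$category)
mg_reference_cohort <- function(include_control = FALSE) {
  rows <- tibble::tribble(
    ~patient_id, ~achr_class, ~blockade,     ~mac_class, ~igg_class, ~titre_nmol_l, ~category,
    "MG2",       "++",        "yes",         "+",        "++",       5.43,          1L,
    "MG3",       "++",        "yes",         "++",       "+++",      143.49,        1L,
    "MG14",      "++",        "yes",         "+",        "++",       13.65,         1L,
    "MG15",      "++",        "yes",         "+",        "++",       12.09,         1L,
    "MG16",      "++",        "yes",         "+",        "++",       23.60,         1L,
    "MG17",      "++",        "yes",         "++",       "+++",      67.52,         1L,
    "MSDN04",    "++",        "yes_partial", "+++",      "+++",      130.32,        1L,
    "MSDN09",    "++",        "yes",         "+++",      "+++",      1.78,          1L,
    "MSDN19",    "++",        "yes_partial", "+++",      "+++",      53.84,         1L,
    "MG4",       "+",         "yes",         "-",        "++",       4.80,          2L,
    "MG12",      "+",         "yes",         "-",        "++",       10.13,         2L,
    "MG13",      "+",         "yes",         "-",        "+",        3.80,          2L,
    "MG1",       "-",         NA,            "-",        "++",       18.40,         3L,
    "MG5",       "-",         NA,            "-",        "+",        16.28,         4L,
    "MG8",       "-",         NA,            "-",        "+",        2.18,          4L,
    "MG9",       "-",         NA,            "-",        "+",        3.21,          4L,
    "MG11",      "-",         NA,            "-",        "+",        4.37,          4L,
    "MG18",      "-",         NA,            "-",        "-",        41.89,         4L,
    "MSDN12",    "-",         NA,            "+",        "-",        NA,            4L
  )
  if (include_control) {
    rows <- dplyr::bind_rows(rows, tibble(
      patient_id = "pooled_ctrl_plasma", achr_class = "-",
      blockade = NA_character_, mac_class = "-", igg_class = "-",
      titre_nmol_l = NA_real_, category = NA_integer_
    ))
  }
  rows
}
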