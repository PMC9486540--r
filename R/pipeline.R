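#' Run the full stratification pipeline on a synthetic cohort
#'
#' Chains the stages end to end: simulate imaging fields (or tabular well
#' measurements) for a cohort of archetype patients, quantify each field
#' (segmentation, spot detection, positivity calls with plate-level
#' thresholds set on the NHS-only control well), normalize to per-plate
#' fold changes, classify, assess anti-C7 blockade and assign patient
#' categories. Deterministic for a fixed configuration and seed.
#'
#' Each patient plate carries the five complement-assay arms (NHS only,
#' plasma + NHS, plasma + NHS + anti-C7, plasma + NHS + isotype control,
#' control plasma + NHS; marker channel MAC) plus one binding-assay well
#' (heat-inactivated plasma, marker channel IgG) supplying the
#' immunoglobulin-binding readouts.
#'
#' @param config A list (or path to a JSON file) with elements:
#'   `cohort` — named archetype counts, e.g. `list(cat1 = 2, cat4 = 1)`;
#'   `seed` — integer;
#'   `mode` — `"images"` (default) or `"tabular"` (fast path bypassing
#'   imaging via [simulate_cohort_wells()]);
#'   `n_experiments` — plates per patient (default 1 for images, 3 for
#'   tabular);
#'   `imaging` — optional list of [simulation_config()] overrides;
#'   `noise_pct` — tabular-mode measurement noise (default 2).
#' @param out_dir Optional directory; when given, the per-well table,
#'   per-patient readouts and a JSON cohort summary (carrying the config
#'   hash and seed) are written as CSV/JSON.
#' @return A list with `wells` (per-well measurements), `readouts`
#'   (per-patient tibble from [stratify_cohort()]), `summary`
#'   (from [cohort_summary()]), `config_hash` and `seed`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(list(cohort = list(cat1 = 1, cat4 = 1), seed = 1,
#'                          mode = "tabular"))
#' res$readouts
#' }
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config) || is.null(config$cohort) || is.null(config$seed)) {
    abort("config must provide at least `cohort` (named counts) and `seed`")
  }
  mode <- config$mode %||% "images"
  if (!mode %in% c("images", "tabular")) {
    abort("config$mode must be \"images\" or \"tabular\"")
  }
  cohort <- unlist(config$cohort)
  seed <- as.integer(config$seed)
  cfg_hash <- rlang::hash(config)

  if (mode == "tabular") {
    wells <- simulate_cohort_wells(
      cohort, seed = seed,
      n_experiments = config$n_experiments %||% 3,
      noise_pct = config$noise_pct %||% 2
    )
  } else {
    wells <- simulate_cohort_images(
      cohort, seed = seed,
      n_experiments = config$n_experiments %||% 1,
      imaging = config$imaging %||% list()
    )
  }
  if (nrow(wells) == 0L) abort("empty cohort")

  readouts <- stratify_cohort(wells)
  readouts <- dplyr::left_join(
    readouts,
    dplyr::distinct(wells[, c("patient_id", "phenotype")]),
    by = "patient_id"
  )
  summ <- cohort_summary(readouts)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(df) {
      df$config_hash <- cfg_hash
      df$seed <- seed
      df
    }
    readr::write_csv(stamp(wells), file.path(out_dir, "wells.csv"), na = "")
    readr::write_csv(stamp(readouts), file.path(out_dir, "patient_readouts.csv"),
                     na = "")
    jsonlite::write_json(
      c(summ, list(config_hash = cfg_hash, seed = seed)),
      file.path(out_dir, "cohort_summary.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  list(wells = wells, readouts = readouts, summary = summ,
       config_hash = cfg_hash, seed = seed)
}

## Image-based cohort simulation + quantification: one plate per
## experiment per patient, five complement arms + one binding well.
simulate_cohort_images <- function(cohort, seed, n_experiments = 1,
                                   imaging = list()) {
  if (is.null(names(cohort)) || any(names(cohort) == "")) {
    abort("cohort must be a named vector of archetype counts")
  }
  if (sum(cohort) == 0) {
    return(tibble(patient_id = character(), phenotype = character(),
                  plate_id = character(), arm = character(),
                  pct_achr_pos = numeric(),
                  pct_mac_pos_in_achr_pos = numeric(),
                  pct_ig_pos = numeric(), pct_ig_pos_in_achr_neg = numeric()))
  }
  arms <- c("NHS_only", "plasma_NHS", "plasma_NHS_antiC7",
            "plasma_NHS_isotype", "ctrl_plasma_NHS")
  patients <- purrr::imap(cohort, function(count, label) {
    if (count == 0) return(NULL)
    tibble(phenotype = label,
           patient_id = sprintf("%s_p%02d", label, seq_len(count)))
  }) |> purrr::compact() |> dplyr::bind_rows()

  n_wells_per_plate <- length(arms) + 1L
  n_total <- nrow(patients) * n_experiments * n_wells_per_plate
  well_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_total))
  widx <- 0L

  rows <- list()
  for (p in seq_len(nrow(patients))) {
    ph <- phenotype_params(patients$phenotype[p])
    for (e in seq_len(n_experiments)) {
      plate_id <- sprintf("%s_e%d", patients$patient_id[p], e)
      plate_rows <- list()
      plate_quants <- list()
      for (a in arms) {
        widx <- widx + 1L
        cfg <- do.call(simulation_config,
                       modifyList(imaging, list(seed = well_seeds[widx])))
        sim <- generate_field(cfg, ph, arm = a, marker = "MAC",
                              well_id = paste0(plate_id, "_", a))
        plate_quants[[a]] <- quantify_field(sim$field,
                                            achr_threshold = "otsu",
                                            marker_threshold = "otsu")
        plate_quants[[a]]$field <- sim$field
      }
      ## plate-level thresholds from the NHS-only control well
      thr <- plate_quants[["NHS_only"]]$thresholds
      for (a in arms) {
        q <- plate_quants[[a]]
        rec <- q$records
        rec$achr_pos <- call_positive(rec$achr_sum, unname(thr["achr"]))
        rec$marker_pos <- call_positive(rec$marker_sum, unname(thr["marker"]))
        q$records <- rec
        m <- measure_well(q, q$field)
        m$patient_id <- patients$patient_id[p]
        m$phenotype <- patients$phenotype[p]
        m$plate_id <- plate_id
        plate_rows[[a]] <- m
      }
      ## binding-assay well (heat-inactivated plasma, IgG marker)
      widx <- widx + 1L
      cfg <- do.call(simulation_config,
                     modifyList(imaging, list(seed = well_seeds[widx])))
      simb <- generate_field(cfg, ph, arm = "plasma_NHS", marker = "IgG",
                             well_id = paste0(plate_id, "_binding"))
      qb <- quantify_field(simb$field, achr_threshold = unname(thr["achr"]),
                           marker_threshold = "otsu")
      mb <- measure_well(qb, simb$field)
      mb$patient_id <- patients$patient_id[p]
      mb$phenotype <- patients$phenotype[p]
      mb$plate_id <- plate_id
      ## binding wells contribute only the immunoglobulin readouts
      mb$pct_achr_pos <- NA_real_
      mb$pct_mac_pos_in_achr_pos <- NA_real_
      plate_rows[["binding"]] <- mb
      rows[[plate_id]] <- dplyr::bind_rows(plate_rows)
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::select("patient_id", "phenotype", "plate_id", "well_id", "arm",
                  "n_cells", "pct_achr_pos", "pct_mac_pos_in_achr_pos",
                  "pct_ig_pos", "pct_ig_pos_in_achr_neg",
                  "pct_ig_pos_in_achr_pos")
}
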