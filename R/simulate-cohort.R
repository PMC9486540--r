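#' Generate per-patient well-measurement tables without imaging
#'
#' Tabular fast path of the cohort generator: emits the per-well readouts
#' that the imaging stages would produce, with the statistical structure
#' the stratification stage assumes, so categorization can be tested at
#' scale without rendering or segmenting any field. Each patient is an
#' archetype phenotype (see [phenotype_params()]); each experiment is one
#' plate carrying the five treatment arms, with Gaussian measurement noise
#' on the percentages. Immunoglobulin-binding readouts (a separate assay
#' without complement) are attached to the `plasma_NHS` rows.
#'
#' @param n_per_category Named counts of patients per archetype, e.g.
#'   `c(cat1 = 9, cat2 = 3, cat3 = 1, cat4 = 7)`. Zero counts allowed.
#' @param seed Integer seed; identical inputs give identical tables.
#' @param n_experiments Independent experiments (plates) per patient.
#' @param noise_pct Gaussian noise standard deviation, in percentage
#'   points, applied to every readout (0 for noiseless tables).
#' @param transfection_fraction Fraction of cells expressing AChR; sets
#'   the baseline percent-AChR-positive level.
#' @param mac_baseline_pct Percent MAC-positive cells within the
#'   AChR-positive population under NHS alone.
#' @return A tibble of well measurements: `patient_id`, `phenotype`,
#'   `plate_id`, `arm`, `pct_achr_pos`, `pct_mac_pos_in_achr_pos`,
#'   `pct_ig_pos`, `pct_ig_pos_in_achr_neg`. Empty counts give an empty
#'   tibble.
#' @export
#' @examples
#' wells <- simulate_cohort_wells(c(cat1 = 2, cat2 = 1, cat4 = 2), seed = 7)
#' stratify_cohort(wells)
simulate_cohort_wells <- function(n_per_category, seed,
                                  n_experiments = 3, noise_pct = 2,
                                  transfection_fraction = 0.6,
                                  mac_baseline_pct = 10) {
  if (is.null(names(n_per_category)) || any(names(n_per_category) == "")) {
    abort("n_per_category must be a named vector of archetype counts")
  }
  if (any(n_per_category < 0)) abort("counts must be >= 0")
  cols <- c("patient_id", "phenotype", "plate_id", "arm", "pct_achr_pos",
            "pct_mac_pos_in_achr_pos", "pct_ig_pos", "pct_ig_pos_in_achr_neg")
  if (sum(n_per_category) == 0) {
    return(tibble(patient_id = character(), phenotype = character(),
                  plate_id = character(), arm = character(),
                  pct_achr_pos = numeric(),
                  pct_mac_pos_in_achr_pos = numeric(),
                  pct_ig_pos = numeric(), pct_ig_pos_in_achr_neg = numeric()))
  }

  arms <- c("NHS_only", "plasma_NHS", "plasma_NHS_antiC7",
            "plasma_NHS_isotype", "ctrl_plasma_NHS")
  base_achr <- 100 * transfection_fraction

  patients <- purrr::imap(n_per_category, function(count, label) {
    if (count == 0) return(NULL)
    tibble(phenotype = label,
           patient_id = sprintf("%s_p%02d", label, seq_len(count)))
  }) |> purrr::compact() |> dplyr::bind_rows()

  with_seed(seed, {
    rows <- purrr::pmap(patients, function(phenotype, patient_id) {
      ph <- phenotype_params(phenotype)
      L <- achr_loss_factor(ph$complement_activation)
      M <- mac_fold_factor(ph$complement_activation)
      purrr::map(seq_len(n_experiments), function(exp_i) {
        loss <- c(NHS_only = 1, plasma_NHS = L, plasma_NHS_antiC7 = 1,
                  plasma_NHS_isotype = L, ctrl_plasma_NHS = 1)
        macf <- c(NHS_only = 1, plasma_NHS = M, plasma_NHS_antiC7 = 1,
                  plasma_NHS_isotype = M, ctrl_plasma_NHS = 1)
        achr <- clamp_pct(base_achr * loss[arms] + rnorm(length(arms), 0, noise_pct))
        mac <- clamp_pct(mac_baseline_pct * macf[arms] +
                           rnorm(length(arms), 0, noise_pct))
        ig_all <- clamp_pct(
          100 * (transfection_fraction * ph$igg_binding_strength +
                   ph$nonspecific_binding) + rnorm(1, 0, noise_pct))
        ig_neg <- clamp_pct(100 * ph$nonspecific_binding +
                              rnorm(1, 0, noise_pct))
        tibble(
          patient_id = patient_id,
          phenotype = phenotype,
          plate_id = sprintf("%s_e%d", patient_id, exp_i),
          arm = arms,
          pct_achr_pos = unname(achr),
          pct_mac_pos_in_achr_pos = unname(mac),
          pct_ig_pos = ifelse(arms == "plasma_NHS", ig_all, NA_real_),
          pct_ig_pos_in_achr_neg = ifelse(arms == "plasma_NHS", ig_neg,
                                          NA_real_)
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    rows[, cols]
  })
}

clamp_pct <- function(x) pmin(pmax(x, 0), 100)
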