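#' Background-correct immunoglobulin binding
#'
#' Subtracts the percentage of immunoglobulin-positive cells within the
#' AChR-negative population (non-specific binding) from the overall
#' immunoglobulin-positive percentage, flooring the result at zero. The
#' floor exists because a negative percentage is an artefact of subtraction:
#' the binding classes start at 0%.
#'
#' @param pct_ig_pos Percent Ig-positive cells (0-100). Vectorized.
#' @param pct_ig_pos_in_achr_neg Percent Ig-positive cells within the
#'   AChR-negative population (0-100). Vectorized, recycled against
#'   `pct_ig_pos`.
#' @return Corrected percentage in \[0, 100\]; `NA` propagates.
#' @export
#' @examples
#' background_correct_ig(70, 5)   # 65
#' background_correct_ig(5, 12)   # floored at 0
background_correct_ig <- function(pct_ig_pos, pct_ig_pos_in_achr_neg) {
  check_pct(pct_ig_pos, "pct_ig_pos")
  check_pct(pct_ig_pos_in_achr_neg, "pct_ig_pos_in_achr_neg")
  pmax(pct_ig_pos - pct_ig_pos_in_achr_neg, 0)
}

check_pct <- function(x, name) {
  bad <- is.finite(x) & (x < 0 | x > 100)
  if (any(bad)) abort(paste0(name, " must lie in [0, 100]"))
  invisible(x)
}

#' Fold change relative to the NHS-only control
#'
#' Per-plate normalization: each treatment readout is divided by the
#' NHS-only (complement source alone) readout from the same plate.
#'
#' @param treatment_value Readout under the treatment arm (vectorized).
#' @param nhs_value NHS-only readout for the same plate; must be > 0
#'   (a non-positive control readout means the plate control failed).
#' @return Non-negative ratio.
#' @export
fold_change <- function(treatment_value, nhs_value) {
  if (any(is.finite(nhs_value) & nhs_value <= 0)) {
    abort("NHS-only control readout must be > 0 (plate control failure)")
  }
  treatment_value / nhs_value
}

#' Ordinal classification of fold-change and binding readouts
#'
#' Maps readouts onto the ordinal `-`/`+`/`++`/`+++` scales using fixed
#' numeric bands. For the AChR-loss readout (fold change of % AChR-positive
#' cells relative to NHS alone) the bands are 1-0.8 (`-`), 0.8-0.6 (`+`),
#' 0.6-0.3 (`++`); the scale is capped at `++` and values below 0.3 saturate
#' there, while fold changes above 1 (no loss) map to `-`. For the MAC
#' readout the bands are 1-1.3 (`-`), 1.3-1.8 (`+`), 1.8-2.3 (`++`),
#' 2.3-3.5 (`+++`), saturating at `+++` above 3.5 and at `-` below 1. For
#' background-corrected IgG binding the bands are 0-15% (`-`), 15-40% (`+`),
#' 40-65% (`++`), 65-100% (`+++`).
#'
#' Shared band endpoints are resolved half-open with the boundary belonging
#' to the milder class for fold changes (0.8 -> `-`, 1.3 -> `-`) and to the
#' stronger class for percentages (15 -> `+`, 40 -> `++`, 65 -> `+++`).
#'
#' @param fc Fold change relative to the NHS-only control; must be > 0.
#' @param pct Background-corrected percentage in \[0, 100\].
#' @return Character vector of class symbols (use [ordinal_class()] for an
#'   ordered factor). `NA` propagates.
#' @export
#' @examples
#' classify_achr_fold(c(0.9, 0.7, 0.45))  # "-", "+", "++"
#' classify_mac_fold(c(1.1, 2.0, 3.0))    # "-", "++", "+++"
#' classify_igg_binding(c(10, 50, 70))    # "-", "++", "+++"
classify_achr_fold <- function(fc) {
  if (any(is.finite(fc) & fc <= 0)) abort("AChR fold change must be > 0")
  out <- rep(NA_character_, length(fc))
  ok <- is.finite(fc)
  out[ok & fc >= 0.8] <- "-"           # includes fc > 1: no loss
  out[ok & fc >= 0.6 & fc < 0.8] <- "+"
  out[ok & fc < 0.6] <- "++"           # scale max; < 0.3 saturates here
  out
}

#' @rdname classify_achr_fold
#' @export
classify_mac_fold <- function(fc) {
  if (any(is.finite(fc) & fc <= 0)) abort("MAC fold change must be > 0")
  out <- rep(NA_character_, length(fc))
  ok <- is.finite(fc)
  out[ok & fc <= 1.3] <- "-"           # includes fc < 1: no deposition
  out[ok & fc > 1.3 & fc <= 1.8] <- "+"
  out[ok & fc > 1.8 & fc <= 2.3] <- "++"
  out[ok & fc > 2.3] <- "+++"          # > 3.5 saturates at scale max
  out
}

#' @rdname classify_achr_fold
#' @export
classify_igg_binding <- function(pct) {
  check_pct(pct, "corrected IgG binding percentage")
  out <- rep(NA_character_, length(pct))
  ok <- is.finite(pct)
  out[ok & pct < 15] <- "-"
  out[ok & pct >= 15 & pct < 40] <- "+"
  out[ok & pct >= 40 & pct < 65] <- "++"
  out[ok & pct >= 65] <- "+++"
  out
}

#' Assess anti-C7 blockade of AChR loss
#'
#' Determines whether the AChR loss caused by a patient's plasma is blocked
#' by a C7-inhibiting antibody. The question is undefined (`NA`) when the
#' plasma arm shows no loss (`-` class). Blockade is `"yes"` when the
#' anti-C7 arm reverts to the `-` class while the isotype-control arm
#' retains the plasma arm's class; `"yes_partial"` when the anti-C7 arm
#' improves by at least one class step but does not reach `-`; `"no"`
#' otherwise.
#'
#' @param achr_fold_plasma,achr_fold_antiC7,achr_fold_isotype AChR fold
#'   changes for the plasma + NHS, plasma + NHS + anti-C7 and plasma + NHS +
#'   isotype-control arms of the same plate. Vectorized.
#' @return Character vector in `{"yes", "yes_partial", "no", NA}`.
#' @export
assess_blockade <- function(achr_fold_plasma, achr_fold_antiC7,
                            achr_fold_isotype) {
  n <- max(length(achr_fold_plasma), length(achr_fold_antiC7),
           length(achr_fold_isotype))
  plasma <- rep_len(achr_fold_plasma, n)
  antic7 <- rep_len(achr_fold_antiC7, n)
  iso <- rep_len(achr_fold_isotype, n)

  cls_plasma <- classify_achr_fold(plasma)
  out <- rep(NA_character_, n)
  active <- !is.na(cls_plasma) & cls_plasma != "-"
  if (!any(active)) return(out)

  if (any(active & (is.na(antic7) | is.na(iso)))) {
    warn("missing anti-C7 or isotype arm; blockade reported as NA")
  }
  idx <- which(active & !is.na(antic7) & !is.na(iso))
  if (length(idx)) {
    cls_c7 <- classify_achr_fold(antic7[idx])
    cls_iso <- classify_achr_fold(iso[idx])
    r_plasma <- class_rank(cls_plasma[idx])
    r_c7 <- class_rank(cls_c7)
    full <- cls_c7 == "-" & cls_iso == cls_plasma[idx]
    partial <- !full & r_c7 <= r_plasma - 1L
    out[idx] <- dplyr::case_when(full ~ "yes", partial ~ "yes_partial",
                                 TRUE ~ "no")
  }
  out
}

#' Assign a patient category from ordinal readout classes
#'
#' Four-way categorization of anti-AChR antibody positive patients by how
#' their immunoglobulins act on AChR-expressing cells:
#' category 1 — high (`++`) complement-dependent AChR loss;
#' category 2 — low (`+`) AChR loss;
#' category 3 — no detectable AChR loss but moderate-or-stronger (`>= ++`)
#' IgG cell binding (binding without complement effect);
#' category 4 — no AChR loss and no or low IgG binding.
#' The function is total over defined class combinations; `mac_class` and
#' `blockade` are carried for reporting but do not alter the assignment
#' (categories 1 and 2 are, by construction of the cohort, the
#' anti-C7-blockable ones).
#'
#' @param achr_class AChR-loss class symbol (`-`, `+`, `++`). Vectorized.
#' @param blockade Blockade status from [assess_blockade()] (optional,
#'   `NA` allowed).
#' @param mac_class MAC-deposition class symbol (optional).
#' @param igg_class IgG-binding class symbol.
#' @return Integer vector of categories 1-4.
#' @export
#' @examples
#' assign_category("++", "yes", "++", "+++")  # 1
#' assign_category("-", NA, "-", "++")        # 3
#' assign_category("-", NA, "+", "-")         # 4
assign_category <- function(achr_class, blockade = NA, mac_class = NA,
                            igg_class) {
  n <- max(length(achr_class), length(igg_class))
  achr <- ordinal_class(rep_len(as.character(achr_class), n))
  igg <- ordinal_class(rep_len(as.character(igg_class), n))
  dplyr::case_when(
    achr == "++" | achr == "+++" ~ 1L,
    achr == "+" ~ 2L,
    igg >= "++" ~ 3L,
    TRUE ~ 4L
  )
}

#' Summarize a categorized cohort
#'
#' Counts patients per category and reports the complement-dependent
#' fraction: patients in categories 1 and 2 (those with clear
#' C7-dependent AChR loss) over the whole cohort. The percentage is
#' rounded to the nearest integer.
#'
#' @param readouts Data frame with a `category` column (integers 1-4), one
#'   row per patient.
#' @return A list with `n_patients`, `counts` (named integer vector over
#'   categories 1-4), `n_complement_dependent` and
#'   `pct_complement_dependent`.
#' @export
cohort_summary <- function(readouts) {
  stopifnot(is.data.frame(readouts), "category" %in% names(readouts))
  cat <- readouts$category
  if (length(cat) == 0L) abort("empty cohort")
  if (any(!cat %in% 1:4)) abort("categories must be integers 1-4")
  counts <- table(factor(cat, levels = 1:4))
  counts <- setNames(as.integer(counts), paste0("category_", 1:4))
  n <- length(cat)
  n12 <- counts[["category_1"]] + counts[["category_2"]]
  list(
    n_patients = n,
    counts = counts,
    n_complement_dependent = n12,
    pct_complement_dependent = round(100 * n12 / n)
  )
}

#' Spearman rank correlation with confidence interval
#'
#' Two-tailed, non-parametric Spearman correlation with a 95% confidence
#' interval obtained by the Fisher z-transform of the rank correlation with
#' the Fieller-Hartley-Pearson standard error `sqrt(1.06 / (n - 3))`.
#' Pairs with a missing member are dropped.
#'
#' @param x,y Paired numeric vectors (n >= 4 complete pairs).
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble with `rho`, `p_value`, `conf_low`, `conf_high`, `n`.
#'   A constant vector yields `NA` rho with a warning.
#' @export
spearman_correlation <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) abort("need at least 4 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warn("constant input: Spearman rho undefined")
    return(tibble(rho = NA_real_, p_value = NA_real_,
                  conf_low = NA_real_, conf_high = NA_real_, n = n))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  alternative = "two.sided"))
  rho <- unname(ct$estimate)
  z <- atanh(rho)
  se <- sqrt(1.06 / (n - 3))
  q <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    rho = rho,
    p_value = unname(ct$p.value),
    conf_low = tanh(z - q * se),
    conf_high = tanh(z + q * se),
    n = n
  )
}
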