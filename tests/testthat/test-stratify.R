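test_that("background correction subtracts the AChR-negative Ig signal and floors at zero", {
  expect_equal(background_correct_ig(70, 5), 65)
  expect_equal(background_correct_ig(10, 10), 0)
  expect_equal(background_correct_ig(5, 12), 0)
  expect_equal(background_correct_ig(c(70, NA), c(5, 5)), c(65, NA))
  expect_error(background_correct_ig(120, 5), "0, 100")
})

test_that("fold change divides by the plate's NHS control and rejects failed controls", {
  expect_equal(fold_change(5, 5), 1)
  expect_equal(fold_change(30, 60), 0.5)
  expect_equal(fold_change(0, 60), 0)
  expect_error(fold_change(10, 0), "control")
  expect_error(fold_change(10, -1), "control")
})

test_that("AChR-loss classes follow the printed bands with saturation at the scale cap", {
  expect_equal(classify_achr_fold(c(0.9, 0.7, 0.45)), c("-", "+", "++"))
  # boundary values belong to the milder class
  expect_equal(classify_achr_fold(c(1, 0.8, 0.6)), c("-", "-", "+"))
  # out-of-band saturation: no loss above 1, scale max below 0.3
  expect_equal(classify_achr_fold(c(1.4, 0.2, 0.05)), c("-", "++", "++"))
  expect_error(classify_achr_fold(0), "> 0")
  expect_equal(classify_achr_fold(NA_real_), NA_character_)
})

test_that("MAC-deposition classes follow the printed bands", {
  expect_equal(classify_mac_fold(c(1.1, 2.0, 3.0)), c("-", "++", "+++"))
  expect_equal(classify_mac_fold(c(1, 1.3, 1.8, 2.3)), c("-", "-", "+", "++"))
  expect_equal(classify_mac_fold(c(0.4, 5.0)), c("-", "+++"))
  expect_error(classify_mac_fold(-1), "> 0")
})

test_that("IgG-binding classes follow the printed percentage bands", {
  expect_equal(classify_igg_binding(c(10, 50, 70)), c("-", "++", "+++"))
  # lower bound inclusive for percentage bands
  expect_equal(classify_igg_binding(c(0, 15, 40, 65, 100)),
               c("-", "+", "++", "+++", "+++"))
  expect_error(classify_igg_binding(101), "0, 100")
})

test_that("all three classifiers are total, deterministic and monotone; fold change 1 is always '-'", {
  expect_equal(classify_achr_fold(1), "-")
  expect_equal(classify_mac_fold(1), "-")
  set.seed(42)
  fc <- sort(runif(200, 0.01, 4))
  pct <- sort(runif(200, 0, 100))
  # stronger loss (smaller fold) never gives a milder class
  expect_true(all(diff(class_rank(classify_achr_fold(fc))) <= 0))
  expect_true(all(diff(class_rank(classify_mac_fold(fc))) >= 0))
  expect_true(all(diff(class_rank(classify_igg_binding(pct))) >= 0))
  expect_identical(classify_achr_fold(fc), classify_achr_fold(fc))
})

test_that("anti-C7 blockade status distinguishes full, partial and absent block", {
  # full block: anti-C7 arm reverts to '-', isotype retains the plasma class
  expect_equal(assess_blockade(0.5, 0.95, 0.5), "yes")
  # no loss in the plasma arm: question undefined
  expect_equal(assess_blockade(0.9, 0.95, 0.9), NA_character_)
  # one-class improvement without reaching '-'
  expect_equal(assess_blockade(0.45, 0.7, 0.45), "yes_partial")
  # no improvement
  expect_equal(assess_blockade(0.45, 0.5, 0.45), "no")
  expect_warning(out <- assess_blockade(0.5, NA, 0.5), "missing")
  expect_equal(out, NA_character_)
})

test_that("category assignment follows AChR loss first, then IgG binding", {
  expect_equal(assign_category("++", "yes", "++", "+++"), 1L)
  expect_equal(assign_category("+", "yes", "-", "++"), 2L)
  expect_equal(assign_category("-", NA, "-", "++"), 3L)
  expect_equal(assign_category("-", NA, "+", "-"), 4L)
  # total over every class combination
  grid <- expand.grid(achr = c("-", "+", "++"),
                      igg = c("-", "+", "++", "+++"),
                      stringsAsFactors = FALSE)
  out <- assign_category(grid$achr, NA, NA, grid$igg)
  expect_true(all(out %in% 1:4))
})

test_that("cohort summary counts categories and the complement-dependent fraction", {
  s <- cohort_summary(tibble::tibble(category = c(1, 1, 2, 3, 4)))
  expect_equal(unname(s$counts), c(2L, 1L, 1L, 1L))
  expect_equal(s$n_complement_dependent, 3L)
  expect_equal(s$pct_complement_dependent, 60)
  s4 <- cohort_summary(tibble::tibble(category = 4L))
  expect_equal(s4$pct_complement_dependent, 0)
  expect_error(cohort_summary(tibble::tibble(category = integer())), "empty")
})

test_that("Spearman correlation matches a brute-force rank-then-Pearson oracle", {
  expect_equal(spearman_correlation(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_correlation(1:10, -(1:10))$rho, -1)
  set.seed(99)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    expect_equal(spearman_correlation(x, y)$rho, spearman_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(spearman_correlation(1:3, 3:1), "at least 4")
  expect_warning(out <- spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out$rho))
  # CI brackets the estimate
  ci <- spearman_correlation(c(1, 3, 2, 5, 4, 6, 8, 7), 1:8)
  expect_true(ci$conf_low < ci$rho && ci$rho < ci$conf_high)
})

test_that("stratify_cohort averages experiments before classification and demands NHS controls", {
  wells <- simulate_cohort_wells(c(cat1 = 1, cat3 = 1), seed = 5,
                                 noise_pct = 0)
  r <- stratify_cohort(wells)
  expect_equal(nrow(r), 2L)
  r1 <- r[r$patient_id == "cat1_p01", ]
  expect_equal(r1$achr_fold, 0.45, tolerance = 1e-10)
  expect_equal(r1$achr_class, "++")
  expect_equal(r1$blockade, "yes")
  expect_equal(r1$category, 1L)
  r3 <- r[r$patient_id == "cat3_p01", ]
  expect_equal(r3$category, 3L)
  # removing the NHS wells breaks the normalization
  expect_error(stratify_cohort(wells[wells$arm != "NHS_only", ]), "NHS_only")
  expect_error(stratify_cohort(wells[, -4]), "missing column")
})
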