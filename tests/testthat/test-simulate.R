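test_that("identical config and seed give bitwise-identical fields and truth", {
  cfg <- noisy_config(seed = 11)
  ph <- phenotype_params("cat1")
  a <- generate_field(cfg, ph, arm = "plasma_NHS")
  b <- generate_field(cfg, ph, arm = "plasma_NHS")
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth, b$truth)
  d <- generate_field(noisy_config(seed = 12), ph, arm = "plasma_NHS")
  expect_false(identical(a$field$channels, d$field$channels))
})

test_that("ground-truth spot sums equal the integral of the noiseless spot layer", {
  cfg <- small_config(seed = 7)
  sim <- generate_field(cfg, phenotype_params("cat2"), arm = "plasma_NHS")
  layer_integral <- sum(sim$field$channels$achr) -
    cfg$background * cfg$image_size^2
  expect_equal(sum(sim$truth$true_achr_spot_sum), layer_integral,
               tolerance = 1e-6)
})

test_that("untransfected monolayers carry no AChR signal", {
  cfg <- small_config(seed = 2, transfection_fraction = 0)
  sim <- generate_field(cfg, phenotype_params("cat1"), arm = "plasma_NHS")
  expect_true(all(!sim$truth$transfected))
  expect_true(all(sim$truth$true_achr_spot_sum == 0))
  q <- quantify_field(sim$field)
  expect_equal(percent_positive(q$records$achr_pos), 0)
})

test_that("complement arms attenuate AChR and deposit MAC; anti-C7 reverts to baseline", {
  ph <- phenotype_params("cat1")
  cfg <- small_config(seed = 4)
  nhs <- generate_field(cfg, ph, arm = "NHS_only")
  plasma <- generate_field(cfg, ph, arm = "plasma_NHS")
  antic7 <- generate_field(cfg, ph, arm = "plasma_NHS_antiC7")
  iso <- generate_field(cfg, ph, arm = "plasma_NHS_isotype")
  tr <- function(s) s$truth$true_achr_spot_sum[s$truth$transfected]
  expect_lt(mean(tr(plasma)), mean(tr(nhs)))
  # anti-C7 and isotype arms bracket the effect at the same seed
  expect_identical(tr(antic7), tr(nhs))
  expect_identical(tr(iso), tr(plasma))
  expect_gt(mean(plasma$truth$true_mac_spot_sum),
            mean(nhs$truth$true_mac_spot_sum))
  expect_identical(antic7$truth$true_mac_spot_sum,
                   nhs$truth$true_mac_spot_sum)
  expect_error(generate_field(cfg, ph, arm = "mystery_arm"), "unknown")
})

test_that("complement activation is monotone: AChR never gains, MAC never loses", {
  cfg <- small_config(seed = 9)
  achr_means <- c(); mac_means <- c()
  for (ca in c(0, 0.25, 0.5, 0.75, 1)) {
    ph <- phenotype_params("custom", igg_binding_strength = 0.5,
                          complement_activation = ca)
    sim <- generate_field(cfg, ph, arm = "plasma_NHS")
    achr_means <- c(achr_means, mean(sim$truth$true_achr_spot_sum))
    mac_means <- c(mac_means, mean(sim$truth$true_mac_spot_sum))
  }
  expect_true(all(diff(achr_means) <= 0))
  expect_true(all(diff(mac_means) >= 0))
})

test_that("phenotype and configuration validation rejects out-of-range values", {
  expect_error(phenotype_params("x", igg_binding_strength = 1.5,
                                complement_activation = 0), "0, 1")
  expect_error(phenotype_params("x", igg_binding_strength = NaN,
                                complement_activation = 0.5), "finite")
  expect_error(simulation_config(transfection_fraction = 2), "0, 1")
  expect_error(simulation_config(n_cells = 1e6), "too large")
})

test_that("cohort tables are deterministic, respect empty requests, and recover their categories", {
  a <- simulate_cohort_wells(c(cat1 = 2, cat4 = 1), seed = 3)
  b <- simulate_cohort_wells(c(cat1 = 2, cat4 = 1), seed = 3)
  expect_identical(a, b)
  expect_equal(nrow(simulate_cohort_wells(c(cat1 = 0, cat2 = 0), seed = 1)), 0L)
  expect_error(simulate_cohort_wells(c(3, 2), seed = 1), "named")

  # archetype round trip at default noise: >= 18 of 20 recovered
  wells <- simulate_cohort_wells(c(cat1 = 9, cat2 = 3, cat3 = 1, cat4 = 7),
                                 seed = 7)
  r <- stratify_cohort(wells)
  expected <- as.integer(sub("cat(\\d)_.*", "\\1", r$patient_id))
  expect_gte(sum(r$category == expected), 18)
  # and perfectly when noiseless
  wells0 <- simulate_cohort_wells(c(cat1 = 9, cat2 = 3, cat3 = 1, cat4 = 7),
                                  seed = 7, noise_pct = 0)
  r0 <- stratify_cohort(wells0)
  expected0 <- as.integer(sub("cat(\\d)_.*", "\\1", r0$patient_id))
  expect_equal(sum(r0$category == expected0), 20)
})

test_that("archetype cohort tables land inside the published class bands", {
  wells <- simulate_cohort_wells(c(cat1 = 3, cat4 = 3), seed = 21,
                                 noise_pct = 0)
  r <- stratify_cohort(wells)
  cat1 <- r[grepl("^cat1", r$patient_id), ]
  expect_true(all(cat1$achr_fold > 0.3 & cat1$achr_fold <= 0.6))
  expect_true(all(cat1$mac_fold > 1.3))
  expect_true(all(cat1$igg_binding_pct > 40))
  cat4 <- r[grepl("^cat4", r$patient_id), ]
  expect_true(all(abs(cat4$achr_fold - 1) < 0.05))
  expect_true(all(cat4$igg_binding_pct < 15))
})
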