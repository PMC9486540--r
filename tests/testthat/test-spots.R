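test_that("per-cell spot counts are recovered on noiseless fields", {
  cfg <- small_config(seed = 19)
  sim <- generate_field(cfg, phenotype_params("cat4"), arm = "NHS_only")
  nuc <- detect_nuclei(sim$field)
  cells <- segment_cells(sim$field, nuc)
  sp <- detect_spots(sim$field, cells, "achr")
  gt <- match_truth(sim$truth, cells)
  sc <- attr(sim$truth, "spot_centers")
  true_counts <- tabulate(sc$cell_id, nbins = nrow(sim$truth))[gt]
  det_counts <- tabulate(factor(sp$cell_id, levels = seq_along(gt)),
                         nbins = length(gt))
  expect_gte(mean(det_counts == true_counts), 0.95)
})

test_that("diffuse (no Rapsyn) AChR signal produces no spots", {
  cfg <- small_config(seed = 19, rapsyn = FALSE)
  sim <- generate_field(cfg, phenotype_params("cat4"), arm = "NHS_only")
  expect_gt(max(sim$field$channels$achr) - cfg$background, 5) # signal present
  cells <- segment_cells(sim$field, detect_nuclei(sim$field))
  sp <- detect_spots(sim$field, cells, "achr")
  expect_equal(nrow(sp), 0L)
})

test_that("a blank channel yields an empty spot table", {
  cfg <- small_config(seed = 19)
  sim <- generate_field(cfg, phenotype_params("cat4"), arm = "NHS_only")
  cells <- segment_cells(sim$field, detect_nuclei(sim$field))
  sp <- detect_spots(matrix(0, cfg$image_size, cfg$image_size), cells)
  expect_equal(nrow(sp), 0L)
})

test_that("per-cell sums add each cell's spots and conserve the table total", {
  cells <- structure(list(
    nuclei_labels = matrix(c(1L, 0L, 0L, 2L), 2),
    cell_labels = matrix(c(1L, 1L, 2L, 2L), 2),
    n_cells = 2L), class = "cell_label_map")
  spots <- tibble::tibble(spot_id = 1:3, cell_id = c(1L, 1L, 1L),
                          channel = "achr", centroid_row = 1,
                          centroid_col = 1, area = 4L,
                          intensity = c(10, 20, 5))
  sums <- per_cell_spot_sum(spots, cells)
  expect_equal(sums$spot_sum, c(35, 0))          # spotless cell gets 0
  expect_equal(sum(sums$spot_sum), sum(spots$intensity))
})

test_that("recovered spot sums rank-correlate with ground truth on noiseless fields", {
  cfg <- small_config(seed = 29)
  sim <- generate_field(cfg, phenotype_params("cat4"), arm = "NHS_only")
  cells <- segment_cells(sim$field, detect_nuclei(sim$field))
  sp <- detect_spots(sim$field, cells, "achr")
  sums <- per_cell_spot_sum(sp, cells)
  gt <- match_truth(sim$truth, cells)
  rho <- suppressWarnings(
    cor(sums$spot_sum, sim$truth$true_achr_spot_sum[gt], method = "spearman"))
  expect_gte(rho, 0.99)
})

test_that("positivity calls threshold the sums; fixed and automatic rules", {
  expect_equal(call_positive(c(0, 10, 100), threshold = 50),
               c(FALSE, FALSE, TRUE))
  # threshold 0: every cell with any spot signal is positive
  expect_equal(call_positive(c(0, 1, 30), threshold = 0),
               c(FALSE, TRUE, TRUE))
  # automatic split separates a bimodal population
  sums <- c(rep(0, 50), rlnorm(50, log(5000), 0.3))
  calls <- call_positive(sums)
  expect_equal(calls, sums > 0)
  # degenerate all-zero reference: nothing called positive
  expect_equal(call_positive(rep(0, 10)), rep(FALSE, 10))
  expect_error(call_positive(1:3, threshold = "magic"), "threshold")
})

test_that("percent positive and the MAC-within-AChR+ readout follow their definitions", {
  expect_equal(percent_positive(c(rep(TRUE, 30), rep(FALSE, 90))), 25)
  expect_equal(percent_positive(rep(FALSE, 7)), 0)
  expect_equal(percent_positive(rep(TRUE, 7)), 100)
  expect_warning(out <- percent_positive(logical(0)), "no cells")
  expect_true(is.na(out))

  rec <- tibble::tibble(achr_pos = c(rep(TRUE, 10), rep(FALSE, 5)),
                        mac_pos = c(rep(TRUE, 5), rep(FALSE, 10)))
  expect_equal(mac_within_achr_pos(rec), 50)
  rec$mac_pos <- FALSE
  expect_equal(mac_within_achr_pos(rec), 0)
  rec$mac_pos <- rec$achr_pos
  expect_equal(mac_within_achr_pos(rec), 100)
  expect_warning(out <- mac_within_achr_pos(
    tibble::tibble(achr_pos = rep(FALSE, 3), mac_pos = rep(FALSE, 3))),
    "AChR-positive")
  expect_true(is.na(out))
})

test_that("double positives never exceed either single-positive population", {
  cfg <- noisy_config(seed = 31)
  sim <- generate_field(cfg, phenotype_params("cat1"), arm = "plasma_NHS")
  q <- quantify_field(sim$field)
  n_double <- sum(q$records$achr_pos & q$records$marker_pos)
  expect_lte(n_double, sum(q$records$achr_pos))
  expect_lte(n_double, sum(q$records$marker_pos))
  # percent positive is order-invariant and monotone in the threshold
  sums <- q$records$achr_sum
  expect_equal(percent_positive(call_positive(sums, 100)),
               percent_positive(call_positive(rev(sums), 100)))
  thr <- sort(runif(10, 0, max(sums)), decreasing = TRUE)
  pcts <- vapply(thr, function(t) percent_positive(call_positive(sums, t)),
                 numeric(1))
  expect_true(all(diff(pcts) >= 0))
})
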