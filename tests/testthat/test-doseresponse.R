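test_that("percent hemolysis maps absorbances linearly between the lysis controls", {
  expect_equal(percent_hemolysis(0.5, 0.1, 0.9), 50)
  expect_equal(percent_hemolysis(0.1, 0.1, 0.9), 0)
  expect_equal(percent_hemolysis(0.9, 0.1, 0.9), 100)
  # affine invariance: a shared absorbance offset changes nothing
  expect_equal(percent_hemolysis(0.5 + 0.3, 0.1 + 0.3, 0.9 + 0.3), 50)
  expect_error(percent_hemolysis(0.5, 0.9, 0.1), "degenerate")
  flagged <- percent_hemolysis(c(0.05, 0.95), 0.1, 0.9,
                               flag_out_of_range = TRUE)
  expect_equal(attr(flagged, "out_of_range"), c(TRUE, TRUE))
})

test_that("4PL recovery is exact on noiseless curves and unbiased under noise", {
  x <- 2e-9 * 3^seq(-5, 6)  # 12-point 1:3 dilution series around 2 nM
  y <- curve_4pl(x, bottom = 0, top = 100, x_half = 2e-9, hill = 1)
  fit <- fit_4pl(x, y)
  expect_equal(unname(coef(fit)["x_half"]), 2e-9, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["hill"]), 1, tolerance = 1e-5)
  # objective at the fit is no worse than at the generating parameters
  expect_lte(fit$rss, sum((y - curve_4pl(x, 0, 100, 2e-9, 1))^2) + 1e-8)

  # mean recovered inflection over 100 noisy replicates within 10%
  est <- vapply(1:100, function(s) {
    set.seed(s)
    unname(coef(fit_4pl(x, y + rnorm(length(y), 0, 5)))["x_half"])
  }, numeric(1))
  expect_lt(abs(mean(est) - 2e-9) / 2e-9, 0.10)
})

test_that("rescaling the dose axis rescales only the inflection", {
  x <- 2 * 3^seq(-4, 5)
  y <- curve_4pl(x, 5, 95, 2, 1.3)
  f1 <- fit_4pl(x, y)
  f2 <- fit_4pl(x * 1000, y)
  expect_equal(unname(coef(f2)["x_half"]) / unname(coef(f1)["x_half"]),
               1000, tolerance = 1e-6)
  expect_equal(coef(f1)[c("bottom", "top", "hill")],
               coef(f2)[c("bottom", "top", "hill")], tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with informative errors", {
  x <- 2^(1:8)
  expect_error(fit_4pl(x, rep(50, 8)), "constant")
  expect_error(fit_4pl(c(-1, x[-1]), seq(0, 70, 10)), "positive")
  expect_error(fit_4pl(x[1:3], (1:3) * 10), "5 distinct")
})

test_that("weighted fits and a fixed top asymptote are supported", {
  x <- 10^seq(-2, 3, length.out = 10)
  y <- curve_4pl(x, 2, 98, 5, -1.1)
  fw <- fit_4pl(x, y, weighting = "inv_y2")
  expect_equal(unname(coef(fw)["x_half"]), 5, tolerance = 1e-4)
  ft <- fit_4pl(x, curve_4pl(x, 0, 100, 5, 1), fix_top = 100)
  expect_equal(unname(coef(ft)["top"]), 100)
  expect_equal(unname(coef(ft)["x_half"]), 5, tolerance = 1e-6)
})

test_that("back-interpolation inverts the curve and applies dilution factors", {
  x <- 10^seq(-2, 2, length.out = 9)
  y <- curve_4pl(x, 0, 100, 2, 1)
  fit <- fit_4pl(x, y)
  mid <- predict(fit, newdata = list(x = 2))
  out <- interpolate_concentration(fit, mid)
  expect_equal(out$concentration, 2, tolerance = 1e-6)
  out26 <- interpolate_concentration(fit, mid, dilution_factor = 26)
  expect_equal(out26$concentration, 26 * 2, tolerance = 1e-6)

  # forward-then-inverse round-trips inside the asymptote range
  probe <- c(0.05, 0.4, 2, 13, 80)
  yy <- predict(fit, newdata = list(x = probe))
  back <- interpolate_concentration(fit, yy)
  expect_equal(back$concentration, probe, tolerance = 1e-9)

  # out-of-range responses are flagged, not extrapolated
  oob <- interpolate_concentration(fit, c(-5, 105))
  expect_true(all(is.na(oob$concentration)))
  # falling curve (hill > 0): response below bottom means beyond the top dose
  expect_equal(oob$flag, c("above_detection", "below_detection"))
  expect_error(interpolate_concentration(fit, 50, dilution_factor = 0.5),
               ">= 1")
})

test_that("tidy, glance and autoplot expose the fit", {
  x <- 10^seq(-2, 2, length.out = 9)
  fit <- fit_4pl(x, curve_4pl(x, 0, 100, 2, 1))
  td <- tidy(fit)
  expect_equal(td$term, c("bottom", "top", "x_half", "hill"))
  gl <- glance(fit)
  expect_equal(gl$n, 9L)
  expect_lt(gl$rss, 1e-10)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
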