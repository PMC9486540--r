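#' Percent hemolysis from plate absorbances
#'
#' `100 * (A_test - A_0) / (A_100 - A_0)` at 405 nm, where `A_0` and
#' `A_100` are the 0% (buffer only) and 100% (water) lysis controls. The
#' value is not clipped: noisy wells may fall slightly outside
#' \[0, 100\]; set `flag_out_of_range = TRUE` to attach a logical
#' attribute marking such wells.
#'
#' @param a_test Test-well absorbance(s).
#' @param a_0pct,a_100pct 0% / 100% lysis control absorbances;
#'   `a_100pct` must exceed `a_0pct`.
#' @param flag_out_of_range Attach an `out_of_range` attribute?
#' @return Percent hemolysis (vectorized over `a_test`).
#' @export
#' @examples
#' percent_hemolysis(0.5, 0.1, 0.9)  # 50
percent_hemolysis <- function(a_test, a_0pct, a_100pct,
                              flag_out_of_range = FALSE) {
  if (!all(is.finite(c(a_0pct, a_100pct))) || a_100pct <= a_0pct) {
    abort("degenerate lysis controls: need a_100pct > a_0pct")
  }
  out <- 100 * (a_test - a_0pct) / (a_100pct - a_0pct)
  if (flag_out_of_range) {
    attr(out, "out_of_range") <- out < 0 | out > 100
  }
  out
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + (x/x_half)^hill)`
#' by Levenberg-Marquardt nonlinear least squares, optionally weighted by
#' `1/y^2` (the weighting commonly used for immunoassay standard curves).
#' `x_half` is the inflection concentration, reported as EC50 or IC50
#' depending on assay direction; `hill` is the slope (negative for rising
#' curves under this parameterization, positive for falling ones).
#' Initial values: `bottom = min(y)`, `top = max(y)`, `x_half` the
#' geometric median of `x`, `hill = +/-1` by response direction.
#'
#' @param x Concentrations or dilutions; strictly positive, at least 5
#'   distinct values spanning the transition.
#' @param y Responses (percent lysis, OD, ECL signal, ...).
#' @param weighting `"none"` or `"inv_y2"` (weights `1/y^2`).
#' @param fix_top Optionally fix the upper asymptote (e.g. 100 for
#'   hemolysis curves reaching complete lysis); `NULL` to fit it.
#' @return An object of class `fit_4pl` with elements `coefficients`
#'   (`bottom`, `top`, `x_half`, `hill`), `rss`, `fitted`, `residuals`,
#'   `data`, `weighting`, `convergence`. Supports [tidy()], [glance()],
#'   [predict()][stats::predict] and [autoplot()][ggplot2::autoplot].
#' @export
#' @examples
#' x <- 10^seq(-2, 2, length.out = 9)
#' y <- 100 / (1 + (x / 2)^-1)
#' fit <- fit_4pl(x, y)
#' coef(fit)["x_half"]
fit_4pl <- function(x, y, weighting = c("none", "inv_y2"), fix_top = NULL) {
  weighting <- match.arg(weighting)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (any(x <= 0)) abort("x must be strictly positive (log-scale dose)")
  if (length(unique(x)) < 5) abort("need at least 5 distinct dose points")
  if (diff(range(y)) < sqrt(.Machine$double.eps) * max(1, max(abs(y)))) {
    abort("constant response: no transition to fit")
  }
  if (weighting == "inv_y2" && any(y == 0)) {
    abort("1/y^2 weighting undefined for zero responses")
  }

  rising <- unname(coef(stats::lm(y ~ log(x)))[2]) > 0
  start <- c(bottom = min(y), top = max(y),
             x_half = exp(median(log(x))),
             hill = if (rising) -1 else 1)
  w <- if (weighting == "inv_y2") 1 / y^2 else rep(1, length(y))
  sw <- sqrt(w)

  free <- if (is.null(fix_top)) names(start) else setdiff(names(start), "top")
  full_par <- function(par) {
    cf <- start
    cf[free] <- par
    if (!is.null(fix_top)) cf["top"] <- fix_top
    cf
  }
  resid_fn <- function(par) sw * (y - predict_4pl(full_par(par), x))

  fit <- minpack.lm::nls.lm(
    par = start[free], fn = resid_fn,
    lower = c(bottom = -Inf, top = -Inf, x_half = .Machine$double.xmin,
              hill = -Inf)[free],
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (fit$info == 0) {
    abort(paste0("4PL fit did not converge: ", fit$message))
  }
  if (fit$info == 5) {
    warn(paste0("4PL fit stopped at the iteration limit: ", fit$message))
  }
  cf <- full_par(fit$par)[c("bottom", "top", "x_half", "hill")]
  res <- y - predict_4pl(cf, x)
  structure(
    list(coefficients = cf, rss = sum(res^2), fitted = predict_4pl(cf, x),
         residuals = res, data = tibble(x = x, y = y, weight = w),
         weighting = weighting, fixed_top = fix_top,
         convergence = list(info = fit$info, message = fit$message,
                            niter = fit$niter)),
    class = "fit_4pl"
  )
}

predict_4pl <- function(cf, x) {
  cf[["bottom"]] + (cf[["top"]] - cf[["bottom"]]) /
    (1 + (x / cf[["x_half"]])^cf[["hill"]])
}

#' @export
coef.fit_4pl <- function(object, ...) object$coefficients

#' @export
predict.fit_4pl <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata$x %||% newdata
  predict_4pl(object$coefficients, x)
}

#' @export
print.fit_4pl <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "<fit_4pl> bottom %.4g, top %.4g, x_half %.4g, hill %.4g (RSS %.4g, weighting %s)\n",
    cf["bottom"], cf["top"], cf["x_half"], cf["hill"], x$rss, x$weighting))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a 4PL fit
#'
#' @param x A `fit_4pl` object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @method tidy fit_4pl
#' @export
tidy.fit_4pl <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @rdname tidy.fit_4pl
#' @return For `glance`: a one-row tibble with `rss`, `n`, `weighting`
#'   and `x_half`.
#' @method glance fit_4pl
#' @export
glance.fit_4pl <- function(x, ...) {
  tibble(rss = x$rss, n = nrow(x$data), weighting = x$weighting,
         x_half = unname(x$coefficients["x_half"]))
}

#' Back-interpolate a concentration from a fitted standard curve
#'
#' Inverts the fitted four-parameter logistic at an observed response and
#' multiplies by the dilution factor, the standard-curve reading used to
#' quantify unknown samples. Responses at or beyond the fitted asymptotes
#' cannot be inverted and are returned `NA` with a `flag` of
#' `"below_detection"` or `"above_detection"` (relative to the
#' concentration axis).
#'
#' @param fit A `fit_4pl` object.
#' @param y_observed Observed response(s).
#' @param dilution_factor Dilution factor(s) >= 1 applied to the sample
#'   (e.g. 26 for a 1:26 dilution); recycled against `y_observed`.
#' @return Tibble with `y`, `concentration` (interpolated x times the
#'   dilution factor) and `flag` (`"ok"`, `"below_detection"`,
#'   `"above_detection"`).
#' @export
interpolate_concentration <- function(fit, y_observed, dilution_factor = 1) {
  stopifnot(inherits(fit, "fit_4pl"))
  if (any(dilution_factor < 1)) abort("dilution_factor must be >= 1")
  cf <- fit$coefficients
  lo <- min(cf["bottom"], cf["top"])
  hi <- max(cf["bottom"], cf["top"])
  n <- length(y_observed)
  dil <- rep_len(dilution_factor, n)
  conc <- rep(NA_real_, n)
  flag <- rep("ok", n)
  inside <- y_observed > lo & y_observed < hi
  if (any(inside)) {
    ratio <- (cf[["top"]] - cf[["bottom"]]) /
      (y_observed[inside] - cf[["bottom"]]) - 1
    conc[inside] <- cf[["x_half"]] * ratio^(1 / cf[["hill"]]) * dil[inside]
  }
  out_lo <- !inside & !is.na(y_observed)
  if (any(out_lo)) {
    ## which side of the concentration axis an out-of-range response maps
    ## to depends on the curve direction (sign of hill)
    below_y <- y_observed <= lo
    if (cf[["hill"]] < 0) {
      flag[out_lo & below_y] <- "below_detection"
      flag[out_lo & !below_y] <- "above_detection"
    } else {
      flag[out_lo & below_y] <- "above_detection"
      flag[out_lo & !below_y] <- "below_detection"
    }
  }
  tibble(y = y_observed, concentration = conc, flag = flag)
}
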