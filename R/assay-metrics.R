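#' Relative expression by the delta-delta-Ct method
#'
#' `ddCt = (ct - reference_ct)_treated - (ct - reference_ct)_control`;
#' relative expression is `2^(-ddCt)`, assuming perfect per-cycle doubling.
#' An `efficiency` other than 1 replaces the base 2 with
#' `1 + efficiency` (e.g. from a fitted standard curve).
#'
#' @param treated,control Lists (or one-row data.frames) with fields `ct`,
#'   `reference_ct` and `target`; the `target` assays must match.
#' @param efficiency Amplification efficiency as a fraction (default 1 =
#'   perfect doubling).
#' @return Fold change (positive real) of treated over control.
#' @examples
#' ddct(list(target = "miR-375", ct = 20, reference_ct = 15),
#'      list(target = "miR-375", ct = 22, reference_ct = 15))  # 4.0
#' @export
ddct <- function(treated, control, efficiency = 1) {
  if (!identical(treated$target, control$target))
    stop("ddct: mismatched target assays ('", treated$target, "' vs '",
         control$target, "')", call. = FALSE)
  ddct <- (treated$ct - treated$reference_ct) -
    (control$ct - control$reference_ct)
  (1 + efficiency)^(-ddct)
}

#' Spike-in recovery correction
#'
#' Rescales a relative quantity by `2^(spike_ct_sample -
#' spike_ct_reference)`: if the exogenous spike-in (e.g. cel-miR-39a added
#' before RNA purification) comes up one cycle later in the sample than in
#' the reference, only half the material was recovered and the quantity is
#' doubled.
#'
#' @param quantity Relative quantity to correct.
#' @param spike_ct_sample,spike_ct_reference Spike-in Ct in the sample and
#'   the reference purification.
#' @return Corrected quantity.
#' @examples
#' spike_normalize(1, 26, 25)  # 2: half recovery, doubled
#' @export
spike_normalize <- function(quantity, spike_ct_sample, spike_ct_reference) {
  stopifnot(is.finite(spike_ct_sample), is.finite(spike_ct_reference))
  quantity * 2^(spike_ct_sample - spike_ct_reference)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct (y) on log10 copy number (x) over a
#' dilution series. A valid curve has a negative slope; the amplification
#' efficiency is `10^(-1/slope) - 1` (1.0 at the perfect-doubling slope
#' `-1/log10(2) = -3.3219`).
#'
#' @param log10_copies Numeric vector of log10 input copy numbers.
#' @param ct Numeric vector of observed Ct values.
#' @return An object of class `standard_curve` with components `slope`
#'   (cycles per log10 copy), `intercept` (cycles), `r_squared`,
#'   `efficiency`, and the underlying `lm` fit. Has `print()`, `coef()`
#'   and `predict()` methods; `predict()` maps copies to expected Ct.
#' @examples
#' sc <- fit_standard_curve(c(3, 4, 5), c(30, 30 - 1/log10(2), 30 - 2/log10(2)))
#' sc$efficiency  # 1.0
#' @export
fit_standard_curve <- function(log10_copies, ct) {
  stopifnot(length(log10_copies) == length(ct))
  if (length(ct) < 3L)
    stop("fit_standard_curve: need >= 3 points", call. = FALSE)
  if (diff(range(log10_copies)) < 2)
    stop("fit_standard_curve: points must span >= 2 log10 units",
         call. = FALSE)
  fit <- stats::lm(ct ~ log10_copies)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0)
    stop("fit_standard_curve: non-negative slope (", signif(slope, 4),
         "); not a valid dilution curve", call. = FALSE)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = rsq(fit),
                 efficiency = 10^(-1 / slope) - 1,
                 fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve: Ct = ", signif(x$intercept, 6), " + ",
      signif(x$slope, 6), " * log10(copies)\n", sep = "")
  cat("  efficiency ", round(100 * x$efficiency, 1), "%, R^2 ",
      signif(x$r_squared, 4), "\n", sep = "")
  invisible(x)
}

#' @method coef standard_curve
#' @export
coef.standard_curve <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @rdname fit_standard_curve
#' @param object A `standard_curve`.
#' @param copies Copy numbers at which to predict Ct.
#' @param ... Unused.
#' @export
predict.standard_curve <- function(object, copies, ...)
  object$intercept + object$slope * log10(copies)

#' Absolute copy number from a standard curve
#'
#' Inverts the curve: `copies = 10^((ct - intercept) / slope)`. A Ct equal
#' to the intercept corresponds to one copy.
#'
#' @param curve A `standard_curve` from [fit_standard_curve()].
#' @param ct Observed Ct value(s).
#' @return Copy number(s).
#' @examples
#' sc <- fit_standard_curve(c(3, 4, 5), c(30, 26.6781, 23.3562))
#' absolute_copies(sc, predict(sc, 1e4))  # 1e4, round trip
#' @export
absolute_copies <- function(curve, ct) {
  if (!inherits(curve, "standard_curve"))
    stop("absolute_copies: 'curve' must be a standard_curve", call. = FALSE)
  10^((ct - curve$intercept) / curve$slope)
}

#' Fit an exponential decay and half-life
#'
#' Models percent-remaining over time as `P(t) = P0 * exp(-k t)`. The
#' default fit is ordinary least squares of `ln(percent)` on time
#' (closed-form, exact on noiseless exponentials); `method = "nls"` fits
#' the exponential directly by nonlinear least squares as a sensitivity
#' check. The half-life is `ln(2) / k`. A non-decaying series (k <= 0) is
#' returned flagged, with `halflife_h = NA`.
#'
#' @param series A `decay_series` from [simulate_decay_series()], or any
#'   list with `timepoints_h` and `percent_remaining`.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return An object of class `decay_fit`: `k` (1/h), `halflife_h`,
#'   `r_squared` (of the log-linear regression), `decaying` (logical),
#'   `method`, and the fitted model. Has `print()`, `coef()` and
#'   `predict()` methods.
#' @examples
#' fit_decay(list(timepoints_h = c(0, 1, 2),
#'                percent_remaining = c(100, 50, 25)))  # t1/2 = 1 h
#' @export
fit_decay <- function(series, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  t <- series$timepoints_h
  p <- series$percent_remaining
  stopifnot(length(t) == length(p))
  if (length(t) < 3L)
    stop("fit_decay: need >= 3 timepoints", call. = FALSE)
  if (any(p <= 0))
    stop("fit_decay: non-positive percent value; log-linear fit undefined",
         call. = FALSE)

  ll <- stats::lm(log(p) ~ t)
  k <- -unname(stats::coef(ll)[2L])
  fit <- ll
  if (method == "nls") {
    nl <- stats::nls(p ~ p0 * exp(-k * t),
                     start = list(p0 = exp(unname(stats::coef(ll)[1L])),
                                  k = max(k, 1e-6)),
                     control = stats::nls.control(maxiter = 200,
                                                  scaleOffset = 1))
    k <- unname(stats::coef(nl)["k"])
    fit <- nl
  }
  decaying <- k > 0
  structure(list(k = k,
                 halflife_h = if (decaying) log(2) / k else NA_real_,
                 r_squared = rsq(ll),
                 decaying = decaying,
                 method = method,
                 fit = fit),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$decaying)
    cat("decay_fit (", x$method, "): k = ", signif(x$k, 4), " /h, t1/2 = ",
        signif(x$halflife_h, 4), " h, R^2 = ", signif(x$r_squared, 4),
        "\n", sep = "")
  else
    cat("decay_fit (", x$method, "): series not decaying (k = ",
        signif(x$k, 4), " /h), half-life undefined\n", sep = "")
  invisible(x)
}

#' @method coef decay_fit
#' @export
coef.decay_fit <- function(object, ...)
  c(k = object$k, halflife_h = object$halflife_h)

#' @rdname fit_decay
#' @param object A `decay_fit`.
#' @param timepoints_h Times (hours) at which to predict percent remaining.
#' @param ... Unused.
#' @export
predict.decay_fit <- function(object, timepoints_h, ...) {
  p0 <- if (inherits(object$fit, "nls"))
    unname(stats::coef(object$fit)["p0"]) else
      exp(unname(stats::coef(object$fit)[1L]))
  p0 * exp(-object$k * timepoints_h)
}

#' Tumor volume from caliper measurements
#'
#' `V = 0.5 * L * W^2` with length and width in mm; volume in mm^3.
#'
#' @param length_mm,width_mm Caliper length and width, mm (>= 0).
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(10, 5)  # 125
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm < 0) || any(width_mm < 0))
    stop("tumor_volume: negative measurement", call. = FALSE)
  0.5 * length_mm * width_mm^2
}

#' Percent gap closure in a scratch assay
#'
#' Raw closure is `(1 - area_t24 / area_t0) * 100`, relative to the gap
#' area at 0 h. When `control_closure` is supplied the result is
#' normalized by subtraction so the untreated control maps to 0%.
#'
#' @param area_t0 Gap area at 0 h (> 0).
#' @param area_t24 Gap area at 24 h (>= 0).
#' @param control_closure Optional raw closure of the untreated control.
#' @return Percent closure.
#' @examples
#' gap_closure(100, 50)       # 50
#' gap_closure(100, 50, 20)   # 30, control = 0%
#' @export
gap_closure <- function(area_t0, area_t24, control_closure = NULL) {
  if (any(area_t0 <= 0))
    stop("gap_closure: gap area at 0 h must be positive", call. = FALSE)
  if (any(area_t24 < 0))
    stop("gap_closure: negative area", call. = FALSE)
  raw <- (1 - area_t24 / area_t0) * 100
  if (is.null(control_closure)) raw else raw - control_closure
}

# R^2 without summary.lm's zero-residual warning path
rsq <- function(fit) {
  y <- stats::fitted(fit) + stats::resid(fit)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum(stats::resid(fit)^2) / tss
}
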