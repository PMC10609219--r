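# Enzyme-assay arithmetic: endpoint percent inhibition, kinetic relative
# inhibition from delta-RFU pairs, and IC50 from a log-linear
# dose-response fit.

#' Percent inhibition from endpoint signals
#'
#' `100 * (negative_control - inhibitor) / negative_control`: the fraction
#' of the uninhibited signal suppressed by the test compound. Invariant to
#' rescaling both signals by the same positive factor.
#'
#' @param negative_control Signal of the uninhibited (solvent) well; must be
#'   nonzero.
#' @param inhibitor Signal of the inhibitor well.
#' @return Percent inhibition.
#' @export
percent_inhibition <- function(negative_control, inhibitor) {
  if (any(negative_control == 0)) {
    abort("negative control signal is zero: percent inhibition undefined",
          class = "ifpr_error")
  }
  100 * (negative_control - inhibitor) / negative_control
}

#' Kinetic reading pair
#'
#' Two fluorescence readings in the linear range of the enzyme kinetics,
#' at least 10 minutes apart.
#'
#' @param rfu1,rfu2 Relative fluorescence units at `t1` and `t2`.
#' @param t1,t2 Reading times in minutes, `t2 > t1`.
#' @return List of class `kinetic_pair` with a `delta_rfu` field.
#' @export
kinetic_pair <- function(rfu1, rfu2, t1 = 0, t2 = 10) {
  if (t2 <= t1) {
    abort("kinetic pair requires t2 > t1", class = "ifpr_error")
  }
  structure(list(rfu1 = rfu1, rfu2 = rfu2, t1 = t1, t2 = t2,
                 delta_rfu = rfu2 - rfu1),
            class = "kinetic_pair")
}

delta_rfu <- function(x) {
  if (inherits(x, "kinetic_pair")) x$delta_rfu else as.numeric(x)
}

#' Relative inhibition from kinetic delta-RFU
#'
#' `100 * (dRFU_ec - dRFU_sample) / dRFU_ec`, where `dRFU = RFU2 - RFU1`
#' over the chosen reading window for the enzyme control (ec) and the
#' sample.
#'
#' @param ec Enzyme-control [kinetic_pair()] (or a bare delta-RFU value).
#' @param sample Sample [kinetic_pair()] (or a bare delta-RFU value).
#' @return Percent relative inhibition.
#' @export
relative_inhibition <- function(ec, sample) {
  dec <- delta_rfu(ec)
  if (any(dec == 0)) {
    abort("enzyme-control delta-RFU is zero: relative inhibition undefined",
          class = "ifpr_error")
  }
  100 * (dec - delta_rfu(sample)) / dec
}

#' IC50 from log-linear regression of a dose-response table
#'
#' Ordinary least squares of percent response on log10 concentration;
#' the IC50 is the concentration at which the fitted line crosses 50
#' percent: `10^((50 - intercept) / slope)`. Noise-free linear data are
#' inverted exactly for any nonzero slope.
#'
#' @param data Data frame with concentration and response columns.
#' @param concentration,response Column names (strings). Concentrations must
#'   be positive; responses are percent inhibition.
#' @return Object of class `ic50_fit` with fields `ic50`, `slope`,
#'   `intercept`, `r_squared`, `n`, `model` (the underlying `lm`), and
#'   `data`. Supports [tidy()], [glance()], [autoplot()] and `print()`.
#' @examples
#' d <- data.frame(conc = c(10, 1000), resp = 25 * log10(c(10, 1000)))
#' fit <- ic50_loglinear(d, "conc", "resp")
#' fit$ic50
#' @export
ic50_loglinear <- function(data, concentration = "concentration",
                           response = "response") {
  conc <- data[[concentration]]
  resp <- data[[response]]
  if (any(conc <= 0)) {
    abort("concentrations must be positive for a log-scale fit",
          class = "ifpr_error")
  }
  if (length(unique(conc)) < 2) {
    abort("at least 2 distinct concentrations are required",
          class = "ifpr_error")
  }
  d <- tibble(log_conc = log10(conc), response = resp)
  model <- lm(response ~ log_conc, data = d)
  slope <- unname(coef(model)[2])
  intercept <- unname(coef(model)[1])
  if (!is.finite(slope) || abs(slope) < 1e-12) {
    abort("dose-response line has zero slope: no 50% crossing",
          class = "ifpr_error")
  }
  structure(list(
    ic50 = 10^((50 - intercept) / slope),
    slope = slope, intercept = intercept,
    # suppressed: "essentially perfect fit" warning on exact data
    r_squared = suppressWarnings(summary(model)$r.squared),
    n = nrow(d), model = model, data = d
  ), class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat("<ic50_fit> log-linear dose-response\n")
  cat(sprintf("  IC50      %.4g\n", x$ic50))
  cat(sprintf("  slope     %.4g %%/log10\n  intercept %.4g %%\n", x$slope,
              x$intercept))
  cat(sprintf("  R-squared %.4f (n = %d)\n", x$r_squared, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ic50_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @exportS3Method generics::glance
glance.ic50_fit <- function(x, ...) {
  tibble(ic50 = x$ic50, slope = x$slope, intercept = x$intercept,
         r.squared = x$r_squared, n = x$n)
}
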