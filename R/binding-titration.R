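#' Fluorescence titration series
#'
#' Host concentrations and observed fluorescence intensities for a 1:1
#' binding experiment at fixed guest concentration.  The zero-concentration
#' point defines the reference intensity F0.
#'
#' @param cd_conc host concentrations, M; non-negative, strictly
#'   increasing, first entry 0
#' @param intensity fluorescence intensities (arbitrary units)
#' @param guest_conc fixed guest concentration, M (metadata)
#' @return an object of class `titration_series`
#' @export
titration_series <- function(cd_conc, intensity, guest_conc = 25e-6) {
  if (length(cd_conc) != length(intensity)) stop("length mismatch")
  if (cd_conc[1] != 0) stop("first concentration must be the zero reference")
  if (any(diff(cd_conc) <= 0)) stop("concentrations must be strictly increasing")
  if (sum(cd_conc > 0) < 4)
    stop("need at least 4 nonzero-concentration points for fitting")
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  structure(list(cd_conc = as.numeric(cd_conc),
                 intensity = as.numeric(intensity),
                 guest_conc = guest_conc),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %d points, host %.3g-%.3g M, guest %.3g M\n",
              length(x$cd_conc), min(x$cd_conc[x$cd_conc > 0]),
              max(x$cd_conc), x$guest_conc))
  invisible(x)
}

# enhancement over the zero-concentration reference, nonzero points only
delta_f <- function(series) {
  f0 <- series$intensity[series$cd_conc == 0][1]
  nz <- series$cd_conc > 0
  list(conc = series$cd_conc[nz], dF = series$intensity[nz] - f0, f0 = f0)
}

#' Benesi-Hildebrand double-reciprocal binding fit
#'
#' For a 1:1 complex under the excess-host approximation the enhancement
#' obeys 1/dF = 1/dF_c + 1/(Kc dF_c) * 1/[CD]0, so an ordinary
#' least-squares line of 1/dF on 1/[CD]0 yields dF_c = 1/intercept and
#' Kc = intercept/slope.  The standard error of Kc follows by first-order
#' propagation from the regression coefficient covariance.  The
#' zero-concentration point defines F0 and is excluded (1/0 undefined).
#' The regression is unweighted by default, matching the usual linear-fit
#' practice; `weighted = TRUE` applies 1/dF^2-style weights (w = dF^4)
#' that undo the reciprocal transform's variance distortion.
#'
#' @param series a [titration_series()]
#' @param weighted use dF^4 weights in the reciprocal regression
#' @return an object of class `binding_fit`: list with kc (1/M), dF_c,
#'   r_squared, stderr_kc, method
#' @export
fit_benesi_hildebrand <- function(series, weighted = FALSE) {
  stopifnot(inherits(series, "titration_series"))
  d <- delta_f(series)
  if (any(d$dF <= 0))
    stop("non-positive enhancement dF at nonzero concentration: the ",
         "fluorescence-enhancement assumption of the double-reciprocal fit ",
         "is violated")
  xr <- 1 / d$conc
  yr <- 1 / d$dF
  w <- if (weighted) d$dF^4 else rep(1, length(yr))
  fit <- stats::lm(yr ~ xr, weights = w)
  cf <- stats::coef(fit)
  intercept <- unname(cf[1]); slope <- unname(cf[2])
  if (abs(intercept) < 1e-12 * abs(slope) * max(xr))
    stop("near-zero intercept: data are saturated and Kc is unstable; ",
         "add lower host concentrations")
  if (slope <= 0 || intercept <= 0)
    stop("non-positive slope or intercept: data inconsistent with a 1:1 ",
         "enhancement isotherm")
  kc <- intercept / slope
  # delta method on kc = b0/b1; suppress the perfect-fit chatter that
  # summary.lm emits on noise-free data
  V <- suppressWarnings(stats::vcov(fit))
  grad <- c(1 / slope, -intercept / slope^2)
  se_kc <- sqrt(drop(t(grad) %*% V %*% grad))
  ss_tot <- sum(w * (yr - stats::weighted.mean(yr, w))^2)
  r2 <- 1 - sum(w * stats::resid(fit)^2) / ss_tot
  structure(list(kc = kc, dF_c = 1 / intercept, r_squared = r2,
                 stderr_kc = se_kc, method = "benesi_hildebrand"),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Kc = %.4g +/- %.3g 1/M  (dF_c = %.4g, r^2 = %.5f, %s)\n",
              x$kc, x$stderr_kc, x$dF_c, x$r_squared, x$method))
  invisible(x)
}

#' Direct nonlinear 1:1 isotherm fit
#'
#' Fits dF(c) = dF_c Kc c / (1 + Kc c) by nonlinear least squares on the
#' untransformed enhancements, starting from the double-reciprocal
#' estimate (or a saturation-based guess if that fails).  On noise-free
#' data it agrees with [fit_benesi_hildebrand()]; under realistic
#' heteroscedastic noise it is the better-behaved estimator because the
#' reciprocal transform over-weights the smallest enhancements.
#' `exact_mass_balance = TRUE` replaces the excess-host free concentration
#' with the exact 1:1 mass-balance solution (quadratic in the complex
#' concentration) for validation at guest concentrations comparable to
#' the host's.
#'
#' @param series a [titration_series()]
#' @param exact_mass_balance solve the exact quadratic mass balance
#'   instead of assuming [CD]free = [CD]0
#' @return a `binding_fit` with method `"nonlinear"`
#' @export
fit_isotherm_nonlinear <- function(series, exact_mass_balance = FALSE) {
  stopifnot(inherits(series, "titration_series"))
  d <- delta_f(series)
  if (any(d$dF <= 0)) stop("non-positive enhancement dF at nonzero concentration")
  start <- tryCatch({
    bh <- fit_benesi_hildebrand(series)
    list(kc = bh$kc, dF_c = bh$dF_c)
  }, error = function(e) list(kc = 1 / stats::median(d$conc), dF_c = max(d$dF) * 1.2))
  conc <- d$conc; dF <- d$dF; g0 <- series$guest_conc
  model <- if (exact_mass_balance) {
    function(kc, dF_c) {
      # complex conc from the exact 1:1 mass balance, scaled to dF_c at
      # full saturation of the guest
      b <- conc + g0 + 1 / kc
      cc <- (b - sqrt(b^2 - 4 * conc * g0)) / 2
      dF_c * cc / g0
    }
  } else {
    function(kc, dF_c) dF_c * kc * conc / (1 + kc * conc)
  }
  fit <- suppressWarnings(
    stats::nls(dF ~ model(kc, dF_c), start = start,
               control = stats::nls.control(maxiter = 500, warnOnly = TRUE)))
  rms <- sqrt(mean(stats::resid(fit)^2))
  if (!isTRUE(fit$convInfo$isConv) && rms > 1e-8 * diff(range(dF)))
    warning("nonlinear isotherm fit did not fully converge (rms = ",
            signif(rms, 3), ")")
  cf <- stats::coef(fit)
  kc <- unname(cf["kc"])
  if (kc <= 0) stop("nonlinear fit produced Kc <= 0")
  # identifiability diagnostic: all points deep in saturation
  if (kc * min(conc) > 20)
    warning("all concentrations lie deep in saturation (Kc*c >> 1); ",
            "Kc is weakly identified by these data")
  se <- tryCatch(suppressWarnings(
    summary(fit)$coefficients["kc", "Std. Error"]),
    error = function(e) NA_real_)
  ss_tot <- sum((dF - mean(dF))^2)
  r2 <- 1 - sum(stats::resid(fit)^2) / ss_tot
  structure(list(kc = kc, dF_c = unname(cf["dF_c"]), r_squared = r2,
                 stderr_kc = se,
                 method = if (exact_mass_balance) "nonlinear_exact"
                          else "nonlinear"),
            class = "binding_fit")
}

#' Linearity-based 1:1 stoichiometry check
#'
#' Reports the r^2 of the double-reciprocal regression and a verdict:
#' a straight double-reciprocal plot is consistent with (never proof of)
#' 1:1 stoichiometry.  Constant intensity yields the verdict
#' `"no binding signal"`.
#'
#' @param series a [titration_series()]
#' @param threshold minimum r^2 for the consistent verdict (default 0.99)
#' @return list with `r_squared` and `verdict` (one of
#'   `"consistent with 1:1"`, `"inconsistent with 1:1"`,
#'   `"no binding signal"`)
#' @export
stoichiometry_check <- function(series, threshold = 0.99) {
  stopifnot(inherits(series, "titration_series"))
  d <- delta_f(series)
  ok <- d$dF > 0
  if (diff(range(series$intensity)) == 0 || sum(ok) < 3)
    return(list(r_squared = NA_real_, verdict = "no binding signal"))
  # straight regression of the double-reciprocal plot; unlike the binding
  # fit this must not error on curved (non-1:1) data -- curvature is
  # exactly what it measures
  fit <- stats::lm(I(1 / d$dF[ok]) ~ I(1 / d$conc[ok]))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(r_squared = r2,
       verdict = if (r2 >= threshold) "consistent with 1:1"
                 else "inconsistent with 1:1")
}

#' Read a titration series from CSV
#'
#' Expects columns `concentration_mM` (or `concentration_M`) and
#' `intensity`.
#'
#' @param path CSV file
#' @param guest_conc guest concentration, M
#' @return a [titration_series()]
#' @export
read_titration_csv <- function(path, guest_conc = 25e-6) {
  df <- utils::read.csv(path)
  conc <- if ("concentration_M" %in% names(df)) df$concentration_M
          else if ("concentration_mM" %in% names(df)) df$concentration_mM * 1e-3
          else stop("need a concentration_mM or concentration_M column")
  titration_series(conc, df$intensity, guest_conc = guest_conc)
}
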