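#' Generic (x, signal) decay series
#'
#' Container for inversion-recovery curves (x = delay, s) and pulsed-field
#' gradient attenuation curves (x = gradient strength, gauss/cm).  The
#' gradient kind carries its acquisition constants: gyromagnetic ratio
#' gamma (rad s^-1 T^-1), gradient pulse length delta (s) and diffusion
#' delay Delta (s).
#'
#' @param x,signal equal-length numeric vectors; x non-negative with >= 3
#'   distinct values
#' @param kind `"inversion_recovery"` or `"gradient_decay"`
#' @param gamma,delta,Delta acquisition constants (gradient kind only)
#' @return an object of class `decay_series`
#' @export
decay_series <- function(x, signal, kind = c("inversion_recovery",
                                             "gradient_decay"),
                         gamma = GAMMA_1H, delta = 2e-3, Delta = 100e-3) {
  kind <- match.arg(kind)
  if (length(x) != length(signal)) stop("x and signal lengths differ")
  if (length(unique(x)) < 3) stop("need >= 3 distinct x values")
  if (any(x < 0)) stop("x must be non-negative")
  if (!all(is.finite(signal))) stop("signal must be finite")
  structure(list(x = as.numeric(x), signal = as.numeric(signal), kind = kind,
                 gamma = gamma, delta = delta, Delta = Delta),
            class = "decay_series")
}

#' Fit an inversion-recovery curve (three-parameter exponential)
#'
#' Fits signal = B + F * exp(-x * G) by nonlinear least squares and
#' reports T1 = 1/G.  B is the fully-recovered baseline and F the
#' (negative) inversion amplitude; after an ideal 180-degree pulse
#' F = -2B.  Initialization: B0 = signal at the largest delay,
#' F0 = signal(0) - B0, G0 from a log-linear regression of |signal - B0|
#' against delay; on non-convergence up to 5 seeded restarts with jittered
#' G0 are attempted.
#'
#' @param series a [decay_series()] of kind `inversion_recovery`
#' @param max_restarts restarts with jittered G0 on non-convergence
#' @return an object of class `relaxation_fit`: list with B, F, G, T1 (s)
#'   and residual_rms
#' @export
fit_inversion_recovery <- function(series, max_restarts = 5) {
  stopifnot(inherits(series, "decay_series"))
  if (series$kind != "inversion_recovery")
    stop("series kind must be inversion_recovery")
  x <- series$x
  y <- series$signal
  if (diff(range(y)) == 0)
    stop("flat signal: amplitude F is 0 and the rate G is unidentifiable")
  b0 <- y[which.max(x)]
  f0 <- y[which.min(x)] - b0
  if (abs(f0) < 1e-12 * max(abs(y), 1))
    stop("zero amplitude at the shortest delay: G unidentifiable")
  # log-linearized tail for the rate guess; fall back to 1/median(x)
  resid0 <- abs(y - b0)
  ok <- resid0 > 1e-9 * max(resid0)
  g0 <- if (sum(ok) >= 2) {
    sl <- stats::coef(stats::lm(log(resid0[ok]) ~ x[ok]))[2]
    if (is.finite(sl) && sl < 0) -sl else 1 / stats::median(x[x > 0])
  } else 1 / stats::median(x[x > 0])
  # nls refuses zero-residual (noise-free) data; fit with warnOnly and
  # accept if it converged or the residual is numerically zero
  attempt <- function(g_start) {
    fit <- tryCatch(suppressWarnings(
      stats::nls(y ~ B + F * exp(-x * G),
                 start = list(B = b0, F = f0, G = g_start),
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    rms <- sqrt(mean(stats::resid(fit)^2))
    ok <- isTRUE(fit$convInfo$isConv) || rms < 1e-8 * diff(range(y))
    if (ok) fit else NULL
  }
  fit <- attempt(g0)
  if (is.null(fit)) {
    jitters <- with_seed(7L, stats::runif(max_restarts, 0.2, 5))
    for (j in jitters) {
      fit <- attempt(g0 * j)
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit))
    stop("inversion-recovery fit failed to converge after ", max_restarts,
         " restarts; check that the series is a mono-exponential recovery")
  cf <- stats::coef(fit)
  if (cf[["G"]] <= 0)
    stop("fitted rate G <= 0: series is not a decaying recovery")
  structure(list(B = cf[["B"]], F = cf[["F"]], G = cf[["G"]],
                 T1 = 1 / cf[["G"]],
                 residual_rms = sqrt(mean(stats::resid(fit)^2))),
            class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf("T1 = %.4f s (B=%.4g, F=%.4g, G=%.4g 1/s, rms=%.3g)\n",
              x$T1, x$B, x$F, x$G, x$residual_rms))
  invisible(x)
}

#' Percentage-change metric for T1 tables
#'
#' The published before/after tables report, for values in seconds, the
#' absolute difference scaled by 100: |T1_free - T1_complex| * 100 -- the
#' only convention consistent with every scalar row (e.g. 1.36 s vs
#' 1.12 s gives 24).  The conventional relative change
#' 100 |T1_free - T1_complex| / T1_free is computed alongside, clearly
#' labelled.
#'
#' @param t1_free,t1_complex relaxation times, s
#' @return list with `percent` (table convention, rounded half-up to
#'   integer), `percent_exact` (unrounded) and `percent_relative`
#' @export
t1_percentage_change <- function(t1_free, t1_complex) {
  if (t1_free <= 0 || t1_complex <= 0) stop("T1 values must be > 0")
  p <- abs(t1_free - t1_complex) * 100
  list(percent = round_half_up(p, 0),
       percent_exact = p,
       percent_relative = 100 * abs(t1_free - t1_complex) / t1_free)
}

# round half away from zero (printed tables use half-up, not banker's)
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Fit a Stejskal-Tanner gradient decay
#'
#' Ordinary least squares of ln(I) against
#' b(g) = gamma^2 g^2 delta^2 (Delta - delta/3) with g converted from
#' gauss/cm to T/m; the diffusion coefficient is minus the slope.
#'
#' @param series a [decay_series()] of kind `gradient_decay`
#' @return list with `D` (m^2/s), `I0`, `r_squared`, `stderr_D`
#' @export
fit_diffusion <- function(series) {
  stopifnot(inherits(series, "decay_series"))
  if (series$kind != "gradient_decay") stop("series kind must be gradient_decay")
  if (any(series$signal <= 0))
    stop("non-positive intensities cannot enter the log-linear fit")
  g_si <- series$x * 1e-2
  b <- series$gamma^2 * g_si^2 * series$delta^2 * (series$Delta - series$delta / 3)
  if (length(unique(b)) < 3) stop("need >= 3 distinct gradient strengths")
  fit <- stats::lm(log(series$signal) ~ b)
  cf <- stats::coef(fit)
  ss_tot <- sum((log(series$signal) - mean(log(series$signal)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  list(D = unname(-cf[2]), I0 = unname(exp(cf[1])), r_squared = r2,
       stderr_D = unname(suppressWarnings(summary(fit)$coefficients[2, 2])))
}

#' Chemical-shift table
#'
#' Rows of proton label, free shift and complex shift (ppm).  Ranged
#' entries (multiplets printed as intervals, e.g. "5.35-5.09") may be
#' given as two-element numeric vectors through `delta_free_hi` /
#' `delta_complex_hi`; such rows are carried but flagged non-scalar and
#' excluded from scalar perturbation ranking.
#'
#' @param label character, unique proton labels
#' @param delta_free,delta_complex numeric, ppm (lower bound for ranged
#'   rows)
#' @param delta_free_hi,delta_complex_hi optional upper bounds for ranged
#'   rows (NA for scalar rows)
#' @return an object of classes `shift_table` / `data.frame`
#' @export
shift_table <- function(label, delta_free, delta_complex,
                        delta_free_hi = NA_real_, delta_complex_hi = NA_real_) {
  if (anyDuplicated(label)) stop("proton labels must be unique")
  n <- length(label)
  df <- data.frame(label = as.character(label),
                   delta_free = rep_len(delta_free, n),
                   delta_complex = rep_len(delta_complex, n),
                   delta_free_hi = rep_len(delta_free_hi, n),
                   delta_complex_hi = rep_len(delta_complex_hi, n),
                   stringsAsFactors = FALSE)
  if (!all(is.finite(c(df$delta_free, df$delta_complex))))
    stop("shifts must be finite")
  df$ranged <- !is.na(df$delta_free_hi) | !is.na(df$delta_complex_hi)
  structure(df, class = c("shift_table", "data.frame"))
}

#' Chemical-shift perturbations between free and complexed tables
#'
#' Joins two shift tables on the proton label and reports, per matched
#' scalar row, the perturbation |delta_free - delta_complex| rounded
#' half-up to 2 decimals (the printed-table convention) alongside the
#' exact value.  Ranged rows give the interval of boundary differences
#' and are flagged non-scalar; labels present in only one table are
#' reported as missing, never as zero.
#'
#' @param free,complex `shift_table`s with `delta_complex` ignored in
#'   `free` and `delta_free` ignored in `complex`; alternatively a single
#'   combined table may be passed as `free` with `complex = NULL`
#' @return data.frame with columns label, delta_free, delta_complex,
#'   delta_delta (2-dec convention), delta_delta_exact, ranged, missing
#' @export
shift_differences <- function(free, complex = NULL) {
  stopifnot(inherits(free, "shift_table"))
  if (is.null(complex)) {
    combined <- free
  } else {
    stopifnot(inherits(complex, "shift_table"))
    labels <- union(free$label, complex$label)
    combined <- data.frame(label = labels, stringsAsFactors = FALSE)
    fi <- match(labels, free$label)
    ci <- match(labels, complex$label)
    combined$delta_free <- free$delta_free[fi]
    combined$delta_free_hi <- free$delta_free_hi[fi]
    combined$delta_complex <- complex$delta_complex[ci]
    combined$delta_complex_hi <- complex$delta_complex_hi[ci]
    combined$ranged <- (!is.na(combined$delta_free_hi)) |
      (!is.na(combined$delta_complex_hi))
  }
  out <- data.frame(label = combined$label,
                    delta_free = combined$delta_free,
                    delta_complex = combined$delta_complex,
                    stringsAsFactors = FALSE)
  out$missing <- is.na(out$delta_free) | is.na(out$delta_complex)
  out$ranged <- combined$ranged & !out$missing
  dd <- abs(out$delta_free - out$delta_complex)
  dd[out$missing | out$ranged] <- NA_real_
  out$delta_delta_exact <- dd
  out$delta_delta <- round_half_up(dd, 2)
  # interval difference for ranged rows: |free - complex| at both bounds
  rng <- which(out$ranged)
  out$delta_delta_lo <- rep(NA_real_, nrow(out))
  out$delta_delta_hi <- rep(NA_real_, nrow(out))
  for (i in rng) {
    d1 <- abs(combined$delta_free[i] - combined$delta_complex[i])
    d2 <- abs((combined$delta_free_hi[i] %||% combined$delta_free[i]) -
                (combined$delta_complex_hi[i] %||% combined$delta_complex[i]))
    d2 <- ifelse(is.na(d2), d1, d2)
    out$delta_delta_lo[i] <- min(d1, d2)
    out$delta_delta_hi[i] <- max(d1, d2)
  }
  out
}

#' Rank protons by chemical-shift perturbation
#'
#' Scalar rows sorted by descending perturbation; ties broken
#' lexicographically by label.  Ranged and missing rows are excluded.
#'
#' @param delta_table output of [shift_differences()]
#' @return character vector of labels (possibly empty)
#' @export
rank_perturbations <- function(delta_table) {
  keep <- !delta_table$missing & !delta_table$ranged
  d <- delta_table[keep, ]
  if (nrow(d) == 0) return(character(0))
  d$label[order(-d$delta_delta_exact, d$label)]
}

#' Read a decay series or shift table from CSV
#'
#' `read_decay_csv` expects columns `x`, `signal` (and takes kind and
#' acquisition constants as arguments); `read_shifts_csv` expects columns
#' `label`, `delta_free`, `delta_complex` and optional `*_hi` bounds.
#'
#' @param path CSV file
#' @param ... passed to [decay_series()]
#' @return a `decay_series` / `shift_table`
#' @export
read_decay_csv <- function(path, ...) {
  df <- utils::read.csv(path)
  decay_series(df$x, df$signal, ...)
}

#' @rdname read_decay_csv
#' @export
read_shifts_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  shift_table(df$label, df$delta_free, df$delta_complex,
              delta_free_hi = df$delta_free_hi %||% NA_real_,
              delta_complex_hi = df$delta_complex_hi %||% NA_real_)
}
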