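# Modified Langmuir-Hinshelwood kinetics coupled to photon absorption.
#
# Unit convention (one convention, used consistently by the fitter, the rate
# law and the reactor simulator): TOC in ppm (mg C/L); the photon term is
# VRPA^m in W^m; the tank-level rate -V_T d[TOC]/dt is in ppm*m3/s with V_T in
# m3 and time in seconds; hence k_T carries ppm*m3/(s*W^m). Interfaces that
# take minutes (time series) convert internally. The local-LVRPA form of the
# rate law used by the streamline marching differs from this by a constant
# geometry factor; the reactor module handles the conversion explicitly (see
# `photon_term` in single_pass()).

#' Kinetic parameters of the modified Langmuir-Hinshelwood rate law
#'
#' @param k_T Kinetic constant, ppm*m3/(s*W^m) in the package convention
#'   (> 0).
#' @param K_R Apparent adsorption equilibrium constant under irradiation,
#'   1/ppm (> 0). Need not equal the dark-adsorption constant; the two are
#'   reported separately throughout.
#' @param m_exp Photon-order exponent in \[0.5, 1\]; 0.5 when irradiance is
#'   high enough that electron-hole recombination dominates.
#' @return Object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(k_T, K_R, m_exp = 0.5) {
  if (k_T <= 0 || K_R <= 0) stop("k_T and K_R must be positive")
  if (m_exp < 0.5 || m_exp > 1) stop("m_exp must lie in [0.5, 1]")
  structure(list(k_T = k_T, K_R = K_R, m_exp = m_exp),
            class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat(sprintf("L-H kinetics: k_T = %.4g ppm*m3/(s*W^%g), K_R = %.4g 1/ppm, m = %g\n",
              x$k_T, x$m_exp, x$K_R, x$m_exp))
  invisible(x)
}

#' Modified Langmuir-Hinshelwood rate
#'
#' `r = -k_T K_R [TOC] / (1 + K_R [TOC]) * photon_term`: zero at zero TOC,
#' saturating to `-k_T * photon_term` when `K_R [TOC] >> 1`. In the package
#' convention the photon term is `VRPA^m` (W^m) and the rate is the tank-level
#' `V_T d[TOC]/dt` in ppm*m3/s.
#'
#' @param toc TOC concentration(s), ppm. Vectorised.
#' @param params A [kinetic_parameters()] object.
#' @param photon_term `VRPA^m`, W^m (>= 0).
#' @return Rate (negative), ppm*m3/s.
#' @export
lh_rate <- function(toc, params, photon_term) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (any(toc < 0)) stop("toc must be non-negative")
  if (photon_term < 0) stop("photon_term must be non-negative")
  -params$k_T * params$K_R * toc / (1 + params$K_R * toc) * photon_term
}

#' Initial mineralization rate of a TOC time series
#'
#' OLS slope of TOC against standardized time over the first `window` points;
#' negative for a decaying series. The standard error is the usual OLS slope
#' standard error (NA for window = 2).
#'
#' @param series Data frame with columns `t30w_min` and `toc_ppm`, ordered in
#'   time starting at zero; the output of [gen_decay_experiment()] qualifies.
#' @param window Number of leading points used (>= 2).
#' @return List with `rate` (ppm/min), `se` (ppm/min) and `window`.
#' @export
initial_rate <- function(series, window = 3) {
  if (!all(c("t30w_min", "toc_ppm") %in% names(series)))
    stop("series must have columns t30w_min and toc_ppm")
  if (window < 2) stop("window must be at least 2 points")
  if (nrow(series) < window)
    stop(sprintf("series has %d points, need %d", nrow(series), window))
  d <- series[seq_len(window), ]
  x <- d$t30w_min - mean(d$t30w_min)
  sxx <- sum(x^2)
  slope <- sum(x * d$toc_ppm) / sxx
  res <- d$toc_ppm - mean(d$toc_ppm) - slope * x
  se <- if (window > 2) sqrt(sum(res^2) / (window - 2) / sxx) else NA_real_
  list(rate = slope, se = se, window = window)
}

#' Fit k_T and K_R from initial rates by the linearized double-reciprocal form
#'
#' Inverting the tank-level rate law gives a line in double-reciprocal
#' coordinates,
#' `1 / |V_T d[TOC]/dt| = slope * (1/[TOC]0) + intercept`, with
#' `slope = 1 / (K_R k_T VRPA^m)` and `intercept = 1 / (k_T VRPA^m)`, so
#' `K_R = intercept / slope` and `k_T = 1 / (intercept * VRPA^m)`.
#'
#' @param initial_rates Data frame with columns `toc0` (ppm) and `rate_vt`
#'   (the measured `V_T * d[TOC]/dt` at time zero, ppm*m3/s; negative values
#'   are converted to magnitudes). At least 2 distinct `toc0`.
#' @param vrpa Total volumetric rate of photon absorption, W.
#' @param m_exp Photon-order exponent (default 0.5).
#' @return Object of class `lh_fit`: `params` ([kinetic_parameters()] or NULL
#'   on failure), `slope`, `intercept`, `r_squared`, `ok`.
#' @examples
#' # reference operating point: printed regression of the reference study
#' f <- fit_lh_from_line(slope = 348947, intercept = 25773, vrpa = 4.86)
#' signif(f$params$K_R, 4); signif(f$params$k_T, 3)
#' @export
fit_lh_linearized <- function(initial_rates, vrpa, m_exp = 0.5) {
  if (!all(c("toc0", "rate_vt") %in% names(initial_rates)))
    stop("initial_rates must have columns toc0 and rate_vt")
  d <- initial_rates
  if (length(unique(d$toc0)) < 2)
    stop("need at least 2 distinct initial concentrations")
  if (any(d$toc0 <= 0)) stop("toc0 must be positive")
  r <- abs(d$rate_vt)
  if (any(r == 0)) stop("zero initial rate: cannot linearize")
  x <- 1 / d$toc0
  y <- 1 / r
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  out <- fit_lh_from_line(slope, intercept, vrpa, m_exp)
  out$r_squared <- r2
  out$n <- nrow(d)
  out
}

#' @rdname fit_lh_linearized
#' @param slope,intercept Coefficients of the double-reciprocal line.
#' @export
fit_lh_from_line <- function(slope, intercept, vrpa, m_exp = 0.5) {
  ok <- is.finite(slope) && is.finite(intercept) && slope > 0 && intercept > 0
  params <- NULL
  if (ok) {
    phot <- vrpa^m_exp
    params <- kinetic_parameters(k_T = 1 / (intercept * phot),
                                 K_R = intercept / slope, m_exp = m_exp)
  }
  structure(list(params = params, slope = slope, intercept = intercept,
                 vrpa = vrpa, m_exp = m_exp, ok = ok, r_squared = NA_real_,
                 n = NA_integer_),
            class = "lh_fit")
}

#' @export
print.lh_fit <- function(x, ...) {
  if (!x$ok) {
    cat("L-H linearized fit FAILED: non-positive slope or intercept\n")
    return(invisible(x))
  }
  cat(sprintf("L-H linearized fit (VRPA = %.3g W, m = %g):\n", x$vrpa, x$m_exp))
  cat(sprintf("  slope = %.6g, intercept = %.6g (R2 = %s)\n", x$slope,
              x$intercept,
              ifelse(is.na(x$r_squared), "-", sprintf("%.4f", x$r_squared))))
  print(x$params)
  invisible(x)
}

#' Standardized illumination time t30W
#'
#' Rescales clock time to the equivalent time under the reference clear-sky UV
#' irradiance of 30 W/m2, weighting by the irradiated volume fraction:
#' `t30W(n) = t30W(n-1) + dt * (I_UV / 30) * (V_irr / V_T)`.
#'
#' @param clock_times_min Increasing clock times, min, starting at 0.
#' @param uv_irradiance UV irradiance at each time, W/m2 (scalar or vector;
#'   interval dose uses the irradiance at the interval start).
#' @param V_irr Irradiated volume (any unit consistent with `V_T`).
#' @param V_T Total system volume.
#' @return Standardized times, min, same length as `clock_times_min`.
#' @export
t30w_axis <- function(clock_times_min, uv_irradiance, V_irr, V_T) {
  if (any(diff(clock_times_min) <= 0)) stop("clock times must increase")
  if (any(uv_irradiance < 0)) stop("irradiance must be non-negative")
  if (V_irr <= 0 || V_T <= 0 || V_irr > V_T) stop("need 0 < V_irr <= V_T")
  n <- length(clock_times_min)
  iuv <- rep_len(uv_irradiance, n)
  dt <- diff(clock_times_min)
  cumsum(c(0, dt * (iuv[-n] / 30) * (V_irr / V_T)))
}

#' Total UV(A+B) irradiance from a UV-B measurement
#'
#' UV-B is close to 10% of the solar UV A+B irradiance, so a radiometer UV-B
#' reading converts as `I_UV = I_UVB / 0.10`.
#'
#' @param i_uvb UV-B irradiance, W/m2 (>= 0). Vectorised.
#' @return UV A+B irradiance, W/m2.
#' @export
uva_from_uvb <- function(i_uvb) {
  if (any(i_uvb < 0)) stop("irradiance must be non-negative")
  i_uvb / 0.10
}
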