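# Six-flux slab solution: LVRPA profile plus the slab reflectance and
# transmittance of the equivalent two-stream medium. The two-stream reduction
# has attenuation alpha = a*beta*C and coupling beta' = b*beta*C, so the decay
# constant is 1/lambda = a*beta*C*sqrt(1-wc^2) and the semi-infinite
# reflectance is R_inf = (1 - sqrt(1-wc^2)) / omega_corr.

#' Local volumetric rate of photon absorption in a slab
#'
#' Closed-form six-flux LVRPA at depth `rp` into a slurry slab illuminated on
#' one face with irradiance `I0`:
#' \deqn{LVRPA(x) = \frac{I_0}{\lambda \omega_c (1-\gamma)}
#'   \left[(\omega_c - 1 + s) e^{-x/\lambda} +
#'         \gamma (\omega_c - 1 - s) e^{x/\lambda}\right],
#'   \quad s = \sqrt{1-\omega_c^2}.}
#' In the pure-absorption limit (`omega_corr` below `1e-8`) the analytic
#' Beer-Lambert form `I0 * kappa * C * exp(-kappa C x)` is evaluated instead
#' of the indeterminate 0/0 expression.
#'
#' @param rp Depth(s) into the slurry, m, in `[0, delta]`. Vectorised.
#' @param I0 Incident irradiance on the slab face, W/m2.
#' @param sfm An `sfm_derived` object from [sfm_derive()].
#' @return LVRPA in W/m3, same length as `rp`; non-negative throughout the
#'   slab.
#' @examples
#' sf <- sfm_derive(slurry_state(optical_properties(), 0.6, 0.033))
#' lvrpa_slab(0, 30, sf)       # wall value, ~8.2e3 W/m3
#' @export
lvrpa_slab <- function(rp, I0, sfm) {
  stopifnot(inherits(sfm, "sfm_derived"))
  if (any(rp < 0) || any(rp > sfm$slurry$delta + 1e-12))
    stop("rp must lie within the slab [0, delta]")
  if (I0 < 0) stop("I0 must be non-negative")
  if (sfm$gamma >= 1) stop("gamma must be < 1")
  wc <- sfm$omega_corr
  if (sfm$slurry$c_cat == 0) return(rep(0, length(rp)))
  if (wc < 1e-8) {
    kc <- sfm$slurry$props$kappa * sfm$slurry$c_cat
    return(I0 * kc * exp(-kc * rp))
  }
  s <- sqrt(1 - wc^2)
  pref <- I0 / (sfm$lambda_omega * wc * (1 - sfm$gamma))
  v <- pref * ((wc - 1 + s) * exp(-rp / sfm$lambda_omega) +
                 sfm$gamma * (wc - 1 - s) * exp(rp / sfm$lambda_omega))
  pmax(v, 0)
}

#' Reflectance, transmittance and absorbed fraction of the six-flux slab
#'
#' Two-stream closed forms for a slab of apparent optical thickness
#' `tau_app`: with `Rinf = (1-s)/omega_corr` (semi-infinite reflectance,
#' `s = sqrt(1-omega_corr^2)`) and `u = exp(-2 tau_app)`,
#' `R = Rinf (1-u) / (1 - Rinf^2 u)`, `T = (1-Rinf^2) exp(-tau_app) /
#' (1 - Rinf^2 u)`, and the absorbed fraction is `A = 1 - R - T`, which equals
#' the depth integral of [lvrpa_slab()] divided by `I0`.
#'
#' @param omega_corr Corrected albedo in \[0, 1).
#' @param tau_app Apparent optical thickness (>= 0). Vectorised.
#' @return Data frame with columns `tau_app`, `reflectance`, `transmittance`,
#'   `absorbed`.
#' @export
slab_energy_balance <- function(omega_corr, tau_app) {
  if (omega_corr < 0 || omega_corr >= 1) stop("omega_corr must lie in [0, 1)")
  if (any(tau_app < 0)) stop("tau_app must be non-negative")
  if (omega_corr < 1e-8) {
    tr <- exp(-tau_app)
    return(data.frame(tau_app = tau_app, reflectance = 0,
                      transmittance = tr, absorbed = 1 - tr))
  }
  s <- sqrt(1 - omega_corr^2)
  rinf <- (1 - s) / omega_corr
  u <- exp(-2 * tau_app)
  refl <- rinf * (1 - u) / (1 - rinf^2 * u)
  trans <- (1 - rinf^2) * exp(-tau_app) / (1 - rinf^2 * u)
  data.frame(tau_app = tau_app, reflectance = refl, transmittance = trans,
             absorbed = 1 - refl - trans)
}

#' Absorbed fraction of a semi-infinite six-flux slab
#'
#' Limit of the slab absorbed fraction as `tau_app` grows:
#' `(omega_corr - 1 + sqrt(1 - omega_corr^2)) / omega_corr`. Equals 0.5445 for
#' the P-25 corrected albedo 0.7545.
#'
#' @param omega_corr Corrected albedo in (0, 1).
#' @return Dimensionless absorbed fraction in \[0, 1\].
#' @export
absorbed_fraction_semiinf <- function(omega_corr) {
  if (omega_corr <= 0 || omega_corr >= 1) stop("omega_corr must lie in (0, 1)")
  (omega_corr - 1 + sqrt(1 - omega_corr^2)) / omega_corr
}
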