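#' Spectrum-averaged optical properties of a photocatalyst slurry
#'
#' Bundles the specific absorption and scattering coefficients of the catalyst
#' together with the six-flux scattering phase-function probabilities. The six
#' flux directions are 1 forward, 1 backward and 4 sideways, so the
#' probabilities must satisfy `p_f + p_b + 4 p_s = 1`.
#'
#' The defaults are the solar-spectrum averages (up to the TiO2 activation
#' edge at 385 nm) for Aeroxide P-25 in water: kappa = 174.7 m2/kg,
#' sigma = 1295.8 m2/kg, p_f = 0.110, p_b = 0.710, p_s = 0.045.
#'
#' @param kappa Specific absorption coefficient, m2/kg.
#' @param sigma Specific scattering coefficient, m2/kg.
#' @param p_f,p_b,p_s Forward, backward and side scattering probabilities
#'   (dimensionless). One side direction's probability; there are four.
#' @return An object of class `optical_properties` with fields `kappa`,
#'   `sigma`, `beta` (extinction, kappa + sigma), `p_f`, `p_b`, `p_s`.
#' @examples
#' op <- optical_properties()
#' scattering_albedo(op)
#' @export
optical_properties <- function(kappa = 174.7, sigma = 1295.8,
                               p_f = 0.110, p_b = 0.710, p_s = 0.045) {
  stopifnot(is.numeric(kappa), is.numeric(sigma),
            length(kappa) == 1L, length(sigma) == 1L)
  if (kappa < 0 || sigma < 0)
    stop("absorption and scattering coefficients must be non-negative")
  if (kappa + sigma <= 0)
    stop("total extinction kappa + sigma must be positive")
  if (any(c(p_f, p_b, p_s) < 0))
    stop("scattering probabilities must be non-negative")
  psum <- p_f + p_b + 4 * p_s
  if (abs(psum - 1) > 1e-6)
    stop(sprintf("p_f + p_b + 4*p_s must equal 1 (got %.8f)", psum))
  structure(
    list(kappa = kappa, sigma = sigma, beta = kappa + sigma,
         p_f = p_f, p_b = p_b, p_s = p_s),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  cat("Catalyst optical properties (spectrum-averaged)\n")
  cat(sprintf("  kappa = %.1f m2/kg   sigma = %.1f m2/kg   beta = %.1f m2/kg\n",
              x$kappa, x$sigma, x$beta))
  cat(sprintf("  p_f = %.3f  p_b = %.3f  p_s = %.3f  (p_f + p_b + 4 p_s = 1)\n",
              x$p_f, x$p_b, x$p_s))
  invisible(x)
}

#' Slurry state: optics, catalyst loading and optical path
#'
#' @param props An [optical_properties()] object.
#' @param c_cat Catalyst concentration, kg/m3 (numerically equal to g/L).
#' @param delta Optical path length across the tube, m.
#' @return An object of class `slurry_state`.
#' @export
slurry_state <- function(props = optical_properties(), c_cat, delta) {
  stopifnot(inherits(props, "optical_properties"))
  if (!is.numeric(c_cat) || length(c_cat) != 1L || c_cat < 0)
    stop("c_cat must be a single non-negative number (kg/m3)")
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("delta must be a single positive number (m)")
  structure(list(props = props, c_cat = c_cat, delta = delta),
            class = "slurry_state")
}

#' Scattering albedo
#'
#' Fraction of the extinction due to scattering, `sigma / (sigma + kappa)`.
#' For P-25 in water this evaluates to 0.88.
#'
#' @param props An [optical_properties()] object.
#' @return Dimensionless albedo in \[0, 1\].
#' @export
scattering_albedo <- function(props) {
  stopifnot(inherits(props, "optical_properties"))
  if (props$beta <= 0) stop("albedo undefined for zero total extinction")
  props$sigma / props$beta
}

#' Six-flux combination coefficients a and b
#'
#' The six-flux model collapses the scattered photon fluxes into two effective
#' stream-coupling coefficients,
#' `a = 1 - w*p_f - 4 w^2 p_s^2 / d` and `b = w*p_b + 4 w^2 p_s^2 / d`
#' with `d = 1 - w*p_f - w*p_b - 2 w*p_s`. For a physical phase function and
#' albedo `w < 1`, `a > b >= 0`.
#'
#' @param props An [optical_properties()] object.
#' @param omega Scattering albedo; computed from `props` when missing.
#' @return Named numeric vector `c(a = , b = )`.
#' @export
sfm_ab_coefficients <- function(props, omega = scattering_albedo(props)) {
  stopifnot(inherits(props, "optical_properties"))
  d <- 1 - omega * props$p_f - omega * props$p_b - 2 * omega * props$p_s
  if (d <= 0)
    stop("invalid phase-function probabilities: six-flux denominator <= 0")
  side <- 4 * omega^2 * props$p_s^2 / d
  c(a = 1 - omega * props$p_f - side, b = omega * props$p_b + side)
}

#' Corrected scattering albedo
#'
#' Ratio `b / a` of the six-flux combination coefficients: the albedo of the
#' effective two-stream medium the SFM reduces to. For P-25 in water this
#' evaluates to 0.75.
#'
#' @param a,b Six-flux combination coefficients from [sfm_ab_coefficients()].
#' @return Dimensionless corrected albedo.
#' @export
corrected_albedo <- function(a, b) {
  if (a <= 0) stop("coefficient a must be positive")
  b / a
}

#' Optical thickness of the slurry
#'
#' `tau = (sigma + kappa) * delta * C_cat`: extinction events along the
#' optical path. At P-25 optics, delta = 33 mm and 0.6 kg/m3 this is 29.1.
#'
#' @param slurry A [slurry_state()] object.
#' @return Dimensionless optical thickness.
#' @export
optical_thickness <- function(slurry) {
  stopifnot(inherits(slurry, "slurry_state"))
  slurry$props$beta * slurry$delta * slurry$c_cat
}

#' Apparent optical thickness
#'
#' `tau_app = a * tau * sqrt(1 - omega_corr^2)`: the optical thickness of the
#' equivalent purely absorbing medium after the scattering correction. Linear
#' in `tau`, hence in catalyst loading.
#'
#' @param a Six-flux coefficient.
#' @param tau Optical thickness.
#' @param omega_corr Corrected albedo, in \[0, 1).
#' @return Dimensionless apparent optical thickness.
#' @export
apparent_optical_thickness <- function(a, tau, omega_corr) {
  if (omega_corr < 0 || omega_corr >= 1)
    stop("omega_corr must lie in [0, 1)")
  a * tau * sqrt(1 - omega_corr^2)
}

#' Slab back-reflection coefficient gamma
#'
#' `gamma = (1 - sqrt(1 - wc^2)) / (1 + sqrt(1 - wc^2)) * exp(-2 tau_app)`:
#' couples the forward and backward photon streams through the far boundary of
#' a slab of apparent thickness `tau_app`. Vanishes in the optically thick
#' limit.
#'
#' @param omega_corr Corrected albedo, in \[0, 1).
#' @param tau_app Apparent optical thickness, >= 0.
#' @return Dimensionless gamma in \[0, 1).
#' @export
gamma_coefficient <- function(omega_corr, tau_app) {
  if (omega_corr < 0 || omega_corr >= 1)
    stop("omega_corr must lie in [0, 1)")
  if (tau_app < 0) stop("tau_app must be non-negative")
  s <- sqrt(1 - omega_corr^2)
  (1 - s) / (1 + s) * exp(-2 * tau_app)
}

#' Photon absorption-scattering length
#'
#' `lambda = 1 / (a * (sigma + kappa) * C_cat * sqrt(1 - wc^2))`: the e-folding
#' depth of the six-flux photon density. Halves when the catalyst loading
#' doubles.
#'
#' @param a Six-flux coefficient.
#' @param props An [optical_properties()] object.
#' @param c_cat Catalyst concentration, kg/m3 (> 0).
#' @param omega_corr Corrected albedo, in \[0, 1).
#' @return Length in m.
#' @export
photon_path_length <- function(a, props, c_cat, omega_corr) {
  stopifnot(inherits(props, "optical_properties"))
  if (c_cat <= 0) stop("photon path length diverges at zero catalyst loading")
  if (omega_corr < 0 || omega_corr >= 1)
    stop("omega_corr must lie in [0, 1)")
  1 / (a * props$beta * c_cat * sqrt(1 - omega_corr^2))
}

#' Derived six-flux radiation parameters for a slurry
#'
#' Evaluates the whole SFM parameter chain (albedo, a/b coefficients,
#' corrected albedo, optical and apparent optical thickness, gamma, photon
#' path length) for a slurry state.
#'
#' @param slurry A [slurry_state()] object.
#' @return An object of class `sfm_derived`: list with `omega`, `a`, `b`,
#'   `omega_corr`, `tau`, `tau_app`, `gamma`, `lambda_omega` plus the input
#'   `slurry`.
#' @examples
#' sf <- sfm_derive(slurry_state(optical_properties(), c_cat = 0.6, delta = 0.033))
#' round(sf$omega, 2); round(sf$omega_corr, 2)
#' @export
sfm_derive <- function(slurry) {
  stopifnot(inherits(slurry, "slurry_state"))
  omega <- scattering_albedo(slurry$props)
  ab <- sfm_ab_coefficients(slurry$props, omega)
  wc <- corrected_albedo(ab[["a"]], ab[["b"]])
  tau <- optical_thickness(slurry)
  tau_app <- apparent_optical_thickness(ab[["a"]], tau, wc)
  gam <- gamma_coefficient(wc, tau_app)
  lambda <- if (slurry$c_cat > 0)
    photon_path_length(ab[["a"]], slurry$props, slurry$c_cat, wc)
  else Inf
  structure(
    list(omega = omega, a = ab[["a"]], b = ab[["b"]], omega_corr = wc,
         tau = tau, tau_app = tau_app, gamma = gam, lambda_omega = lambda,
         slurry = slurry),
    class = "sfm_derived"
  )
}

#' @export
print.sfm_derived <- function(x, ...) {
  cat("Six-flux derived radiation parameters\n")
  cat(sprintf("  omega      = %.4f    omega_corr = %.4f\n", x$omega, x$omega_corr))
  cat(sprintf("  a          = %.4f    b          = %.4f\n", x$a, x$b))
  cat(sprintf("  tau        = %.3f    tau_app    = %.3f\n", x$tau, x$tau_app))
  cat(sprintf("  gamma      = %.3e    lambda     = %.3e m\n", x$gamma, x$lambda_omega))
  invisible(x)
}
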