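#' CPC reactor geometry and illumination parameters
#'
#' Describes the tubular absorber and compound-parabolic reflector of a solar
#' CPC photoreactor. Defaults follow the pilot unit modelled throughout this
#' package: ten 1.2 m borosilicate tubes (12 m total), 33 mm working optical
#' path, 90 degree acceptance angle (unit concentration ratio).
#'
#' @param tube_radius Absorber tube inner radius, m.
#' @param delta Optical path across the tube used for optical thickness, m
#'   (working value 0.033).
#' @param tube_length Length of one tube, m.
#' @param n_tubes Number of tubes in series.
#' @param theta_a Acceptance half-angle of the collector, radians, in
#'   (0, pi/2].
#' @param aperture_width Width of the illuminated aperture per tube, m. Used
#'   by the illumination models to convert ambient irradiance into wall
#'   irradiance.
#' @param optical_efficiency Dimensionless collector/reflector efficiency in
#'   (0, 1]; scales the photon power reaching the absorber wall.
#' @return Object of class `cpc_geometry`; field `length_total` is
#'   `n_tubes * tube_length`.
#' @export
cpc_geometry <- function(tube_radius = 0.0165, delta = 0.033,
                         tube_length = 1.2, n_tubes = 10,
                         theta_a = pi / 2, aperture_width = 0.1,
                         optical_efficiency = 1) {
  if (tube_radius <= 0) stop("tube_radius must be positive")
  if (tube_length <= 0 || n_tubes < 1) stop("invalid tube length/count")
  if (theta_a <= 0 || theta_a > pi / 2) stop("theta_a must lie in (0, pi/2]")
  if (optical_efficiency <= 0 || optical_efficiency > 1)
    stop("optical_efficiency must lie in (0, 1]")
  if (aperture_width <= 0) stop("aperture_width must be positive")
  structure(
    list(tube_radius = tube_radius, delta = delta, tube_length = tube_length,
         n_tubes = n_tubes, length_total = n_tubes * tube_length,
         theta_a = theta_a, aperture_width = aperture_width,
         optical_efficiency = optical_efficiency),
    class = "cpc_geometry"
  )
}

#' @export
print.cpc_geometry <- function(x, ...) {
  cat("CPC geometry\n")
  cat(sprintf("  tube radius %.1f mm, optical path %.1f mm, %d x %.2f m = %.1f m\n",
              1e3 * x$tube_radius, 1e3 * x$delta, x$n_tubes, x$tube_length,
              x$length_total))
  cat(sprintf("  acceptance angle %.1f deg, aperture %.3f m, efficiency %.2f\n",
              180 / pi * x$theta_a, x$aperture_width, x$optical_efficiency))
  invisible(x)
}

#' Irradiated reactor volume
#'
#' `V_R = pi * R^2 * L_total` in m3. For the default geometry this is
#' 10.26 L.
#'
#' @param geometry A [cpc_geometry()] object.
#' @return Volume in m3.
#' @export
irradiated_volume <- function(geometry) {
  stopifnot(inherits(geometry, "cpc_geometry"))
  pi * geometry$tube_radius^2 * geometry$length_total
}

#' CPC involute reflector profile
#'
#' Radial coordinate `rho(theta)` of the reflector involute:
#' part AB (`|theta| <= theta_a + pi/2`): `rho = R * theta`; part BC
#' (`theta_a + pi/2 <= |theta| <= 3 pi/2 - theta_a`):
#' `rho = R * (theta + theta_a + pi/2 - cos(theta - theta_a)) /
#' (1 + sin(theta - theta_a))`. The `1 + sin` denominator makes the profile
#' continuous at the AB/BC junction. At `theta_a = pi/2` the BC branch is
#' empty and the profile is the pure involute of the tube circle.
#'
#' @param theta Angular coordinate(s), radians, in
#'   `[0, 3 pi/2 - theta_a]`. Vectorised.
#' @param R Tube radius, m.
#' @param theta_a Acceptance half-angle, radians.
#' @return Radial coordinate rho in m.
#' @export
involute_profile <- function(theta, R, theta_a) {
  if (R <= 0) stop("R must be positive")
  if (theta_a <= 0 || theta_a > pi / 2) stop("theta_a must lie in (0, pi/2]")
  th <- abs(theta)
  if (any(th > 3 * pi / 2 - theta_a + 1e-12))
    stop("theta outside the involute domain [0, 3*pi/2 - theta_a]")
  junction <- theta_a + pi / 2
  ab <- th <= junction
  rho <- numeric(length(th))
  rho[ab] <- R * th[ab]
  if (any(!ab)) {
    t2 <- th[!ab]
    rho[!ab] <- R * (t2 + theta_a + pi / 2 - cos(t2 - theta_a)) /
      (1 + sin(t2 - theta_a))
  }
  rho
}

#' Polar quadrature grid over the tube cross-section
#'
#' Uniform node spacing in r and theta with midpoint-cell quadrature weights
#' `r * dr * dtheta` that close the disc area `pi R^2` exactly in
#' exact arithmetic (midpoint rule is exact for the linear integrand r).
#'
#' @param R Tube radius, m.
#' @param n_r Number of radial nodes (>= 2).
#' @param n_theta Number of angular nodes (>= 4).
#' @return Object of class `polar_grid`: vectors `r` (cell-centred radii),
#'   `theta`, matrix-shaped weight vector `w` (length `n_r * n_theta`,
#'   ordered r fastest), and helper fields.
#' @export
build_polar_grid <- function(R, n_r = 50, n_theta = 72) {
  if (R <= 0) stop("R must be positive")
  if (n_r < 2 || n_theta < 4) stop("grid too coarse: need n_r >= 2, n_theta >= 4")
  dr <- R / n_r
  dth <- 2 * pi / n_theta
  r <- (seq_len(n_r) - 0.5) * dr          # cell centres; wall node excluded
  theta <- (seq_len(n_theta) - 0.5) * dth
  w_r <- r * dr * dth                      # per (r, theta) cell
  structure(
    list(R = R, n_r = n_r, n_theta = n_theta, r = r, theta = theta,
         dr = dr, dtheta = dth, w_r = w_r),
    class = "polar_grid"
  )
}

#' Quadrature weights of a polar grid as a full (r, theta) vector
#'
#' @param grid A [build_polar_grid()] object.
#' @return Numeric vector of length `n_r * n_theta` (r index fastest); sums to
#'   `pi R^2`.
#' @export
grid_weights <- function(grid) {
  stopifnot(inherits(grid, "polar_grid"))
  rep(grid$w_r, times = grid$n_theta)
}
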