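#' Reynolds number of the tube flow
#'
#' `Re = 4 Q / (pi D nu)`. At the reference operating point (Q = 30.2 L/min,
#' D = 33 mm, nu = 1e-6 m2/s) this is 1.94e4, i.e. fully turbulent.
#'
#' @param Q Volumetric flow, m3/s.
#' @param diameter Tube diameter, m.
#' @param kinematic_viscosity m2/s.
#' @return Object of class `reynolds`: the number with a `regime` attribute
#'   (`"laminar"` below 2300, `"transitional"` to 4000, `"turbulent"` above).
#'   Behaves as a plain number in arithmetic.
#' @export
reynolds_number <- function(Q, diameter, kinematic_viscosity = 1e-6) {
  if (Q <= 0 || diameter <= 0 || kinematic_viscosity <= 0)
    stop("Q, diameter and kinematic_viscosity must be positive")
  re <- 4 * Q / (pi * diameter * kinematic_viscosity)
  regime <- if (re < 2300) "laminar" else if (re < 4000) "transitional"
  else "turbulent"
  structure(re, regime = regime, class = c("reynolds", "numeric"))
}

#' @export
print.reynolds <- function(x, ...) {
  cat(sprintf("Re = %.0f (%s)\n", unclass(x), attr(x, "regime")))
  invisible(x)
}

#' Darcy friction factor (Blasius correlation)
#'
#' `f = 0.316 Re^-0.25`, valid for smooth pipes with 4e3 < Re < 1e5. Outside
#' the validity range a warning is emitted and the value is still returned.
#'
#' @param Re Reynolds number.
#' @return Dimensionless Darcy friction factor.
#' @export
friction_factor <- function(Re) {
  Re <- as.numeric(Re)
  if (any(Re <= 0)) stop("Re must be positive")
  out <- which(Re <= 4000 | Re >= 1e5)
  if (length(out))
    warning(sprintf("Re = %.3g outside Blasius validity (4e3, 1e5)",
                    Re[out[1]]))
  0.316 * Re^-0.25
}

#' Power-law exponent of the turbulent velocity profile
#'
#' `n = 0.41 sqrt(8 / f)`, the log-law-derived relation between the Darcy
#' friction factor and the exponent of the `(1 - r/R)^(1/n)` profile. At the
#' reference Re = 1.94e4 this gives n = 7.09, the classic one-seventh law.
#'
#' @param f Darcy friction factor (> 0).
#' @return Dimensionless exponent n.
#' @export
power_law_exponent <- function(f) {
  if (f <= 0) stop("friction factor must be positive")
  0.41 * sqrt(8 / f)
}

#' Ratio of maximum to average velocity
#'
#' For the power-law profile, `v_max / v_avg = (n + 1)(2n + 1) / (2 n^2)`;
#' tends to 1 (plug flow) as n grows.
#'
#' @param n Power-law exponent (> 0).
#' @return Dimensionless ratio.
#' @export
velocity_ratio <- function(n) {
  if (n <= 0) stop("n must be positive")
  (n + 1) * (2 * n + 1) / (2 * n^2)
}

#' Turbulent power-law velocity profile
#'
#' `v_z(r) = v_max (1 - r/R)^(1/n)`; zero at the wall, `v_max` on the axis.
#'
#' @param r Radial position(s), m, in `[0, R]`. Vectorised.
#' @param R Tube radius, m.
#' @param n Power-law exponent.
#' @param v_max Centreline velocity, m/s.
#' @return Axial velocity in m/s.
#' @export
velocity_profile <- function(r, R, n, v_max) {
  if (any(r < 0) || any(r > R)) stop("r must lie in [0, R]")
  if (n <= 0 || v_max < 0 || R <= 0) stop("invalid profile parameters")
  v_max * (1 - r / R)^(1 / n)
}

#' Flow specification for the CPC tubes
#'
#' Derives the turbulent-flow description (Reynolds number, Blasius friction
#' factor, power-law exponent, average and centreline velocities) from the
#' volumetric flow and tube diameter.
#'
#' @param Q Volumetric flow, m3/s.
#' @param diameter Tube inner diameter used for the hydrodynamics, m.
#' @param kinematic_viscosity m2/s (default water at ~20 C).
#' @return Object of class `flow_spec` with fields `Q`, `diameter`, `Re`,
#'   `f`, `n`, `v_avg`, `v_max`.
#' @examples
#' fs <- flow_spec(Q = 30.2 / 60000, diameter = 0.033)
#' round(as.numeric(fs$Re))
#' @export
flow_spec <- function(Q, diameter, kinematic_viscosity = 1e-6) {
  re <- reynolds_number(Q, diameter, kinematic_viscosity)
  f <- friction_factor(re)
  n <- power_law_exponent(f)
  v_avg <- Q / (pi * (diameter / 2)^2)
  structure(
    list(Q = Q, diameter = diameter,
         kinematic_viscosity = kinematic_viscosity,
         Re = re, f = f, n = n, v_avg = v_avg,
         v_max = v_avg * velocity_ratio(n)),
    class = "flow_spec"
  )
}

#' @export
print.flow_spec <- function(x, ...) {
  cat(sprintf("Flow: Q = %.2f L/min, D = %.1f mm, Re = %.0f (%s)\n",
              6e4 * x$Q, 1e3 * x$diameter, as.numeric(x$Re),
              attr(x$Re, "regime")))
  cat(sprintf("  f = %.4f, n = %.2f, v_avg = %.3f m/s, v_max = %.3f m/s\n",
              x$f, x$n, x$v_avg, x$v_max))
  invisible(x)
}
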