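test_that("streamline exit: no-reaction and dark limits, closed form vs RK", {
  p <- kinetic_parameters(1e-30, 0.05)
  expect_equal(streamline_exit_toc(200, 0.5, 1e4, 0.12, p), 200)
  p2 <- kinetic_parameters(5e-4, 0.05)
  expect_equal(streamline_exit_toc(200, 0.5, 0, 0.12, p2), 200)
  out <- streamline_exit_toc(200, 0.5, 50, 0.12, p2)
  expect_lt(out, 200)

  # Runge-Kutta oracle for the frozen-denominator streamline ODE
  skip_if_not_installed("deSolve")
  cin <- 213.6; vz <- 0.45; psi <- 120; Lj <- 0.12
  cf <- streamline_exit_toc(cin, vz, psi, Lj, p2)
  rhs <- function(z, y, parms)
    list(-p2$K_R * p2$k_T * psi * y / (vz * (1 + p2$K_R * cin)))
  rk <- as.numeric(deSolve::ode(c(C = cin), c(0, Lj), rhs, NULL,
                                method = "ode45", rtol = 1e-12,
                                atol = 1e-12)[2, 2])
  expect_equal(cf, rk, tolerance = 1e-8)
})

test_that("mixing-cup average: uniform field, two-zone ordering, flow gate", {
  g <- build_polar_grid(0.0165, 50, 72)
  fs <- ref_flow
  vz <- velocity_profile(g$r, 0.0165, fs$n, fs$v_max)
  expect_equal(mixing_cup_average(rep(150, g$n_r), vz, g, fs$Q), 150,
               tolerance = 1e-12)
  expect_equal(mixing_cup_average(matrix(0, g$n_r, g$n_theta), vz, g, fs$Q),
               0)
  # TOC depleted near the wall (slow fluid): flow-weighted mean > area mean
  toc <- ifelse(g$r > 0.012, 100, 200)
  mc <- mixing_cup_average(toc, vz, g, fs$Q)
  area <- sum(toc * g$w_r) / sum(g$w_r)
  expect_gt(mc, area)
  # brute-force quadrature oracle on a smooth field
  toc_f <- function(r) 150 + 50 * exp(-(0.0165 - r) / 0.002)
  fine <- stats::integrate(function(r)
    r * velocity_profile(r, 0.0165, fs$n, fs$v_max) * toc_f(r),
    0, 0.0165, rel.tol = 1e-12)$value * 2 * pi / fs$Q
  expect_equal(mixing_cup_average(toc_f(g$r), vz, g, fs$Q), fine,
               tolerance = 5e-3)
  # inconsistent velocity/grid pairs are rejected
  expect_error(mixing_cup_average(rep(1, g$n_r), vz * 2, g, fs$Q),
               "differs from Q")
})

test_that("single pass: identity without reaction, sub-reactor convergence", {
  spec1 <- coarse_spec(n_subreactors = 1)
  spec100 <- coarse_spec(n_subreactors = 100)
  pz <- kinetic_parameters(1e-30, 0.05)
  expect_equal(single_pass(213.6, spec1, pz), 213.6, tolerance = 1e-12)
  expect_equal(single_pass(213.6, spec100, pz), 213.6, tolerance = 1e-12)

  # operating-scale kinetics: ~1% conversion per pass
  p <- reference_kinetics()
  s100 <- single_pass(300, coarse_spec(n_subreactors = 100,
                                       rate_scale = 29.24), p)
  s200 <- single_pass(300, coarse_spec(n_subreactors = 200,
                                       rate_scale = 29.24), p)
  expect_lt(s100, 299)
  expect_lt(abs(s100 - s200) / s200, 1e-3)
})

test_that("single pass agrees with a continuous-denominator ODE oracle", {
  skip_if_not_installed("deSolve")
  spec <- coarse_spec(n_subreactors = 20,
                      grid = build_polar_grid(0.0165, 16, 8))
  p <- kinetic_parameters(0.6, 0.05)
  field <- lvrpa_field(spec$grid, spec$slurry, spec$I0, spec$geometry,
                       illumination = spec$illumination)
  got <- single_pass(250, spec, p, field = field)
  expect_lt(got / 250, 0.9)   # a pass that actually converts

  psi <- cpcphotokin:::photon_terms(spec, field, p)
  vz <- velocity_profile(spec$grid$r, spec$geometry$tube_radius,
                         spec$flow$n, spec$flow$v_max)
  Lj <- spec$geometry$length_total / spec$n_subreactors
  cur <- 250
  for (j in seq_len(spec$n_subreactors)) {
    outs <- vapply(seq_along(vz), function(i) {
      rhs <- function(z, y, parms)
        list(-p$K_R * p$k_T * psi[i] * y / (vz[i] * (1 + p$K_R * y)))
      deSolve::ode(c(C = cur), c(0, Lj), rhs, NULL, method = "ode45",
                   rtol = 1e-10, atol = 1e-10)[2, 2]
    }, numeric(1))
    cur <- mixing_cup_average(outs, vz, spec$grid, spec$flow$Q)
  }
  expect_equal(got, cur, tolerance = 1e-2)
})

test_that("recirculation pass counting and fractional-pass handling", {
  spec <- coarse_spec()
  expect_equal(spec$V_R, pi * 0.0165^2 * 12, tolerance = 1e-12)
  pz <- kinetic_parameters(1e-30, 0.05)
  run <- recirculation_run(213.6, 42, spec, pz)
  expect_equal(run$n_pass, 30.2 * 42 / (1000 * spec$V_R),
               tolerance = 1e-12)
  expect_equal(run$n_pass, 123.58, tolerance = 1e-4)
  expect_equal(nrow(run$trajectory), 125)   # start + 123 full + 1 partial
  rd <- recirculation_run(213.6, 42, spec, pz, round_down = TRUE)
  expect_equal(nrow(rd$trajectory), 124)
  expect_error(recirculation_run(213.6, -1, spec, pz), "positive")
})

test_that("mass conservation with inert kinetics over a hundred passes", {
  spec <- coarse_spec()
  pz <- kinetic_parameters(1e-300, 1e-6)
  run <- recirculation_run(150, 42, spec, pz)  # 123.6 passes
  expect_equal(run$toc_final, 150, tolerance = 1e-12)
  expect_true(all(run$trajectory$toc_tank_ppm == 150))
})

test_that("trajectory monotone; more photons never remove less", {
  p <- reference_kinetics()
  r1 <- recirculation_run(213.6, 42, coarse_spec(rate_scale = 29.24), p)
  expect_true(all(diff(r1$trajectory$toc_tank_ppm) <= 0))
  r2 <- recirculation_run(213.6, 42, coarse_spec(rate_scale = 58.48), p)
  expect_gt(r2$removal_pct, r1$removal_pct)
})

test_that("first-order and zero-order kinetic limits match closed forms", {
  spec <- coarse_spec(rate_scale = 1)
  field <- lvrpa_field(spec$grid, spec$slurry, spec$I0, spec$geometry,
                       illumination = spec$illumination)
  vrpa <- vrpa_total(vrpa_per_length(field), spec$geometry$length_total)

  # K_R * TOC << 1: single exponential in t with k1 = kT KR sqrt(VRPA)/VT
  p1 <- kinetic_parameters(k_T = 2e-3, K_R = 1e-4)
  run1 <- recirculation_run(50, 42, spec, p1)
  k1 <- p1$k_T * p1$K_R * sqrt(vrpa) / spec$V_T
  expect_equal(run1$toc_final, 50 * exp(-k1 * 42 * 60), tolerance = 1e-3)

  # K_R * TOC >> 1: linear decay with slope kT sqrt(VRPA)/VT
  p0 <- kinetic_parameters(k_T = 2e-4, K_R = 50)
  run0 <- recirculation_run(500, 42, spec, p0)
  expect_equal(run0$toc_final,
               500 - p0$k_T * sqrt(vrpa) / spec$V_T * 42 * 60,
               tolerance = 1e-3)
})

test_that("percent removal at fixed time decreases with initial concentration", {
  p <- reference_kinetics()
  spec <- coarse_spec(rate_scale = 29.24)
  rem <- vapply(c(213.6, 327.6, 433),
                function(c0) recirculation_run(c0, 42, spec, p)$removal_pct,
                numeric(1))
  expect_true(all(diff(rem) < 0))
})

test_that("full reactor marching agrees with the lumped closed form", {
  p <- reference_kinetics()
  spec <- coarse_spec(rate_scale = 29.24)
  field <- lvrpa_field(spec$grid, spec$slurry, spec$I0, spec$geometry,
                       illumination = spec$illumination)
  vrpa <- vrpa_total(vrpa_per_length(field), spec$geometry$length_total)
  lump <- lumped_trajectory(213.6, 42, p, vrpa, spec$V_T, 29.24)
  run <- recirculation_run(213.6, 42, spec, p)
  # coarse-grid flow-closure error bounds the discrepancy
  expect_equal(run$toc_final, lump, tolerance = 5e-3)
})

test_that("rate-scale calibration round trip", {
  p <- reference_kinetics()
  rs <- calibrate_rate_scale(213.6, 0.311, 42, p, 4.86, 0.04)
  end <- lumped_trajectory(213.6, 42, p, 4.86, 0.04, rs)
  expect_equal(1 - end / 213.6, 0.311, tolerance = 1e-9)
  expect_error(calibrate_rate_scale(213.6, 1.2, 42, p, 4.86, 0.04), "\\(0, 1\\)")
})
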