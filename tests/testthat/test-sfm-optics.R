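test_that("scattering albedo matches the P-25 value and its pure limits", {
  expect_equal(scattering_albedo(ref_optics), 1295.8 / 1470.5, tolerance = 1e-12)
  expect_equal(round(scattering_albedo(ref_optics), 2), 0.88)
  pure_abs <- optical_properties(kappa = 100, sigma = 0)
  expect_equal(scattering_albedo(pure_abs), 0)
  pure_sca <- optical_properties(kappa = 0, sigma = 100)
  expect_equal(scattering_albedo(pure_sca), 1)
  expect_error(optical_properties(kappa = 0, sigma = 0), "extinction")
})

test_that("phase-function probabilities are validated at construction", {
  expect_error(optical_properties(p_f = 0.2, p_b = 0.2, p_s = 0.05),
               "p_f \\+ p_b \\+ 4\\*p_s")
  expect_error(optical_properties(p_f = -0.1, p_b = 0.9, p_s = 0.05),
               "non-negative")
  # Table defaults satisfy 0.110 + 0.710 + 4*0.045 = 1
  expect_silent(optical_properties())
})

test_that("six-flux a and b coefficients: reference values and limits", {
  om <- scattering_albedo(ref_optics)
  ab <- sfm_ab_coefficients(ref_optics, om)
  expect_equal(unname(ab["a"]), 0.8713199, tolerance = 1e-6)
  expect_equal(unname(ab["b"]), 0.6573982, tolerance = 1e-6)
  expect_true(ab["a"] > ab["b"] && ab["b"] >= 0)
  # no scattering: a = 1, b = 0
  ab0 <- sfm_ab_coefficients(ref_optics, omega = 0)
  expect_equal(unname(ab0), c(1, 0))
  # no side scattering: a and b reduce to the direct terms exactly
  op <- optical_properties(p_f = 0.3, p_b = 0.7, p_s = 0)
  om2 <- scattering_albedo(op)
  ab2 <- sfm_ab_coefficients(op, om2)
  expect_identical(unname(ab2["a"]), 1 - om2 * 0.3)
  expect_identical(unname(ab2["b"]), om2 * 0.7)
})

test_that("corrected albedo is b/a with its degenerate limits", {
  expect_equal(corrected_albedo(0.8713199, 0.6573982), 0.7544855,
               tolerance = 1e-6)
  expect_equal(round(corrected_albedo(0.8713199, 0.6573982), 2), 0.75)
  expect_equal(corrected_albedo(0.9, 0), 0)
  expect_equal(corrected_albedo(0.7, 0.7), 1)   # conservative scattering
  expect_error(corrected_albedo(0, 0.5), "positive")
})

test_that("optical thickness is (sigma+kappa)*delta*C with linear scaling", {
  expect_equal(optical_thickness(ref_slurry(0.6)), 29.1159, tolerance = 1e-6)
  expect_equal(optical_thickness(ref_slurry(0)), 0)
  expect_equal(optical_thickness(ref_slurry(0.4)), 19.4106, tolerance = 1e-6)
})

test_that("apparent optical thickness and the documented deviation", {
  sf <- sfm_derive(ref_slurry(0.6))
  expect_equal(apparent_optical_thickness(sf$a, sf$tau, sf$omega_corr),
               sf$tau_app)
  expect_equal(sf$tau_app, 16.6503, tolerance = 1e-4)
  # linear in tau and trivial limits
  expect_equal(apparent_optical_thickness(0.9, 10, 0), 9)
  expect_equal(apparent_optical_thickness(0.9, 0, 0.5), 0)
  expect_error(apparent_optical_thickness(0.9, 10, 1), "\\[0, 1\\)")
  # two code paths for tau_app agree to 1e-12: via tau and via lambda-free form
  direct <- sf$a * ref_optics$beta * 0.6 * 0.033 * sqrt(1 - sf$omega_corr^2)
  expect_equal(sf$tau_app, direct, tolerance = 1e-12)
  expect_equal(sf$tau_app, 0.033 / sf$lambda_omega, tolerance = 1e-12)
})

test_that("gamma coefficient: thin-slab value, thick limit, zero albedo", {
  expect_equal(gamma_coefficient(0.7544855, 0), 0.2074985, tolerance = 1e-6)
  expect_lt(gamma_coefficient(0.7544855, 16.65), 1e-13)
  expect_equal(gamma_coefficient(0, 5), 0)
  g <- gamma_coefficient(0.99, 0.01)
  expect_true(g >= 0 && g < 1)
})

test_that("photon path length: reference value and scaling law", {
  sf <- sfm_derive(ref_slurry(0.6))
  expect_equal(sf$lambda_omega, 1.98195e-3, tolerance = 1e-5)
  l1 <- photon_path_length(sf$a, ref_optics, 0.3, sf$omega_corr)
  l2 <- photon_path_length(sf$a, ref_optics, 0.6, sf$omega_corr)
  expect_equal(l1 / l2, 2, tolerance = 1e-12)
  # Beer-Lambert limit: omega_corr = 0, a = 1
  expect_equal(photon_path_length(1, ref_optics, 0.6, 0),
               1 / (ref_optics$beta * 0.6), tolerance = 1e-12)
  expect_error(photon_path_length(sf$a, ref_optics, 0, sf$omega_corr),
               "diverges")
})

test_that("LVRPA slab profile: wall value, positivity, monotone decay", {
  sf <- sfm_derive(ref_slurry(0.6))
  expect_equal(lvrpa_slab(0, 30, sf), 8241.58, tolerance = 1e-5)
  rp <- seq(0, 0.033, length.out = 200)
  v <- lvrpa_slab(rp, 30, sf)
  expect_true(all(v >= 0))
  expect_true(all(diff(v) < 0))     # gamma ~ 0 here: strictly decreasing
  # linear in I0
  expect_equal(lvrpa_slab(rp, 60, sf), 2 * v, tolerance = 1e-12)
})

test_that("LVRPA converges to the Beer-Lambert profile as scattering vanishes", {
  # omega_corr below the analytic-limit threshold takes the exact branch
  op0 <- optical_properties(kappa = 174.7, sigma = 0)
  sf0 <- sfm_derive(slurry_state(op0, 0.6, 0.033))
  rp <- seq(0, 0.033, length.out = 50)
  kc <- 174.7 * 0.6
  expect_equal(lvrpa_slab(rp, 30, sf0), 30 * kc * exp(-kc * rp),
               tolerance = 1e-12)
  # small but nonzero scattering: full closed form approaches the exponential
  op1 <- optical_properties(kappa = 174.7, sigma = 1e-3)
  sf1 <- sfm_derive(slurry_state(op1, 0.6, 0.033))
  expect_equal(lvrpa_slab(rp, 30, sf1), 30 * kc * exp(-kc * rp),
               tolerance = 1e-4)
})

test_that("slab energy balance matches the depth-integrated LVRPA", {
  for (cc in c(0.1, 0.3, 0.6)) {
    sf <- sfm_derive(ref_slurry(cc))
    eb <- slab_energy_balance(sf$omega_corr, sf$tau_app)
    quad <- stats::integrate(function(x) lvrpa_slab(x, 1, sf), 0, 0.033,
                             rel.tol = 1e-10)$value
    expect_equal(quad, eb$absorbed, tolerance = 1e-6)
    expect_true(eb$reflectance >= 0 && eb$transmittance >= 0)
    expect_lt(eb$absorbed, 1)
  }
})

test_that("semi-infinite absorbed fraction: closed form vs quadrature", {
  sf <- sfm_derive(ref_slurry(0.6))
  expect_equal(absorbed_fraction_semiinf(sf$omega_corr), 0.54448,
               tolerance = 1e-5)
  # quadrature over a deep slab with gamma ~ 0 reproduces it
  deep <- stats::integrate(function(x) lvrpa_slab(x, 1, sf), 0, 0.033,
                           rel.tol = 1e-10)$value
  expect_equal(deep, absorbed_fraction_semiinf(sf$omega_corr),
               tolerance = 1e-6)
  # energy bound for a range of albedos
  for (wc in c(0.1, 0.4, 0.7, 0.95))
    expect_lte(absorbed_fraction_semiinf(wc), 1)
})
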