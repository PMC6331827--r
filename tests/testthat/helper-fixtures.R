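# Shared fixtures: reference optics, slurries and a coarse grid for the
# property-style loops (the defaults are used where quadrature accuracy is
# itself under test).

ref_optics <- optical_properties()          # P-25 solar-spectrum averages

ref_slurry <- function(c_cat = 0.6, delta = 0.033)
  slurry_state(ref_optics, c_cat = c_cat, delta = delta)

ref_flow <- flow_spec(Q = 30.2 / 60000, diameter = 0.033)

coarse_spec <- function(..., grid = build_polar_grid(0.0165, 24, 12)) {
  reactor_spec(geometry = cpc_geometry(), flow = ref_flow,
               slurry = ref_slurry(), grid = grid, ...)
}

reference_kinetics <- function() fit_lh_from_line(348947, 25773, 4.86)$params
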