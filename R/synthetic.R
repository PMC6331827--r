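# Seeded generators emulating the three data streams the estimation pipeline
# consumes: dark-adsorption equilibria, TOC decay experiments in the
# recirculating CPC, and solar UV irradiance logs. All randomness goes through
# the seed argument (local RNG state, restored on exit), so a fixed seed gives
# identical output on any platform.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

apply_noise <- function(x, noise_model, noise_sd) {
  if (noise_sd == 0) return(x)
  switch(noise_model,
         multiplicative = x * (1 + stats::rnorm(length(x), 0, noise_sd)),
         additive = x + stats::rnorm(length(x), 0, noise_sd),
         stop("noise_model must be 'multiplicative' or 'additive'"))
}

#' Generate a dark-adsorption equilibrium dataset
#'
#' Langmuir-equilibrium points over a design of equilibrium TOC
#' concentrations, with optional measurement noise on the adsorbed amount.
#' Besides the direct `q` values the generator emits the raw batch view
#' (initial TOC, equilibrium TOC, volume, catalyst load) whose mass balance
#' reproduces `q_obs`, so both file schemas used in practice can be exercised.
#' Defaults are the reference system: `q0 = 1.52` mg/g,
#' `K_ads = 4.42e-3` 1/ppm, equilibrium TOC spanning 50-450 ppm at 0.6 g/L.
#'
#' @param q0,K_ads Langmuir parameters (see [langmuir_q()]).
#' @param toc_eq Design equilibrium concentrations, ppm (>= 3 values).
#' @param catalyst_g_L,volume_L Batch metadata.
#' @param noise_sd Relative (multiplicative) or absolute (additive) noise sd
#'   on `q`.
#' @param noise_model `"multiplicative"` (default) or `"additive"`.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return Data frame with columns `toc0_ppm`, `toc_eq`, `q_obs`,
#'   `catalyst_g_L`, `volume_L`; attributes `q0`, `K_ads`, `seed`.
#' @export
gen_adsorption_dataset <- function(q0 = 1.52, K_ads = 4.42e-3,
                                   toc_eq = seq(50, 450, by = 40),
                                   catalyst_g_L = 0.6, volume_L = 0.3,
                                   noise_sd = 0,
                                   noise_model = "multiplicative",
                                   seed = NULL) {
  if (length(toc_eq) < 3) stop("need at least 3 equilibrium concentrations")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  q <- langmuir_q(toc_eq, q0, K_ads)
  q <- with_seed(seed, apply_noise(q, noise_model, noise_sd))
  q <- pmax(q, .Machine$double.eps)
  out <- data.frame(
    toc0_ppm = toc_eq + q * catalyst_g_L,   # mass balance back out TOC0
    toc_eq = toc_eq, q_obs = q,
    catalyst_g_L = catalyst_g_L, volume_L = volume_L
  )
  attr(out, "q0") <- q0; attr(out, "K_ads") <- K_ads; attr(out, "seed") <- seed
  out
}

#' Generate a TOC decay experiment
#'
#' Noiseless trajectory from the forward reactor model sampled at a
#' standardized-time grid, plus measurement noise. `method = "reactor"` runs
#' the full [recirculation_run()]; `method = "lumped"` uses the closed-form
#' [lumped_trajectory()] (identical in the zero-dimensional limit, and the
#' fast path for replicated studies). Noise draws that would push a sample to
#' zero or below are resampled (count reported in the `resampled` attribute).
#' An estrogens channel is emitted alongside as first-order decay tied to the
#' fractional TOC removal rate (interface completeness; not fitted anywhere).
#'
#' @param params A [kinetic_parameters()] object.
#' @param spec A [reactor_spec()] object.
#' @param toc0 Initial TOC, ppm.
#' @param t_grid Standardized sampling times, min, starting at 0.
#' @param noise_sd Relative sd of multiplicative noise on TOC (default 0.03,
#'   typical TOC-analyzer repeatability) or absolute sd (ppm) for additive.
#' @param noise_model `"multiplicative"` or `"additive"`.
#' @param seed Integer seed.
#' @param method `"reactor"` or `"lumped"`.
#' @param estrogens0 Initial estrogens concentration, ppm.
#' @param estrogens_ratio Ratio of estrogens to TOC fractional decay rates.
#' @return Data frame with columns `t30w_min`, `toc_ppm`, `estrogens_ppm`;
#'   attributes carry the generating parameters and the noiseless series.
#' @export
gen_decay_experiment <- function(params, spec, toc0,
                                 t_grid = seq(0, 42, by = 6),
                                 noise_sd = 0.03,
                                 noise_model = "multiplicative",
                                 seed = NULL, method = c("reactor", "lumped"),
                                 estrogens0 = 5, estrogens_ratio = 2) {
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(spec, "reactor_spec"))
  method <- match.arg(method)
  if (any(diff(t_grid) <= 0) || t_grid[1] != 0)
    stop("t_grid must increase from 0")
  clean <- if (method == "lumped") {
    field <- lvrpa_field(spec$grid, spec$slurry, spec$I0, spec$geometry,
                         illumination = spec$illumination)
    vrpa <- vrpa_total(vrpa_per_length(field), spec$geometry$length_total)
    lumped_trajectory(toc0, t_grid, params, vrpa, spec$V_T, spec$rate_scale)
  } else {
    vapply(t_grid, function(tt) {
      if (tt == 0) toc0
      else recirculation_run(toc0, tt, spec, params)$toc_final
    }, numeric(1))
  }
  resampled <- 0L
  toc <- with_seed(seed, {
    x <- apply_noise(clean, noise_model, noise_sd)
    while (any(x <= 0)) {            # TOC analyzers report positive values
      bad <- x <= 0
      resampled <- resampled + sum(bad)
      x[bad] <- apply_noise(clean[bad], noise_model, noise_sd)
    }
    x
  })
  estro <- estrogens0 * (clean / toc0)^estrogens_ratio
  out <- data.frame(t30w_min = t_grid, toc_ppm = toc, estrogens_ppm = estro)
  attr(out, "clean_toc") <- clean
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  attr(out, "resampled") <- resampled
  out
}

#' Generate a solar UV irradiance log
#'
#' Constant clear-sky irradiance interrupted by random cloud passages: each
#' minute is cloudy with probability `cloud_fraction`, attenuating the
#' irradiance by a uniform factor in (0.2, 0.7). The accumulated dose
#' `integral(I dt)` is reported in kJ/m2 as an attribute.
#'
#' @param mean_W_m2 Target clear-sky-equivalent mean irradiance, W/m2.
#' @param cloud_fraction Probability a sample falls in a cloud passage.
#' @param duration_min Log length, min.
#' @param step_min Sampling step, min.
#' @param seed Integer seed.
#' @return Data frame with `clock_min`, `uv_W_m2`; attribute `dose_kJ_m2`.
#' @export
gen_irradiance_log <- function(mean_W_m2 = 30, cloud_fraction = 0,
                               duration_min = 42, step_min = 1,
                               seed = NULL) {
  if (mean_W_m2 < 0) stop("mean irradiance must be non-negative")
  if (cloud_fraction < 0 || cloud_fraction >= 1)
    stop("cloud_fraction must lie in [0, 1)")
  times <- seq(0, duration_min, by = step_min)
  iuv <- with_seed(seed, {
    base <- rep(mean_W_m2, length(times))
    if (cloud_fraction > 0) {
      cloudy <- stats::runif(length(times)) < cloud_fraction
      att <- stats::runif(sum(cloudy), 0.2, 0.7)
      base[cloudy] <- base[cloudy] * att
      # renormalize so long logs average to the requested mean
      if (mean(base) > 0) base <- base * (mean_W_m2 / mean(base))
    }
    base
  })
  out <- data.frame(clock_min = times, uv_W_m2 = iuv)
  dt <- diff(times)
  attr(out, "dose_kJ_m2") <- sum(iuv[-length(iuv)] * dt * 60) / 1000
  out
}
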