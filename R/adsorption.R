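#' Langmuir isotherm
#'
#' Equilibrium adsorbed amount on the catalyst,
#' `q = q0 K_ads [TOC] / (1 + K_ads [TOC])` in mg(TOC)/g; saturates at `q0`.
#'
#' @param toc Equilibrium TOC concentration(s), ppm (mg C/L). Vectorised.
#' @param q0 Monolayer capacity, mg/g (> 0).
#' @param K_ads Adsorption equilibrium constant, 1/ppm (> 0).
#' @return Adsorbed amount, mg/g.
#' @examples
#' langmuir_q(400, q0 = 1.52, K_ads = 4.42e-3)
#' @export
langmuir_q <- function(toc, q0, K_ads) {
  if (any(toc < 0)) stop("toc must be non-negative")
  if (q0 <= 0 || K_ads <= 0) stop("q0 and K_ads must be positive")
  q0 * K_ads * toc / (1 + K_ads * toc)
}

#' Fit the Langmuir isotherm by the linearized form
#'
#' Ordinary least squares on `[TOC]/q` against `[TOC]`: the linearized
#' isotherm has slope `1/q0` and intercept `1/(q0 K_ads)`. Both estimates must
#' come out positive for a valid monolayer fit; otherwise the result is
#' flagged as a failure and the parameters are `NA`.
#'
#' @param data Data frame with columns `toc_eq` (ppm, > 0) and `q_obs`
#'   (mg/g, > 0); at least 3 rows. The output of
#'   [gen_adsorption_dataset()] qualifies.
#' @param nonlinear_check Also refit `q ~ q0 K toc / (1 + K toc)` by
#'   [stats::nls()] started at the linear estimates, as a diagnostic
#'   (reported, never used as the estimate).
#' @return Object of class `langmuir_fit`: `q0`, `K_ads`, `ok` (logical),
#'   `r_squared`, `residuals` (on the linearized scale), `slope`, `intercept`,
#'   and optionally `nls` with the nonlinear estimates.
#' @export
fit_langmuir_linear <- function(data, nonlinear_check = TRUE) {
  if (!all(c("toc_eq", "q_obs") %in% names(data)))
    stop("data must have columns toc_eq and q_obs")
  d <- data[data$toc_eq > 0 & data$q_obs > 0, , drop = FALSE]
  if (nrow(d) < 3)
    stop("need at least 3 records with positive toc_eq and q_obs")
  y <- d$toc_eq / d$q_obs
  fit <- stats::lm(y ~ toc_eq, data = d)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  res <- unname(stats::residuals(fit))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  ok <- slope > 0 && intercept > 0
  q0 <- if (ok) 1 / slope else NA_real_
  K_ads <- if (ok) slope / intercept else NA_real_
  nls_est <- NULL
  if (ok && nonlinear_check) {
    nls_est <- tryCatch({
      nf <- stats::nls(q_obs ~ q0 * K * toc_eq / (1 + K * toc_eq), data = d,
                       start = list(q0 = q0, K = K_ads))
      as.list(stats::coef(nf))
    }, error = function(e) NULL)
  }
  structure(
    list(q0 = q0, K_ads = K_ads, ok = ok,
         slope = slope, intercept = intercept,
         r_squared = r2,
         residuals = res,
         n = nrow(d), nls = nls_est),
    class = "langmuir_fit"
  )
}

#' @export
print.langmuir_fit <- function(x, ...) {
  if (!x$ok) {
    cat("Langmuir fit FAILED: non-positive slope or intercept",
        "(data inconsistent with monolayer adsorption)\n")
    cat(sprintf("  slope = %.4g, intercept = %.4g, n = %d\n",
                x$slope, x$intercept, x$n))
    return(invisible(x))
  }
  cat(sprintf("Langmuir fit: q0 = %.4g mg/g, K_ads = %.4g 1/ppm (R2 = %.4f, n = %d)\n",
              x$q0, x$K_ads, x$r_squared, x$n))
  if (!is.null(x$nls))
    cat(sprintf("  nonlinear check: q0 = %.4g, K_ads = %.4g\n",
                x$nls$q0, x$nls$K))
  invisible(x)
}

#' Adsorbed amount from the batch mass balance
#'
#' `q = (TOC0 - TOC_eq) * V / m_cat`, mg adsorbed per g of catalyst in a
#' sealed dark-adsorption beaker.
#'
#' @param toc0,toc_eq Initial and equilibrium TOC, ppm.
#' @param volume_L Liquid volume, L.
#' @param catalyst_g_L Catalyst loading, g/L.
#' @return q in mg/g.
#' @export
q_from_mass_balance <- function(toc0, toc_eq, volume_L, catalyst_g_L) {
  if (any(catalyst_g_L <= 0) || any(volume_L <= 0))
    stop("volume and catalyst loading must be positive")
  (toc0 - toc_eq) * volume_L / (catalyst_g_L * volume_L)
}
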