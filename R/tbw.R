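#' Maternal total body water by isotope dilution
#'
#' Back-extrapolates the dam plasma washout curve to the moment of injection
#' and divides the effective dose by that intercept concentration: ordinary
#' least squares of log concentration on time gives the intercept `b0` and
#' elimination slope; `C(0) = exp(b0)` and
#' `TBWd = purity * d2o_mass / C(0)`. The intercept standard error is
#' propagated to the pool mass by the delta method
#' (`se(TBWd) = TBWd * se(b0)`, since the mass is `D * exp(-b0)`).
#'
#' Non-positive concentrations cannot enter the log fit; they are dropped
#' with a warning, and at least two usable points are required.
#'
#' @param dose a [d2o_dose()].
#' @param series an [enrichment_series()] of baseline-corrected dam plasma
#'   concentrations.
#' @return an object of class `tbw_estimate`: list with `mass` (g),
#'   `fraction` (mass / dam body mass), `intercept_conc` and `intercept_se`
#'   (g/g), `mass_se` (g), `elimination_rate` (h^-1, the fitted washout
#'   slope), `n_used`, `n_excluded`.
#' @examples
#' dose <- d2o_dose(1.69, 337.7)
#' s <- enrichment_series(c(3, 24, 48, 72),
#'                        0.0065 * exp(-0.0244 * c(3, 24, 48, 72)),
#'                        "dam_plasma")
#' estimate_tbw(dose, s)
#' @export
estimate_tbw <- function(dose, series) {
  usable <- is.finite(series$conc_gpg) & series$conc_gpg > 0
  n_excluded <- sum(!usable)
  if (n_excluded > 0)
    warning(sprintf("%d non-positive concentration(s) excluded from the log-linear fit",
                    n_excluded))
  if (sum(usable) < 2)
    stop("need at least 2 strictly positive concentrations to extrapolate the intercept")
  d <- data.frame(t = series$time_h[usable],
                  logc = log(series$conc_gpg[usable]))
  fit <- stats::lm(logc ~ t, data = d)
  b0 <- coef(fit)[[1]]
  se_b0 <- if (nrow(d) > 2) {
    # intercept standard error computed directly (a noiseless washout is a
    # legitimate input and must not warn)
    s2 <- sum(residuals(fit)^2) / (nrow(d) - 2)
    x <- d$t
    sqrt(s2 * (1 / nrow(d) + mean(x)^2 / sum((x - mean(x))^2)))
  } else NA_real_
  c0 <- exp(b0)
  D <- tracer_mass(dose)
  mass <- D / c0
  fraction <- mass / dose$dam_body_mass
  if (fraction >= 1 || fraction <= 0)
    warning(sprintf("estimated body-water fraction %.3f is outside (0, 1); check dose and units",
                    fraction))
  structure(list(mass = mass,
                 fraction = fraction,
                 intercept_conc = c0,
                 intercept_se = if (is.na(se_b0)) NA_real_ else c0 * se_b0,
                 mass_se = if (is.na(se_b0)) NA_real_ else mass * se_b0,
                 elimination_rate = -coef(fit)[[2]],
                 n_used = nrow(d),
                 n_excluded = n_excluded),
            class = "tbw_estimate")
}

#' @export
print.tbw_estimate <- function(x, ...) {
  cat("Total body water by D2O dilution\n")
  cat(sprintf("  mass      : %.1f g (se %.2f)\n", x$mass,
              if (is.na(x$mass_se)) NA else x$mass_se))
  cat(sprintf("  fraction  : %.1f %% of body mass\n", 100 * x$fraction))
  cat(sprintf("  intercept : %.4g g/g at t = 0\n", x$intercept_conc))
  cat(sprintf("  washout   : %.5g h^-1 (log-linear slope)\n", x$elimination_rate))
  cat(sprintf("  samples   : %d used, %d excluded\n", x$n_used, x$n_excluded))
  invisible(x)
}
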