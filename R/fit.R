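#' Control settings for the two-compartment tracer fit
#'
#' @param measurement_cv fractional standard deviation of a single
#'   concentration measurement (constant-CV error model). FTIR enrichment
#'   determination is about 1% relative error, the default.
#' @param start named starting values for `k_out_dam`, `k_dam_to_litter`,
#'   `k_out_litter` (h^-1). Defaults bracket reported rodent values: a 24 h
#'   dam water half-life split between environmental loss and milk.
#' @param lower,upper box constraints on the rate constants (h^-1);
#'   physiologic turnover cannot leave `[1e-5, 1]`.
#' @param free_tbw_litter if `TRUE`, litter body water is fitted as a fourth
#'   parameter instead of being fixed from litter mass.
#' @param fit_tbw_dam if `TRUE`, dam body water is co-fitted rather than
#'   fixed at the dilution-intercept estimate (sensitivity mode; the default
#'   two-stage procedure fixes it so the turnover fit has the three rate
#'   unknowns).
#' @param multistart if `TRUE`, retry from a `start_factors` grid around the
#'   starting values when the first attempt fails to converge, keeping the
#'   best converged fit.
#' @param start_factors multiplicative grid applied to each rate start
#'   during multi-start.
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @param pup_water_fraction body-water fraction used to convert litter mass
#'   to litter body water (combined-group median is 76.1%, rounded).
#' @return an object of class `d2o_control`.
#' @export
d2o_control <- function(measurement_cv = 0.01,
                        start = c(k_out_dam = log(2) / 24,
                                  k_dam_to_litter = 0.01,
                                  k_out_litter = 0.02),
                        lower = 1e-5, upper = 1,
                        free_tbw_litter = FALSE,
                        fit_tbw_dam = FALSE,
                        multistart = TRUE,
                        start_factors = c(0.3, 1, 3),
                        maxiter = 200,
                        pup_water_fraction = 0.76) {
  stopifnot(measurement_cv > 0, lower > 0, upper > lower,
            all(start > 0), maxiter >= 1,
            pup_water_fraction > 0, pup_water_fraction < 1)
  need <- c("k_out_dam", "k_dam_to_litter", "k_out_litter")
  if (!all(need %in% names(start)))
    stop("start must name k_out_dam, k_dam_to_litter and k_out_litter")
  structure(list(measurement_cv = measurement_cv, start = start[need],
                 lower = lower, upper = upper,
                 free_tbw_litter = free_tbw_litter,
                 fit_tbw_dam = fit_tbw_dam,
                 multistart = multistart, start_factors = start_factors,
                 maxiter = maxiter,
                 pup_water_fraction = pup_water_fraction),
            class = "d2o_control")
}

check_series <- function(x, compartment, arg) {
  if (!inherits(x, "enrichment_series"))
    stop(sprintf("%s must be an enrichment_series", arg))
  if (!identical(attr(x, "compartment"), compartment))
    stop(sprintf("%s must have compartment '%s', got '%s' (inputs swapped?)",
                 arg, compartment, attr(x, "compartment")))
  if (nrow(x) < 3)
    stop(sprintf("%s needs at least 3 samples for fitting", arg))
  invisible(x)
}

#' Fit the two-compartment water-turnover model to a dam/litter pair
#'
#' Two-stage estimator of milk flow for one dam and its litter. Stage one
#' estimates maternal total body water by isotope dilution
#' ([estimate_tbw()]); stage two fits the three rate constants of the
#' two-compartment model jointly to the dam plasma and litter urine
#' enrichment series by weighted nonlinear least squares
#' (Levenberg-Marquardt). The objective is
#' \deqn{\sum_i \left(\frac{y_i - \hat y_i(\theta)}{cv\,\hat y_i(\theta)}\right)^2,}
#' a constant-CV (fractional standard deviation) error model in which the
#' weights follow the model predictions, the usual weighting for tracer
#' enrichment data. Litter body water is fixed at
#' `litter_mass * pup_water_fraction` unless supplied directly or freed via
#' the control.
#'
#' Milk flow is `k_dam_to_litter * TBWd` (g/h). Parameter standard
#' deviations come from the weighted-residual covariance
#' `sigma^2 (J'J)^{-1}`; coefficients of variation are `100 * sd / estimate`.
#' Non-convergence after multi-start yields a flagged result (`converged =
#' FALSE`), not an error; a rate landing on a box constraint triggers a
#' warning.
#'
#' @param dam [enrichment_series()] of baseline-corrected dam plasma
#'   concentrations (g/g).
#' @param litter [enrichment_series()] of baseline-corrected pooled litter
#'   urine concentrations (g/g); urine enrichment is taken to equal litter
#'   body-water enrichment with no delay.
#' @param dose the dam's [d2o_dose()].
#' @param litter_mass whole-litter body mass (g), used with
#'   `control$pup_water_fraction` when `tbw_litter` is not given.
#' @param tbw_litter litter body water (g), overrides `litter_mass`.
#' @param control a [d2o_control()].
#' @return an object of class `d2o_fit`; see [summary.d2o_fit()],
#'   [milk_flow()], [predict.d2o_fit()], [plot.d2o_fit()].
#' @examples
#' truth <- kinetic_rates(0.012, 0.0122, 0.02)
#' pools <- water_pools(260, 134)
#' dose <- d2o_dose(1.69, 337.7)
#' tp <- c(3, 24, 48, 72); tu <- c(24, 48, 72, 96)
#' dam <- enrichment_series(tp, dam_tracer_concentration(tp, dose, truth, pools),
#'                          "dam_plasma")
#' lit <- enrichment_series(tu, litter_tracer_concentration(tu, dose, truth, pools),
#'                          "litter_urine")
#' fit <- d2o_fit(dam, lit, dose, tbw_litter = 134)
#' coef(fit)
#' milk_flow(fit)
#' @export
d2o_fit <- function(dam, litter, dose, litter_mass = NULL, tbw_litter = NULL,
                    control = d2o_control()) {
  check_series(dam, "dam_plasma", "dam")
  check_series(litter, "litter_urine", "litter")
  if (!inherits(dose, "d2o_dose")) stop("dose must be a d2o_dose")

  tbw <- estimate_tbw(dose, dam)
  if (is.null(tbw_litter)) {
    if (is.null(litter_mass))
      stop("supply either tbw_litter or litter_mass")
    tbw_litter <- litter_mass * control$pup_water_fraction
  }
  if (tbw_litter <= 0) stop("litter body water must be > 0")

  if (any(litter$time_h == 0)) {
    # model value is identically 0 there: no information, undefined relative weight
    message("dropping litter sample(s) at t = 0 from the fit")
    litter <- litter[litter$time_h > 0, , drop = FALSE]
    if (nrow(litter) < 3) stop("litter needs at least 3 samples at t > 0")
  }

  D <- tracer_mass(dose)
  t_dam <- dam$time_h
  t_lit <- litter$time_h
  y <- c(dam$conc_gpg, litter$conc_gpg)
  cv <- control$measurement_cv

  par0 <- control$start
  lower <- rep(control$lower, 3L)
  upper <- rep(control$upper, 3L)
  if (control$fit_tbw_dam) {
    par0 <- c(par0, tbw_dam = tbw$mass)
    lower <- c(lower, 0.1 * tbw$mass)
    upper <- c(upper, 10 * tbw$mass)
  }
  if (control$free_tbw_litter) {
    par0 <- c(par0, tbw_litter = tbw_litter)
    lower <- c(lower, 0.01 * tbw_litter)
    upper <- c(upper, 100 * tbw_litter)
  }

  pred_fun <- function(p) {
    l1 <- p[["k_out_dam"]] + p[["k_dam_to_litter"]]
    k02 <- p[["k_out_litter"]]
    td <- if (control$fit_tbw_dam) p[["tbw_dam"]] else tbw$mass
    tl <- if (control$free_tbw_litter) p[["tbw_litter"]] else tbw_litter
    cd <- D / td * exp(-l1 * t_dam)
    d <- k02 - l1
    cl <- if (abs(d) < 1e-12 * max(l1, k02))
      D * p[["k_dam_to_litter"]] * t_lit * exp(-l1 * t_lit) / tl
    else
      D * p[["k_dam_to_litter"]] * (-exp(-l1 * t_lit) * expm1(-d * t_lit)) / (tl * d)
    c(cd, cl)
  }
  resid_fun <- function(p) {
    yhat <- pred_fun(p)
    (y - yhat) / (cv * yhat)
  }

  run_lm <- function(p) {
    tryCatch(
      minpack.lm::nls.lm(par = p, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = control$maxiter,
                           ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
  }
  ok <- function(f) !is.null(f) && f$info %in% 1:4 && is.finite(f$deviance)

  fit <- run_lm(par0)
  if ((!ok(fit)) && control$multistart) {
    grid <- expand.grid(f1 = control$start_factors,
                        f2 = control$start_factors,
                        f3 = control$start_factors)
    for (i in seq_len(nrow(grid))) {
      p <- par0
      p[1:3] <- pmin(pmax(par0[1:3] * unlist(grid[i, ]), lower[1:3]), upper[1:3])
      cand <- run_lm(p)
      if (ok(cand) && (!ok(fit) || cand$deviance < fit$deviance)) fit <- cand
    }
  }
  converged <- ok(fit)
  if (!converged)
    warning("tracer fit did not converge; result is flagged, interpret with caution")
  if (is.null(fit)) stop("Levenberg-Marquardt failed to evaluate at every start")

  est <- fit$par
  at_bound <- abs(est - lower) < 1e-10 | abs(est - upper) < 1e-10
  if (any(at_bound))
    warning(sprintf("parameter(s) at bound: %s",
                    paste(names(est)[at_bound], collapse = ", ")))

  n_obs <- length(y)
  p_free <- length(est)
  dfree <- n_obs - p_free
  sigma2 <- if (dfree > 0) fit$deviance / dfree else NA_real_
  vc <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) < 0)) {
    vc <- matrix(NA_real_, p_free, p_free,
                 dimnames = list(names(est), names(est)))
  } else {
    dimnames(vc) <- list(names(est), names(est))
  }
  param_sd <- sqrt(diag(vc))
  param_cv <- 100 * param_sd / abs(est)

  tbw_dam_used <- if (control$fit_tbw_dam) est[["tbw_dam"]] else tbw$mass
  tbw_lit_used <- if (control$free_tbw_litter) est[["tbw_litter"]] else tbw_litter
  k21 <- est[["k_dam_to_litter"]]
  milk <- k21 * tbw_dam_used
  milk_sd <- if (control$fit_tbw_dam && all(is.finite(vc))) {
    g <- setNames(numeric(p_free), names(est))  # d(milk)/d(par)
    g["k_dam_to_litter"] <- tbw_dam_used
    g["tbw_dam"] <- k21
    sqrt(drop(t(g) %*% vc %*% g))
  } else {
    tbw_dam_used * param_sd[["k_dam_to_litter"]]
  }

  rates <- kinetic_rates(est[["k_out_dam"]], k21, est[["k_out_litter"]])
  out <- list(coefficients = est,
              rates = rates,
              pools = water_pools(tbw_dam_used, tbw_lit_used),
              tbw_estimate = tbw,
              dose = dose,
              milk_flow = milk,
              milk_flow_sd = milk_sd,
              param_sd = param_sd,
              param_cv = param_cv,
              vcov = vc,
              objective = fit$deviance,
              converged = converged,
              n_obs = n_obs,
              df.residual = dfree,
              sigma2 = sigma2,
              data = list(dam = dam, litter = litter),
              control = control,
              info = fit$info,
              message = fit$message)
  class(out) <- "d2o_fit"
  out
}

#' Milk flow from a converged tracer fit
#'
#' The dam-to-litter water flow `R21 = k_dam_to_litter * TBWd` in g/h. Its
#' standard deviation is propagated from the transfer constant (dam body
#' water is treated as fixed in the default two-stage fit).
#'
#' @param fit a [d2o_fit()] object.
#' @return numeric milk flow (g/h) with attribute `sd`.
#' @export
milk_flow <- function(fit) {
  stopifnot(inherits(fit, "d2o_fit"))
  structure(fit$milk_flow, sd = fit$milk_flow_sd)
}

#' @export
coef.d2o_fit <- function(object, ...) object$coefficients

#' @export
vcov.d2o_fit <- function(object, ...) object$vcov

#' @export
print.d2o_fit <- function(x, digits = 4, ...) {
  cat("Two-compartment D2O turnover fit\n")
  cat(sprintf("  subject: %s%s\n", attr(x$data$dam, "subject_id"),
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  print(format(x$coefficients, digits = digits), quote = FALSE)
  cat(sprintf("  TBW dam: %.1f g (%.1f%% of body mass)\n",
              x$pools$tbw_dam, 100 * x$tbw_estimate$fraction))
  cat(sprintf("  milk flow: %.3f g/h (sd %.3f)\n", x$milk_flow, x$milk_flow_sd))
  invisible(x)
}

#' Summarise a two-compartment tracer fit
#'
#' @param object a [d2o_fit()].
#' @param ... unused.
#' @return a `summary.d2o_fit` list: coefficient table (estimate, sd, cv%),
#'   pools, milk flow with sd, weighted SSR, convergence, sample size.
#' @export
summary.d2o_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Dev.` = object$param_sd,
               `CV %` = object$param_cv)
  structure(list(coef_table = tab,
                 pools = object$pools,
                 tbw = object$tbw_estimate,
                 milk_flow = object$milk_flow,
                 milk_flow_sd = object$milk_flow_sd,
                 objective = object$objective,
                 sigma2 = object$sigma2,
                 converged = object$converged,
                 n_obs = object$n_obs,
                 df.residual = object$df.residual,
                 subject = attr(object$data$dam, "subject_id")),
            class = "summary.d2o_fit")
}

#' @export
print.summary.d2o_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-compartment D2O turnover fit: %s\n\n", x$subject))
  printCoefmat(x$coef_table, digits = digits, cs.ind = 1:2, tst.ind = integer())
  cat(sprintf("\nTBW dam %.1f g (%.1f%%), TBW litter %.1f g\n",
              x$pools$tbw_dam, 100 * x$tbw$fraction, x$pools$tbw_litter))
  cat(sprintf("Milk flow: %.3f g/h (sd %.3f, cv %.1f%%)\n",
              x$milk_flow, x$milk_flow_sd, 100 * x$milk_flow_sd / x$milk_flow))
  cat(sprintf("Weighted SSR %.4g on %d obs (%d df); converged: %s\n",
              x$objective, x$n_obs, x$df.residual, x$converged))
  invisible(x)
}

#' Predicted enrichment curves from a tracer fit
#'
#' @param object a [d2o_fit()].
#' @param newdata optional data frame with columns `time_h` and
#'   `compartment` (`"dam_plasma"` / `"litter_urine"`); defaults to the
#'   fitted observations.
#' @param ... unused.
#' @return numeric vector of predicted concentrations (g/g).
#' @export
predict.d2o_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- data.frame(
      time_h = c(object$data$dam$time_h, object$data$litter$time_h),
      compartment = rep(c("dam_plasma", "litter_urine"),
                        c(nrow(object$data$dam), nrow(object$data$litter))))
  }
  if (!all(newdata$compartment %in% c("dam_plasma", "litter_urine")))
    stop("compartment must be 'dam_plasma' or 'litter_urine'")
  out <- numeric(nrow(newdata))
  is_dam <- newdata$compartment == "dam_plasma"
  if (any(is_dam))
    out[is_dam] <- dam_tracer_concentration(newdata$time_h[is_dam],
                                            object$dose, object$rates,
                                            object$pools)
  if (any(!is_dam))
    out[!is_dam] <- litter_tracer_concentration(newdata$time_h[!is_dam],
                                                object$dose, object$rates,
                                                object$pools)
  out
}

#' @export
fitted.d2o_fit <- function(object, ...) predict(object)

#' Residuals of a tracer fit
#'
#' @param object a [d2o_fit()].
#' @param type `"weighted"` (residual / (cv * prediction), the fitted
#'   objective's scale) or `"raw"` (g/g).
#' @param ... unused.
#' @export
residuals.d2o_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  y <- c(object$data$dam$conc_gpg, object$data$litter$conc_gpg)
  yhat <- fitted(object)
  r <- y - yhat
  if (type == "weighted") r / (object$control$measurement_cv * yhat) else r
}

#' Plot observed and fitted enrichment curves
#'
#' Observed dam plasma (filled) and litter urine (open) concentrations with
#' the fitted model curves on a fine time grid.
#'
#' @param x a [d2o_fit()].
#' @param log_scale plot concentration on a log axis (plasma washout becomes
#'   a straight line).
#' @param ... passed to [plot()].
#' @export
plot.d2o_fit <- function(x, log_scale = FALSE, ...) {
  tmax <- max(x$data$dam$time_h, x$data$litter$time_h)
  grid <- seq(0.01, tmax * 1.05, length.out = 200)
  cd <- dam_tracer_concentration(grid, x$dose, x$rates, x$pools)
  cl <- litter_tracer_concentration(grid, x$dose, x$rates, x$pools)
  ylim <- range(c(cd, cl, x$data$dam$conc_gpg, x$data$litter$conc_gpg))
  if (log_scale) ylim[1] <- max(ylim[1], min(cl[cl > 0]))
  plot(grid, cd, type = "l", lty = 1, ylim = ylim,
       log = if (log_scale) "y" else "",
       xlab = "time since injection (h)",
       ylab = "D2O concentration (g/g above baseline)", ...)
  lines(grid, cl, lty = 2)
  points(x$data$dam$time_h, x$data$dam$conc_gpg, pch = 16)
  points(x$data$litter$time_h, x$data$litter$conc_gpg, pch = 1)
  legend("topright", bty = "n", lty = c(1, 2), pch = c(16, 1),
         legend = c("dam plasma", "litter urine"))
  invisible(x)
}

#' Simulate noisy datasets from a fitted model
#'
#' Draws new dam/litter enrichment series at the fitted parameters under the
#' fit's constant-CV multiplicative error model (truncated at zero), at the
#' original sampling times. Useful for parametric-bootstrap checks.
#'
#' @param object a [d2o_fit()].
#' @param nsim number of datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of length `nsim`; each element has `dam` and `litter`
#'   [enrichment_series()].
#' @export
simulate.d2o_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cv <- object$control$measurement_cv
  td <- object$data$dam$time_h
  tl <- object$data$litter$time_h
  mu_d <- dam_tracer_concentration(td, object$dose, object$rates, object$pools)
  mu_l <- litter_tracer_concentration(tl, object$dose, object$rates, object$pools)
  lapply(seq_len(nsim), function(i) {
    list(dam = enrichment_series(td, mu_d * pmax(0, 1 + cv * rnorm(length(td))),
                                 "dam_plasma",
                                 subject_id = attr(object$data$dam, "subject_id")),
         litter = enrichment_series(tl, mu_l * pmax(0, 1 + cv * rnorm(length(tl))),
                                    "litter_urine",
                                    subject_id = attr(object$data$litter, "subject_id")))
  })
}
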