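#' Convert between g/g and ppm tracer concentrations
#'
#' The canonical concentration unit in this package is grams of D2O per gram
#' of body water (g/g), which makes dose / concentration dimensionally a mass.
#' Instrument output and natural-abundance baselines are often quoted in ppm;
#' 1 g/g = 1e6 ppm.
#'
#' @param x numeric vector of concentrations.
#' @return numeric vector in the other unit.
#' @examples
#' ppm_to_gpg(155)    # natural-abundance baseline, 1.55e-4 g/g
#' gpg_to_ppm(0.005)  # 5000 ppm
#' @export
ppm_to_gpg <- function(x) x / 1e6

#' @rdname ppm_to_gpg
#' @export
gpg_to_ppm <- function(x) x * 1e6

#' Rate constants of the two-compartment water-turnover model
#'
#' Three first-order rate constants (h^-1) govern water turnover during
#' lactation: loss from the dam to the environment (urine, feces,
#' evaporation), transfer from dam to litter through milk, and loss from the
#' litter to the environment. The dam compartment as a whole empties at
#' `lambda1 = k_out_dam + k_dam_to_litter`; milk transfer is kept separate
#' from environmental loss because milk flow is `k_dam_to_litter * TBWd`.
#'
#' `k_dam_to_litter` may be zero (no lactation); the two environmental loss
#' constants must be strictly positive.
#'
#' @param k_out_dam dam-to-environment loss rate (h^-1), > 0.
#' @param k_dam_to_litter dam-to-litter (milk) transfer rate (h^-1), >= 0.
#' @param k_out_litter litter-to-environment loss rate (h^-1), > 0.
#' @return an object of class `kinetic_rates`.
#' @seealso [steady_state_flows()], [dam_tracer_concentration()]
#' @export
kinetic_rates <- function(k_out_dam, k_dam_to_litter, k_out_litter) {
  r <- c(k_out_dam = as.numeric(k_out_dam),
         k_dam_to_litter = as.numeric(k_dam_to_litter),
         k_out_litter = as.numeric(k_out_litter))
  if (!all(is.finite(r)))
    stop("rate constants must be finite")
  if (r[["k_out_dam"]] <= 0 || r[["k_out_litter"]] <= 0 ||
      r[["k_dam_to_litter"]] < 0)
    stop("elimination constants must be > 0 and the transfer constant >= 0")
  structure(as.list(r), class = "kinetic_rates")
}

#' Combined dam elimination rate
#'
#' Total first-order elimination rate of the dam compartment,
#' `k_out_dam + k_dam_to_litter` (h^-1): the slope of the log-linear plasma
#' washout curve.
#'
#' @param rates a [kinetic_rates()] object.
#' @return numeric scalar (h^-1).
#' @export
lambda_dam <- function(rates) rates$k_out_dam + rates$k_dam_to_litter

#' @export
print.kinetic_rates <- function(x, ...) {
  cat("Water-turnover rate constants (h^-1)\n")
  cat(sprintf("  dam -> environment   : %.5g\n", x$k_out_dam))
  cat(sprintf("  dam -> litter (milk) : %.5g\n", x$k_dam_to_litter))
  cat(sprintf("  litter -> environment: %.5g\n", x$k_out_litter))
  invisible(x)
}

#' Total body water pools of dam and litter
#'
#' Compartment sizes of the turnover model: grams of body water in the dam
#' and in the whole litter. They scale tracer mass to concentration.
#'
#' @param tbw_dam dam total body water (g), > 0.
#' @param tbw_litter whole-litter total body water (g), > 0.
#' @return an object of class `water_pools`.
#' @export
water_pools <- function(tbw_dam, tbw_litter) {
  if (!is.finite(tbw_dam) || !is.finite(tbw_litter) ||
      tbw_dam <= 0 || tbw_litter <= 0)
    stop("body-water masses must be strictly positive and finite")
  structure(list(tbw_dam = as.numeric(tbw_dam),
                 tbw_litter = as.numeric(tbw_litter)),
            class = "water_pools")
}

#' An intravenous D2O dose record
#'
#' The injected tracer mass is the syringe weight difference; `purity` is the
#' mole fraction of D2O in the injectate (commercial heavy water is 99.9
#' mole %) and multiplies the injected mass wherever the dose enters the
#' model. A dose rate outside 1-50 g per kg body mass triggers a warning as
#' a likely unit mistake (the reference protocol uses 5 g/kg).
#'
#' @param d2o_mass grams of D2O injected, > 0.
#' @param dam_body_mass dam body mass in grams, > 0.
#' @param purity mole fraction of D2O in the injectate, in (0, 1].
#' @return an object of class `d2o_dose`.
#' @export
d2o_dose <- function(d2o_mass, dam_body_mass, purity = 0.999) {
  if (!is.finite(d2o_mass) || d2o_mass <= 0)
    stop("d2o_mass must be > 0")
  if (!is.finite(dam_body_mass) || dam_body_mass <= 0)
    stop("dam_body_mass must be > 0")
  if (!is.finite(purity) || purity <= 0 || purity > 1)
    stop("purity must be in (0, 1]")
  rate <- d2o_mass / dam_body_mass
  if (rate < 0.001 || rate > 0.05)
    warning(sprintf(
      "dose rate %.4g g/g body mass is outside the plausible 0.001-0.05 range; check units",
      rate))
  structure(list(d2o_mass = as.numeric(d2o_mass),
                 dam_body_mass = as.numeric(dam_body_mass),
                 purity = as.numeric(purity)),
            class = "d2o_dose")
}

# effective tracer mass entering the model (g)
tracer_mass <- function(dose) dose$purity * dose$d2o_mass

#' A baseline-corrected enrichment time series for one compartment
#'
#' Holds timestamped D2O concentrations (g/g above natural abundance) for one
#' compartment of one dam/litter: `dam_plasma` or `litter_urine`. Times must
#' be non-negative and strictly increasing; concentrations non-negative
#' (baseline correction with clipping is done by [subtract_baseline()]).
#'
#' @param time_h sampling times in hours since injection.
#' @param conc_gpg concentrations in g D2O per g body water, above baseline.
#' @param compartment `"dam_plasma"` or `"litter_urine"`.
#' @param subject_id dam/litter label.
#' @param group group label (e.g. `"NP"`, `"LP"`), optional.
#' @return a data frame of class `enrichment_series` with columns `time_h`
#'   and `conc_gpg` and attributes `subject_id`, `group`, `compartment`.
#' @export
enrichment_series <- function(time_h, conc_gpg,
                              compartment = c("dam_plasma", "litter_urine"),
                              subject_id = "subject", group = NA_character_) {
  compartment <- match.arg(compartment)
  time_h <- as.numeric(time_h)
  conc_gpg <- as.numeric(conc_gpg)
  if (length(time_h) != length(conc_gpg))
    stop("time_h and conc_gpg must have the same length")
  if (any(!is.finite(time_h)) || any(time_h < 0))
    stop("sampling times must be finite and >= 0")
  if (any(diff(time_h) <= 0))
    stop("sampling times must be strictly increasing")
  if (any(!is.finite(conc_gpg)) || any(conc_gpg < 0))
    stop("concentrations must be finite and >= 0 (baseline-corrected)")
  structure(data.frame(time_h = time_h, conc_gpg = conc_gpg),
            subject_id = subject_id, group = group, compartment = compartment,
            class = c("enrichment_series", "data.frame"))
}

#' @export
print.enrichment_series <- function(x, ...) {
  cat(sprintf("Enrichment series: %s / %s (%d samples)\n",
              attr(x, "subject_id"), attr(x, "compartment"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Deduct the natural-abundance baseline from a raw series
#'
#' Before dosing, body water already carries D2O at its natural abundance
#' (about 155 ppm). Raw instrument concentrations are corrected by
#' subtracting the subject's pre-dose baseline; values driven below zero by
#' measurement noise are clipped to zero with a warning (the number clipped
#' is stored in the `n_clipped` attribute). A baseline exceeding every
#' observation is rejected as a probable unit mismatch.
#'
#' @param series an [enrichment_series()] of raw (baseline-inclusive)
#'   concentrations in g/g.
#' @param baseline_gpg the pre-dose concentration in g/g, >= 0.
#' @return the corrected `enrichment_series`.
#' @examples
#' raw <- enrichment_series(24, 0.005, "dam_plasma")
#' subtract_baseline(raw, ppm_to_gpg(155))
#' @export
subtract_baseline <- function(series, baseline_gpg) {
  if (!is.finite(baseline_gpg) || baseline_gpg < 0)
    stop("baseline must be finite and >= 0")
  if (baseline_gpg > 0 && all(series$conc_gpg < baseline_gpg))
    stop("baseline exceeds every observation; check units (ppm vs g/g)")
  corrected <- series$conc_gpg - baseline_gpg
  n_clipped <- sum(corrected < 0)
  if (n_clipped > 0) {
    warning(sprintf("%d concentration(s) below baseline clipped to 0", n_clipped))
    corrected[corrected < 0] <- 0
  }
  out <- series
  out$conc_gpg <- corrected
  attr(out, "n_clipped") <- n_clipped
  out
}
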