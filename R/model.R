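#' Tracer concentration in dam body water after a bolus
#'
#' Closed-form solution of the dam compartment of the two-compartment
#' water-turnover model. With an instantaneous intravenous bolus of effective
#' tracer mass `D = purity * d2o_mass` into dam body water `TBWd`, the dam
#' loses tracer by first-order flow to the environment (`k_out_dam`) and to
#' the litter through milk (`k_dam_to_litter`), so
#'
#' \deqn{C_d(t) = \frac{D}{TBW_d} e^{-(K_{01}+K_{21}) t}}
#'
#' in g D2O per g body water, strictly decreasing in time.
#'
#' @param t time since injection in hours (vectorised), >= 0.
#' @param dose a [d2o_dose()].
#' @param rates a [kinetic_rates()].
#' @param pools a [water_pools()].
#' @return concentrations in g/g, same length as `t`.
#' @export
dam_tracer_concentration <- function(t, dose, rates, pools) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("time must be finite and >= 0")
  tracer_mass(dose) / pools$tbw_dam * exp(-lambda_dam(rates) * t)
}

#' Tracer concentration in litter body water after a maternal bolus
#'
#' Closed-form solution of the litter compartment: tracer arrives from the
#' dam at rate `k_dam_to_litter * m_dam(t)` and leaves at `k_out_litter`,
#' giving the bi-exponential
#'
#' \deqn{C_l(t) = \frac{D\,K_{21}\,(e^{-\lambda_1 t} - e^{-K_{02} t})}
#'                    {TBW_l (K_{02} - \lambda_1)}}
#'
#' with \eqn{\lambda_1 = K_{01} + K_{21}}. At the degenerate point
#' \eqn{K_{02} = \lambda_1} the limit form
#' \eqn{D K_{21} t e^{-\lambda_1 t} / TBW_l} is used. The exponential
#' difference is evaluated through `expm1` so the expression stays accurate
#' near the degeneracy. The curve is 0 at t = 0, non-negative, and unimodal
#' with maximum at [litter_peak_time()].
#'
#' @inheritParams dam_tracer_concentration
#' @return concentrations in g/g, same length as `t`.
#' @export
litter_tracer_concentration <- function(t, dose, rates, pools) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("time must be finite and >= 0")
  l1 <- lambda_dam(rates)
  k02 <- rates$k_out_litter
  D <- tracer_mass(dose)
  k21 <- rates$k_dam_to_litter
  d <- k02 - l1
  if (abs(d) < 1e-12 * max(l1, k02)) {
    D * k21 * t * exp(-l1 * t) / pools$tbw_litter
  } else {
    # e^(-l1 t) - e^(-k02 t) = -e^(-l1 t) * expm1(-(k02 - l1) t)
    D * k21 * (-exp(-l1 * t) * expm1(-d * t)) / (pools$tbw_litter * d)
  }
}

#' Time of maximum litter enrichment
#'
#' The litter curve rises while transfer from the dam outpaces litter
#' elimination and falls afterwards; its maximum is at
#' \eqn{\ln(\lambda_1 / K_{02}) / (\lambda_1 - K_{02})} (or
#' \eqn{1/\lambda_1} when the two rates coincide). Useful for checking that
#' the urine sampling schedule brackets the peak.
#'
#' @param rates a [kinetic_rates()].
#' @return time in hours, > 0.
#' @export
litter_peak_time <- function(rates) {
  l1 <- lambda_dam(rates)
  k02 <- rates$k_out_litter
  if (abs(k02 - l1) < 1e-12 * max(l1, k02)) 1 / l1
  else log(l1 / k02) / (l1 - k02)
}

#' Steady-state water flows implied by rates and pool sizes
#'
#' At steady state each first-order flow is rate times source pool:
#' `R01 = K01*TBWd` (dam output), `R21 = K21*TBWd` (milk flow),
#' `R10 = R01 + R21` (dam intake), `R02 = K02*TBWl` (litter output) and
#' `R20 = R02 - R21` (litter non-milk intake). The two balance identities
#' hold by construction. A negative `R20` is returned but flagged with a
#' warning: a litter excreting less water than it drinks as milk is storing
#' water, i.e. growing, which bends the strict steady-state assumption
#' (expected for suckling pups).
#'
#' @param rates a [kinetic_rates()].
#' @param pools a [water_pools()].
#' @return an object of class `flow_set`: list with `r_in_dam`, `r_out_dam`,
#'   `r_dam_to_litter`, `r_in_litter`, `r_out_litter`, all g/h.
#' @examples
#' steady_state_flows(kinetic_rates(0.012, 0.01223, 0.02),
#'                    water_pools(282.1, 130))
#' @export
steady_state_flows <- function(rates, pools) {
  r_out_dam <- rates$k_out_dam * pools$tbw_dam
  r_dam_to_litter <- rates$k_dam_to_litter * pools$tbw_dam
  r_in_dam <- r_out_dam + r_dam_to_litter
  r_out_litter <- rates$k_out_litter * pools$tbw_litter
  r_in_litter <- r_out_litter - r_dam_to_litter
  if (r_in_litter < 0)
    warning("litter milk intake exceeds litter water output (R20 < 0): litter water pool is growing, strict steady state does not hold")
  structure(list(r_in_dam = r_in_dam,
                 r_out_dam = r_out_dam,
                 r_dam_to_litter = r_dam_to_litter,
                 r_in_litter = r_in_litter,
                 r_out_litter = r_out_litter),
            class = "flow_set")
}

#' @export
print.flow_set <- function(x, ...) {
  cat("Steady-state water flows (g/h)\n")
  cat(sprintf("  dam intake (R10)        : %8.4f\n", x$r_in_dam))
  cat(sprintf("  dam output (R01)        : %8.4f\n", x$r_out_dam))
  cat(sprintf("  milk flow (R21)         : %8.4f\n", x$r_dam_to_litter))
  cat(sprintf("  litter non-milk intake  : %8.4f\n", x$r_in_litter))
  cat(sprintf("  litter output (R02)     : %8.4f\n", x$r_out_litter))
  invisible(x)
}
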