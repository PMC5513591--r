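# Independent oracles used to check the package's closed forms and tests.
# They deliberately avoid the implementation paths: the compartment model is
# integrated numerically (deSolve), the Mann-Whitney reference enumerates
# label assignments and computes U from pairwise comparisons, and the Welch
# reference integrates the t density numerically.

# numerical integration of dm1/dt = -(K01+K21) m1, dm2/dt = K21 m1 - K02 m2
ode_concentrations <- function(t, dose, rates, pools, rtol = 1e-10) {
  D <- dose$purity * dose$d2o_mass
  deriv <- function(time, m, p) {
    list(c(-(p$k01 + p$k21) * m[1],
           p$k21 * m[1] - p$k02 * m[2]))
  }
  times <- sort(unique(c(0, t)))
  sol <- deSolve::lsoda(c(m1 = D, m2 = 0), times, deriv,
                        list(k01 = rates$k_out_dam,
                             k21 = rates$k_dam_to_litter,
                             k02 = rates$k_out_litter),
                        rtol = rtol, atol = 1e-14)
  i <- match(t, sol[, "time"])
  list(dam = sol[i, "m1"] / pools$tbw_dam,
       litter = sol[i, "m2"] / pools$tbw_litter)
}

# cumulative tracer eliminated to the environment up to each time point,
# for the conservation check m1 + m2 + eliminated = D
ode_eliminated <- function(t, dose, rates, rtol = 1e-10) {
  D <- dose$purity * dose$d2o_mass
  deriv <- function(time, m, p) {
    list(c(-(p$k01 + p$k21) * m[1],
           p$k21 * m[1] - p$k02 * m[2],
           p$k01 * m[1] + p$k02 * m[2]))
  }
  times <- sort(unique(c(0, t)))
  sol <- deSolve::lsoda(c(m1 = D, m2 = 0, out = 0), times, deriv,
                        list(k01 = rates$k_out_dam,
                             k21 = rates$k_dam_to_litter,
                             k02 = rates$k_out_litter),
                        rtol = rtol, atol = 1e-14)
  i <- match(t, sol[, "time"])
  list(m1 = sol[i, "m1"], m2 = sol[i, "m2"], out = sol[i, "out"])
}

# brute-force two-sided Mann-Whitney p: enumerate every assignment of the
# pooled values to groups, U from pairwise wins with half-credit for ties
brute_force_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- n1 * (n - n1) / 2
  idx <- utils::combn(n, n1)
  u_all <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  u_obs <- u_of(x, y)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# two-sided Welch p by numeric integration of the t density
welch_p_oracle <- function(x, y) {
  v1 <- var(x) / length(x)
  v2 <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  2 * stats::integrate(function(u) stats::dt(u, df), abs(tstat), Inf,
                       rel.tol = 1e-13)$value
}

# convenience: noiseless series pair from the closed-form model
noiseless_pair <- function(rates, pools, dose,
                           t_plasma = c(3, 24, 48, 72),
                           t_urine = c(24, 48, 72, 96), id = "dam") {
  list(dam = enrichment_series(
         t_plasma, dam_tracer_concentration(t_plasma, dose, rates, pools),
         "dam_plasma", subject_id = id),
       litter = enrichment_series(
         t_urine, litter_tracer_concentration(t_urine, dose, rates, pools),
         "litter_urine", subject_id = id))
}
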