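---
title: "Measuring milk flow by deuterated-water turnover: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring milk flow by deuterated-water turnover: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(d2oflow)
```

## The measurement problem

Milk production in small rodents is traditionally estimated by
weight-suckle-weight (WSW): weigh the litter, let it suckle for a timed bout,
weigh it again. The weight changes involved are tiny relative to litter mass,
pups lose water to urine, feces and evaporation during the bout, and the
resulting estimates are noisy. The isotope-dilution alternative implemented
here injects the dam intravenously with deuterium oxide (D~2~O, heavy water,
5 g per kg body mass) and follows the tracer's washout: part of the dam's
water leaves to the environment, part flows to the litter as milk. Fitting a
compartmental model to the enrichment time courses of dam plasma and pooled
litter urine separates the two routes, and the milk route times the dam's
body-water pool is the milk flow in g/h — an average over the whole sampling
window rather than a single bout.

## The two-compartment model

Dam and litter body water are treated as two well-mixed pools of sizes
$TBW_d$ and $TBW_l$ (grams), each at steady state over the 4-day window, with
three first-order rate constants (h^-1^):

* $K_{01}$ — dam to environment (urine, feces, evaporation),
* $K_{21}$ — dam to litter, the milk route,
* $K_{02}$ — litter to environment.

After a bolus of effective tracer mass $D$ (injected mass times the 0.999
mole-fraction purity), the tracer masses obey

$$\frac{dm_1}{dt} = -(K_{01}+K_{21})\,m_1,\qquad
  \frac{dm_2}{dt} = K_{21}\,m_1 - K_{02}\,m_2,$$

with $m_1(0)=D$, $m_2(0)=0$. Concentrations (g D~2~O per g body water) are
$C_d = m_1/TBW_d$ and $C_l = m_2/TBW_l$, giving the closed forms implemented
in `dam_tracer_concentration()` and `litter_tracer_concentration()`:

$$C_d(t) = \frac{D}{TBW_d}e^{-\lambda_1 t},\qquad
  C_l(t) = \frac{D\,K_{21}\left(e^{-\lambda_1 t}-e^{-K_{02}t}\right)}
               {TBW_l\,(K_{02}-\lambda_1)},\qquad
  \lambda_1 = K_{01}+K_{21}.$$

Two modelling conventions matter. First, $K_{01}$ is environmental loss
*only*; the dam's total elimination is $\lambda_1$, so the log-linear plasma
slope estimates $\lambda_1$, not $K_{01}$. Second, pooled pup urine is taken
to carry the litter's body-water enrichment with no lag — urine is sampled,
body water is modelled, and no delay compartment is introduced between them.
The test suite verifies both closed forms against an independent numerical
integration of the differential system and checks tracer-mass conservation
along all three flows.

At steady state every flow is rate times source pool
(`steady_state_flows()`): milk flow is $R_{21} = K_{21}\,TBW_d$ g/h, dam
intake balances $R_{01}+R_{21}$, and the litter's non-milk intake is
$R_{20} = R_{02}-R_{21}$. $R_{20}<0$ is reported with a warning rather than
an error: suckling pups store water as they grow, so a mildly negative
balance is expected and is exactly the place where the steady-state
assumption bends.

## Total body water by dilution

`estimate_tbw()` regresses log plasma concentration on time, exponentiates
the intercept to the concentration the dose would have had at $t=0$ if
mixing were instantaneous, and divides: $TBW_d = D / C(0)$. The intercept's
standard error propagates to the pool by the delta method
($\mathrm{se}(TBW_d)=TBW_d\cdot\mathrm{se}(b_0)$, since the pool is
$De^{-b_0}$). Dilution-based pools overestimate desiccation values by
roughly 15% — deuterium exchanges with non-aqueous hydrogen, the sampling
window is short, and lactation itself raises body water — and this package
deliberately does not correct for that: the milk-flow comparison inherits
the same convention as the method it implements.

## The weighted fit

`d2o_fit()` is a two-stage estimator, matching the protocol in which the
model has three unknowns:

1. $TBW_d$ is fixed at the dilution estimate (stage one).
2. $K_{01}, K_{21}, K_{02}$ are fitted jointly to the plasma and urine
   series by Levenberg–Marquardt least squares on relative residuals
   $(y_i-\hat y_i)/(cv\,\hat y_i)$, i.e. a constant-CV error model whose
   weights follow the current predictions — the fractional-standard-deviation
   weighting customary for tracer enrichment data. The default
   $cv = 0.01$ reflects the ~1% relative error of FTIR enrichment
   determination.

$TBW_l$ is fixed at litter mass × 0.76 (the rounded combined-group median
body-water fraction) because the urine curve's amplitude needs a scale.
Freeing it (`d2o_control(free_tbw_litter = TRUE)`) is provided as a
sensitivity mode, but note the structural fact verified in the tests: the
urine amplitude identifies only the ratio $K_{21}/TBW_l$, so with $TBW_l$
free the split of $\lambda_1$ into $K_{01}$ and $K_{21}$ sits on a ridge.
That non-identifiability is precisely why the litter pool must be fixed from
an external measurement (litter mass) in this design. Co-fitting $TBW_d$
(`fit_tbw_dam = TRUE`) is harmless by contrast — the plasma amplitude
identifies it — and serves as a cross-check on the two-stage convention.

Numerical choices:

* starting values $K_{01}=\ln 2/24$, $K_{21}=0.01$, $K_{02}=0.02$ h^-1^,
  bracketing reported rodent estimates; on failure a multiplicative
  multi-start grid $\{0.3,1,3\}^3$ is tried and the best converged fit kept;
* box constraints $[10^{-5},1]$ h^-1^ on all rates — physiologic turnover
  cannot leave that range, and the bounds prevent sign flips; a parameter
  landing on a bound triggers a warning;
* the exponential difference in the litter curve is evaluated through
  `expm1`, and within $10^{-12}$ relative of the degeneracy
  $K_{02}=\lambda_1$ the analytic limit $D K_{21} t e^{-\lambda_1 t}/TBW_l$
  is used, so the curve is accurate arbitrarily close to equal rates;
* litter samples at $t=0$ carry no information (the model value is
  identically zero and the relative weight undefined) and are dropped with a
  message;
* parameter covariance is $\hat\sigma^2 (J^\top J)^{-1}$ with $J$ the
  Jacobian of the weighted residuals and
  $\hat\sigma^2 = \mathrm{SSR}_w/(n-p)$; CVs are $100\cdot sd/|\hat\theta|$.
  Non-convergence yields a flagged result (`converged = FALSE`) rather than
  an exception, so one refractory dam cannot abort a study analysis.

```{r fit-example}
truth <- kinetic_rates(0.012, 0.0122, 0.02)
pools <- water_pools(337.7 * 0.769, 134)
dose <- d2o_dose(5 * 337.7 / 1000, 337.7)
tp <- c(3, 24, 48, 72); tu <- c(24, 48, 72, 96)
dam <- enrichment_series(tp, dam_tracer_concentration(tp, dose, truth, pools),
                         "dam_plasma")
lit <- enrichment_series(tu, litter_tracer_concentration(tu, dose, truth, pools),
                         "litter_urine")
summary(d2o_fit(dam, lit, dose, tbw_litter = 134))
```

## Group statistics

Kinetic and growth endpoints come in groups of 4–6 animals, far too small
for normal-theory tests, so `mw_exact_test()` enumerates all
$\binom{n_1+n_2}{n_1}$ assignments of the pooled values and counts those at
least as extreme as observed (U from mid-ranks; the enumeration handles ties
exactly, which base R's exact `wilcox.test` declines to do). A useful
consequence made explicit in the tests: at $n=4$ vs $5$, complete separation
of the two groups gives the smallest achievable two-sided level,
$2/126\approx0.016$. Above a pooled size of 25 the test falls back to the
tie-corrected normal approximation and says so in its method label.

WSW endpoints have more observations and use `welch_t_test()` (unequal
variances, Welch–Satterthwaite df). The replication unit is the litter:
flows are per dam, and per-pup weighings are summed into litter sessions on
ingest (`aggregate_pup_records()`). Small-sample endpoints are summarised as
median with quartiles by linear interpolation (`stats::quantile` type 7 —
conventions differ between software, so the choice is stated) plus
[min; max]. Day-by-day tests are reported raw, with no multiple-testing
correction, matching the reporting convention of the protocol this package
implements.

## The synthetic-study generator

`generate_study()` exists so the whole pipeline is testable with known
ground truth. Its defaults are the reference study conditions: NP (normal
protein) n = 4 and LP (low protein) n = 5 dams; median dam masses 337.7 and
308.3 g; body-water fractions 0.769 and 0.729; transfer medians 0.01223 and
0.00980 h^-1^; a 5 g/kg dose at 0.999 purity; plasma sampling at 3/24/48/72 h
and urine at 24/48/72/96 h; 1% multiplicative measurement noise truncated at
zero (instrument error is quoted as a percentage); a 155 ppm
natural-abundance baseline that is added to the true curve before noising
and subtracted again afterwards, exercising the same correction path real
data take; litters of 8 pups; and 1 h WSW sessions on postnatal days 11–14.

Values the reference conditions do not state were chosen once and are
assumptions, flagged here deliberately:

* elimination centers $K_{01}=0.012$ and $K_{02}=0.02$ h^-1^ — together with
  the transfer median these give a dam water half-life near 28 h, which
  keeps every scheduled sample informative;
* between-dam lognormal variability of 10% CV on rates and 5% on masses —
  chosen to span roughly the published [min; max] ranges;
* median pup mass 22 g with pup water fraction 0.76, giving litter pools
  near 134 g;
* WSW weighing noise of 1.2 g per weighing. The 10 mg scale precision is
  negligible; the dominant variance in a real bout is biological
  (bout-to-bout intake variation, excretion), and 1.2 g per weighing yields
  session SDs around 1.7 g/h, the order of the published day-level spreads.

What the generator does **not** emulate: a growing litter pool (pups are
held at near-steady state, the same assumption the analysis itself makes),
day-to-day lactation dynamics within the window, incomplete tracer mixing
before the 3 h sample, and deuterium exchange with non-aqueous hydrogen.
Passing recovery tests on these synthetic studies therefore demonstrates
that the estimator is correct *under the model's own assumptions*; it cannot
certify the model against the real-data biases just listed.
`inject_suckling_losses()` adds one such bias on purpose — unrecorded water
loss during suckling — to demonstrate the WSW method's downward bias with a
known magnitude: a loss rate $L = Fq/(1+q)$ makes the tracer method
overestimate WSW by exactly the fraction $q$.

## Problem sizes

The test suite and the acceptance script work at sizes chosen to make
Monte-Carlo conclusions stable while keeping a full run interactive:
parameter-recovery checks use 50–100 replicate dams at the reference design,
dilution-recovery checks 200 replicates of the four-point plasma schedule,
estimator-unbiasedness checks 1000–4000 simulated weighings, and the
qualitative diet contrast 8–15 full seeded studies. A complete study fit
(9 dams, 8 observations each) takes well under a second.

## Known limitations

* Milk flow equals dam-to-litter *water* flow; milk solids are invisible to
  the tracer, so "milk flow" here is the water component, as in the source
  method.
* The dilution pool overestimates true body water (exchange, short window,
  lactation), and milk flow inherits that scale.
* One transfer constant per dam: the method averages over the sampling
  window and cannot resolve daily variation — the WSW comparator can, which
  is why both are provided.
* The exact test's enumeration is combinatorial; beyond 25 pooled
  observations it switches to the normal approximation, which is flagged
  but is an approximation nonetheless.
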