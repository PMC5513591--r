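# d2oflow

Milk production in lactating rodents, measured without touching a pup:
**d2oflow** implements the deuterated-water (D₂O) turnover method for
estimating a dam's milk flow, together with the classical
weight-suckle-weight (WSW) comparator and the small-sample statistics needed
to compare diet groups. It is aimed at researchers who quantify lactation in
rat or mouse models — for example to test candidate galactologues or the
effect of maternal diet — and who want a reproducible, scriptable
alternative to spreadsheet-and-GUI workflows.

## The method

The dam receives an intravenous bolus of D₂O (5 g/kg). Her body water and
the litter's body water are modelled as two well-mixed pools coupled by
first-order flows:

```
          K01                K21                 K02
  env  <------  dam (TBWd) ------->  litter  ------->  env
                            (milk)   (TBWl)
```

with rate constants in h⁻¹. The tracer obeys

    dm1/dt = -(K01 + K21) m1
    dm2/dt =  K21 m1 - K02 m2

so dam plasma enrichment decays mono-exponentially with rate
λ₁ = K01 + K21, and litter (pooled urine) enrichment follows the
bi-exponential `D·K21·(e^(−λ₁t) − e^(−K02·t)) / (TBWl·(K02 − λ₁))`. The
package:

1. estimates the dam's total body water by isotope dilution,
   `TBWd = dose / C(0)`, from the back-extrapolated log-linear plasma
   intercept (`estimate_tbw()`);
2. fits K01, K21, K02 to the paired plasma/urine series by weighted
   (constant-CV) Levenberg–Marquardt least squares (`d2o_fit()`), with
   covariance-based SDs and CVs;
3. reports **milk flow = K21 × TBWd** in g/h (`milk_flow()`), the average
   dam-to-litter water flow over the sampling window;
4. compares groups with an exact (full-enumeration, tie-safe) Mann-Whitney
   test for the small kinetic samples and a Welch t test for WSW data
   (`mw_exact_test()`, `welch_t_test()`);
5. generates complete synthetic studies with known ground truth
   (`generate_study()`), so the whole pipeline is testable end to end.

## Worked example

Simulate a two-diet study at the reference design (NP = normal protein,
n = 4; LP = isocaloric low protein, n = 5; plasma at 3/24/48/72 h, urine at
24/48/72/96 h, 1% measurement noise) and analyse it:

```r
library(d2oflow)
study <- generate_study(study_config(seed = 42))
exp1 <- run_experiment1(study)
exp1
#> Deuterated-water turnover experiment
#>
#> Converged dams: 9 (0 excluded)
#>
#>   NP (n=4): milk flow median 3.16 g/h [2.41; 3.49]
#>   LP (n=5): milk flow median 2.14 g/h [1.80; 2.73]
#>
#> Exact Mann-Whitney: milk flow p = 0.03175; TBW mass p = 0.01587
```

The NP median milk flow (3.16 g/h) is the group median of per-dam
K21 × TBWd products; the bracketed values are the group range, and the exact
p-values come from enumerating all 126 assignments of the nine dams to the
two diets. Drilling into one dam:

```r
summary(exp1$fits[["NP1"]])
#> Two-compartment D2O turnover fit: NP1
#>
#>                  Estimate Std. Dev.  CV %
#> k_out_dam       0.0113671 0.0002750 2.419
#> k_dam_to_litter 0.0123746 0.0002206 1.783
#> k_out_litter    0.0211173 0.0005441 2.576
#>
#> TBW dam 281.8 g (77.9%), TBW litter 140.1 g
#> Milk flow: 3.488 g/h (sd 0.062, cv 1.8%)
#> Weighted SSR 11.19 on 8 obs (5 df); converged: TRUE
```

This dam transfers water to her litter at 0.0124 h⁻¹; multiplied by her
281.8 g body-water pool that is 3.49 g of milk water per hour, known to
about 2% — the single-digit CVs are what makes the tracer method more
precise than weight-suckle-weight. The WSW comparator and the method
comparison run the same way (`run_experiment2(study$wsw)`,
`compare_methods()`), and `plot(exp1$fits[["NP1"]])` draws the observed and
fitted enrichment curves.

CSV workflows use `read_tracer_csv()` / `read_dose_csv()` / `read_wsw_csv()`
(small synthetic examples ship under `inst/extdata/`), and
`inst/cli/d2oflow.R` wraps the same functions as a command line with
`simulate`, `fit`, `wsw` and `compare` subcommands.

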