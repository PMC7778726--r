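# dexbetpk

Population pharmacokinetics of intramuscular and oral dexamethasone (DEX)
and betamethasone (BET) — the two corticosteroids used for antenatal
treatment of women at risk of preterm delivery — for pharmacometricians
and clinical pharmacologists who need a reusable, tested implementation
of the published model and a way to exercise it without the (undeposited)
clinical data.

## The model

Both drugs follow two-compartment disposition with first-order input from
up to three depots — IM phosphate (*k<sub>aIM</sub>*), oral
(*k<sub>aPO</sub>*, relative bioavailability *F<sub>r</sub>*), and, for
the BET phosphate/acetate suspension, a slow IM acetate depot
(*k<sub>aIMa</sub>*, *F<sub>ra</sub>*) whose hydrolysis controls a
flip-flop terminal phase:

$$V_p \frac{dC_p}{dt} = k_{aIM}A_{IM} + k_{aPO}A_{PO} + k_{aIMa}A_{IMa}
  - (CL + CL_D)\,C_p + CL_D\,C_T, \qquad
  V_T \frac{dC_T}{dt} = CL_D (C_p - C_T),$$

with each depot draining as $dA/dt = -k_a A$, $A(0) = F \cdot \mathrm{Dose}$.
The package evaluates this in closed form (tri-exponential per dose,
superposed), places log-normal inter-individual variability on selected
parameters ($P_i = \theta_P e^{\eta_i}$, $\eta \sim N(0, \Omega)$), uses a
constant log-scale residual error, handles below-LLOQ records by the Beal
M3 censored likelihood, and estimates by Laplace-approximate marginal
likelihood. A synthetic generator reproduces the source study's design
(8 crossover sequences × 6 women, five 6 mg treatments, 17 samples per
period over 96 h, 10-day washout, 0.1 ng/mL LLOQ, BET-PA carryover into
period 2), so the full pipeline — generate, fit, diagnose, simulate — runs
end to end. See the methods vignette
(`vignettes/popkinetics-methods.Rmd`) for assumptions, numerics and
limitations.

## A worked example

Typical-value kinetics and the descriptors for the BET phosphate/acetate
suspension:

```r
library(dexbetpk)
d <- disposition_constants(dex_typical())
log(2) / d$beta            # DEX terminal disposition half-life: 7.31 h
secondary_descriptors(bet_typical(), "C")
#>   treatment     label     cmax tmax auc_0_96  auc_inf t_half_95_96      mrt
#> 1         C BET-PA IM 35.29377    3  672.895 917.1429      93.2747 83.31265
#>     vss cl_per_kg vss_per_kg
#> 1 72.44 0.1047535   1.275352
```

Reading: a 6 mg BET-PA dose peaks at 35.3 ng/mL around 3 h, delivers
673 ng·h/mL over 96 h (917 to infinity), and declines with a ~93 h
apparent terminal half-life — absorption-limited (the acetate depot's
absorption half-life is `log(2)/0.00638` ≈ 109 h), not
elimination-limited. Vss/F is 72.4 L, i.e. 1.28 L/kg at the study's mean
56.8 kg body weight.

Simulate a reduced synthetic study and refit it:

```r
study <- generate_study(design = study_design(n_per_sequence = 2), seed = 42)
fit <- pk_fit(drug_dataset(study, "DEX"), "DEX")
summary(fit)
#>  parameter estimate rse_pct  omega2 omega2_rse_pct cv_pct
#>         cl   9.1600   6.657 0.01474          43.71  12.19
#>         vp  49.8300   9.282      NA             NA     NA
#>        cld   0.5548  38.530      NA             NA     NA
#>         vt   4.9040  24.220      NA             NA     NA
#>      ka_im   0.4995  16.220 0.02899         119.30  17.15
#>      ka_po   0.6903  18.540 0.15290          59.42  40.64
#>         fr   0.9733   7.521      NA             NA     NA
#>     sigma2   0.0461  12.360      NA             NA     NA
```

The 16-subject refit lands near the generating typical values (CL/F 9.16
vs 9.29 L/h, Vp/F 49.8 vs 51.3 L) with IIV reported as CV%; `coef()`,
`vcov()`, `logLik()`, `predict()` (population or empirical-Bayes
individual), `residuals()`, `simulate()` and `plot()` methods behave as
for other fitted-model objects, and `vpc()` / `regimen_metrics()` build
visual predictive checks and WHO dosing-regimen simulations
(`who_regimens()`).

A command-line wrapper over the same functions is installed at
`inst/scripts/dexbetpk-cli.R` (subcommands `simulate-study`, `fit`,
`vpc`, `regimen-sim`, `secondary`).

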