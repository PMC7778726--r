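---
title: "Population pharmacokinetics of dexamethasone and betamethasone: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of dexamethasone and betamethasone: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dexbetpk)
```

## The problem

Antenatal corticosteroid treatment exposes women at risk of preterm
delivery to dexamethasone (DEX) or betamethasone (BET), given
intramuscularly as phosphate ester solutions, orally as phosphate tablets,
or (for BET) as a one-to-one phosphate/acetate IM suspension whose acetate
component hydrolyzes slowly at the injection site. This package implements
a population (nonlinear mixed-effects) analysis of single-dose
concentration data from a two-period crossover study in healthy
nonpregnant women: 8 sequences x 6 subjects, five 6 mg treatments (DEX-P
IM/PO, BET-P IM/PO, BET-PA IM), 17 plasma samples per period over 96 h, a
10-day washout, and a 0.1 ng/mL lower limit of quantification (LLOQ).
Because the clinical dataset is not public, the package ships a synthetic
study generator with exactly this structure, so estimation, diagnostics
and simulation are exercisable end to end.

## Structural model

Disposition is two-compartment: central volume $V_p/F$ with clearance
$CL/F$, peripheral volume $V_T/F$ exchanging by distributional clearance
$CL_D/F$ (all apparent, scaled by the unidentified IM bioavailability).
Input is first-order from up to three depots — IM phosphate ($k_{aIM}$),
oral ($k_{aPO}$, relative bioavailability $F_r$), and IM acetate
($k_{aIMa}$, $F_{ra}$; BET only). In micro-constant form
($k_{10} = CL/V_p$, $k_{12} = CL_D/V_p$, $k_{21} = CL_D/V_T$) each dose
contributes a tri-exponential

$$C_p(t) = \frac{F D k_a}{V_p}\left[
  \frac{(k_{21}-\alpha)e^{-\alpha t}}{(k_a-\alpha)(\beta-\alpha)} +
  \frac{(k_{21}-\beta)e^{-\beta t}}{(k_a-\beta)(\alpha-\beta)} +
  \frac{(k_{21}-k_a)e^{-k_a t}}{(\alpha-k_a)(\beta-k_a)}\right],$$

with $\alpha,\beta$ the roots of
$s^2 - (k_{10}+k_{12}+k_{21})s + k_{10}k_{21}$, and profiles superpose
over the dose history by linearity. The closed form is the primary path
(it sits inside the estimation inner loop, compiled); adaptive ODE
integration of the same system is retained in the test suite as an
independent oracle. Units are fixed throughout: doses mg, volumes L,
clearances L/h, concentrations ng/mL, with the mg-to-ug conversion inside
the profile evaluator.

Two numerical choices matter here. An absorption rate numerically equal to
a disposition exponent is a removable singularity of the coefficients; we
nudge $k_a$ by a relative $10^{-7}$ whenever it is within $10^{-9}$ of
$\alpha$ or $\beta$, which keeps the evaluation exact to far better than
the $10^{-6}$ oracle tolerance. And predictions are floored at $10^{-12}$
ng/mL before any logarithm, so pre-first-dose records (always below the
LLOQ) are handled without infinities.

## Random effects, residual error, and BLQ records

Individual parameters are log-normal, $P_i = \theta_P e^{\eta_i}$ with
$\eta \sim N(0,\Omega)$; observed concentrations carry additive normal
error on the log scale with constant variance $\sigma^2$. The published
final models define the defaults: DEX places variability on $CL/F$,
$k_{aIM}$ and $k_{aPO}$ (the central-volume variance estimated at zero and
fixed there), BET on all seven of $CL/F$, $V_p/F$, $k_{aIM}$, $k_{aIMa}$,
$k_{aPO}$, $F_r$, $F_{ra}$ with one covariance term between $CL/F$ and
$V_p/F$.

Records below the LLOQ enter the likelihood by the M3 convention: a BLQ
record contributes the censored-normal probability
$\Phi\!\big((\log \mathrm{LLOQ} - \log \hat C_p)/\sigma\big)$ rather than a
density. With a constant log-scale $\sigma$ the residual model does not
depend on $\eta$, so "with interaction" estimation coincides with plain
Laplace; the package implements plain Laplace and relies on this
equivalence.

## Laplace estimation

For each subject the marginal likelihood is approximated by a second-order
expansion around the joint mode: a damped Newton ascent in $\eta$ (central
finite-difference gradients and Hessians, gradient tolerance $10^{-8}$,
started from $\eta = 0$ or the previous mode), then
$\ell \approx \ell_{\mathrm{joint}}(\hat\eta) + \tfrac{p}{2}\log 2\pi -
\tfrac12 \log\det H$. Random effects that cannot influence a subject's
predictions (an oral absorption rate for an IM-only subject) are excluded
from the inner optimization and marginalized exactly, which is valid
because they are uncorrelated with the active effects in the supported
omega structures; this shrinks most subjects' inner problems to 2-5
dimensions.

The population objective (OFV, $-2\sum_i \ell_i$) is minimized over
log-transformed typical values, a log-Cholesky parameterization of
$\Omega$ (the correlated $CL$-$V_p$ block as a 2x2 Cholesky factor,
independent effects as log standard deviations) and $\log\sigma$, using
PORT (`nlminb`) with warm-started inner modes, followed by a short damped
Newton polish on the numerically differentiated OFV: PORT tends to report
false convergence on this objective with a gradient max-norm around 1,
i.e. a few percent short of the stationary point in the softest Hessian
direction. Standard errors come from half the central-difference OFV
Hessian at the optimum (step $10^{-3}$, chosen above the finite-difference
noise floor of the objective), delta-method mapped to the natural scale;
a non-positive-definite information matrix is flagged, never silently
accepted. Starting values are pooled-curve NCA heuristics (dose/AUC for
clearance, terminal slope for volume, time-to-peak for absorption rates),
deliberately crude: they only need to land in the right basin.

How accurate is the Laplace approximation here? Against mode-centred
adaptive quadrature, the implementation is exact (to ~1e-10) on a
log-linear random-effect fixture where the marginal has a conjugate closed
form, and agrees to 1e-4 on sharp-posterior 1- and 2-eta PK fixtures. At
the study's own sampling richness (17 observations per period,
$\sigma^2 \approx 0.02$-$0.05$) the genuine approximation error is of
order 4e-4 to 4e-3 OFV units per subject — ordinary for Laplace, and
irrelevant to the OFV *differences* used in likelihood-ratio tests.

## The synthetic study generator

`generate_study()` reproduces the trial: 8 sequences (AB, BA, CD, DC, ED,
DE, CE, EC) by default 6 subjects each; treatments per the study's dosing
table (treatment C splits 6 mg into 3 mg phosphate + 3 mg acetate); 17
samples per period at 0 (pre-dose) through 96 h; body weight uniform on
47.0-68.7 kg (only the range is reported; weight is a label, not a
covariate, matching the study's finding of no usable weight correlation);
LLOQ censoring at 0.1 ng/mL with the latent value preserved in an
oracle-only column. Period 2 starts 336 h after the first dose - 4
sampling days plus the 10-day washout; the study description gives the
washout but not the clock time of the next pre-dose sample, and 336 h is
validated by an internal consistency check: with typical BET values the model predicts
0.335 ng/mL of BET remaining at 336 h after a BET-PA dose, matching the
reported 0.35 +/- 0.1 ng/mL residual concentrations seen before period 2.
Sequences CE and EC receive BET in both periods and are kept on a common
clock since the first dose, so that carryover enters the fitted record;
all other subjects are re-zeroed at their dose (the study's convention).
Each subject receiving a drug draws one eta vector per drug; no
cross-drug eta correlation is imposed by default (the observed clearance
correlation was weak, r^2 = 0.252), with a configuration point left for
sensitivity analyses.

What the generator does *not* emulate: dropout and missingness (the real
study lost ~5% of DEX records), assay-level error structure beyond the
constant log-scale variance, demographic covariate effects, and
inter-occasion variability. Passing recovery tests therefore show that
the estimator inverts its own generative model at the study's size and
noise level - not that the model is correct for real data.

## Secondary descriptors and regimen simulation

Model-based descriptors follow the reporting conventions: $C_{max}$ and
$t_{max}$ from an hourly simulation grid to 96 h (a finer grid is
available; on it the typical DEX IM peak is 62.8 ng/mL at 3.3 h); AUC by
exact per-exponential integration (trapezoid only for non-model
profiles); terminal half-life from the 95 and 96 h points (undefined and
flagged if the profile is still rising); $V_{ss}/F = V_p/F + V_T/F$ and
per-kilogram normalization at the 56.8 kg mean body weight. The mean
residence time is computed as $(V_{ss}/F)/(CL/F) + 1/k_a$ - the printed
source formula has clearance over volume and a minus sign, which is
dimensionally inconsistent; the corrected form reproduces the published
values (DEX IM 8.24 h) and the literal form is kept behind an explicit
flag for comparison only. For the phosphate/acetate suspension the
composite absorption rate is the absorbed-fraction-weighted harmonic mean
with weight 1 on the phosphate depot (all bioavailabilities are relative
to IM phosphate, so the reference depot carries weight 1; weighting it by
the *oral* relative bioavailability, as the source text literally prints,
is available through the `weights` argument but not the default). The
cross-drug clearance comparison uses orthogonal (total) least squares
through the centroid, which treats the two clearances symmetrically.

Visual predictive checks bin at the nominal sampling times (sampling is
nominal-time by design, so no binning algorithm is needed), compare
observed 5th/50th/95th percentiles with 95% bands from 500 design
replicates, and handle BLQ values on both sides by the LLOQ/2 convention
with the censored fraction reported per bin; an all-BLQ bin gets no
numeric percentile. Regimen simulation covers the three WHO antenatal
regimens (DEX-P 6 mg IM q12h x4, BET-P 12 mg IM q24h x2, BET-PA 12 mg IM
q24h x2) with 200 subjects by default; bands reflect inter-individual
variability only unless residual error is switched on, since the question
the bands answer is about true concentration dispersion, not assay
scatter.

## Problem sizes and known limitations

The test suite runs the full 48-subject design once per drug for the
recovery check, 20 replicates at 2 subjects per sequence for the
bias/coverage check, 1000 random parameter draws for the closed-form/ODE
equivalence, and 500 VPC replicates; these sizes keep the whole suite
within several minutes of CPU time while leaving each check's conclusion
unchanged at larger sizes.

Limitations worth knowing. The distribution-phase parameters ($CL_D/F$,
$V_T/F$) are weakly identified at this design: the full-design sampling
SD of the DEX $CL_D/F$ estimate is ~13%, so single-realization estimates
can sit 15-20% from the truth with no implementation defect; the
replicate-level bias is below a few percent. Inter-occasion variability
is not implemented (the source analysis tested it by LRT - a 5.5-unit OFV
drop, p = 0.019 - and dropped it from the final model; the LRT machinery
is here, the IOV model variant is not). Covariate modeling,
prediction-corrected VPCs, and estimators beyond Laplace (FOCE, SAEM,
importance sampling) are out of scope.
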