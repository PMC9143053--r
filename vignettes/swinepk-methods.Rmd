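---
title: "Methods: population pharmacokinetics of carprofen in swine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics of carprofen in swine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Carprofen is a non-steroidal anti-inflammatory drug whose kinetics in pigs
are of interest both for veterinary dosing and because the pig is a credible
large-animal model for human anti-inflammatory therapy. The published study
this package operationalizes gave four Yorkshire-Landrace pigs (25–50 kg)
4 mg/kg intravenously and, after a 7-day washout, 4 mg/kg intramuscularly,
with plasma sampled at 0.5 min, 15 min, 30 min and 1, 2, 4, 6, 8 and 24 h
after each dose (plus 48 h after the intramuscular dose). `swinepk`
re-implements the complete analysis chain — structural model,
non-compartmental analysis, population (nonlinear mixed-effects) estimation,
model evaluation, dosing-regimen simulation and the bioanalytical validation
statistics — together with a synthetic-study generator so that every stage is
testable without the original animal data, which were never deposited.

## Structural model

Disposition is linear two-compartment with elimination clearance $CL$ from a
central volume $V_c$, distribution clearance $CL_D$ to a peripheral volume
$V_P$, and (for the intramuscular route) first-order absorption $K_a$ from a
depot holding $F \cdot \mathrm{dose}$. The implementation is closed form: the
micro constants are $k_{10} = CL/V_c$, $k_{12} = CL_D/V_c$,
$k_{21} = CL_D/V_P$; the hybrid rates $\alpha \ge \beta$ are the roots of
$s^2 - (k_{10}+k_{12}+k_{21})s + k_{10}k_{21} = 0$, and the intravenous
bolus response is $C(t) = D\,(A e^{-\alpha t} + B e^{-\beta t})$ with
$A + B = 1/V_c$. The depot route uses the standard three-exponential form
with $C(0) = 0$. Multiple doses superpose because the system is linear.

Units are fixed package-wide — hours, mg, litres, mg/L (numerically µg/mL),
1/h — because every printed table in the source study uses them.

Numerical choices worth knowing:

* **Coincident rates.** If $K_a$ collides with $\alpha$ or $\beta$ within
  1e-9 relative, $K_a$ is perturbed by 1e-6 relative instead of evaluating
  the confluent $t e^{-kt}$ limit. At data noise levels (residual CV ~24%)
  the two are indistinguishable; the perturbation keeps one code path.
* **Intravenous input is an instantaneous bolus.** No infusion duration is
  documented for the study; the first sample at 0.5 min is treated as
  post-bolus.
* **Degenerate one-compartment limit.** $CL_D = 0$ is accepted; the
  vanishing root carries zero weight and the profile collapses to
  $C = (D/V_c) e^{-k_{10} t}$ exactly.
* **Availability applies to the depot route only**; intravenous doses have
  unit availability by definition.

At the published parameters the model is strongly two-phase in an unusual
way: $CL_D$ (127 L/h) is ~500-fold larger than $CL$ (0.255 L/h), so
distribution equilibrates within minutes ($\alpha \approx 68\,h^{-1}$,
half-life ~36 s) while elimination is very slow
($\beta \approx 0.0265\,h^{-1}$, terminal half-life ~26 h). Only the 0.5-min
sample sees the distribution phase at all, which is why $CL_D$ and $V_P$
carry very large uncertainty everywhere in this package (and in the source
study, where $V_P$ was reported with 92% relative standard error) while
$CL$, $K_a$, $F$ and the residual error are well identified.

## The synthetic world

`generate_study()` emulates the study design as stated: `n_subjects` animals
with bodyweight uniform on 25–50 kg, 4 mg/kg on both occasions, the sampling
grid above with the "0.5 min" first sample taken literally (1/120 h — the
design is configurable precisely because that reading is a choice), and a
7-day washout which is treated as complete (times restart at each dose; the
published terminal half-life makes carryover ~1% and the study itself
asserts none). Pre-dose blanks are emitted as flagged rows and excluded from
analysis.

The generative model is the published final parameter table: typical values
(CL 0.255 L/h, Vc 7.11 L, CLD 127 L/h, VP 2.51 L, Ka 0.471 1/h, F 90.8%),
log-normal between-animal variability with one $\eta$ per animal shared
across both occasions (the study modelled no inter-occasion variability),
estimated variabilities 33.17/33.47/95.86% CV on CL/Vc/Ka and the fixed 15%
CV ($\omega^2 = 0.0225$) elsewhere, and proportional residual error with
24.23% CV. Draws yielding non-positive concentrations are redrawn, matching
the study's statement that no observation fell below the quantification
limit; at 24% CV this affects essentially nothing. One knowingly unphysical
consequence of the stated world is that individual availabilities
$F_i = 0.908\,e^{\eta}$ can exceed 1 for ~25% of simulated animals; this is
retained because it is what the exponential-variability model states.

That choice has a measurable, understood consequence. The estimation model
bounds availability below 1 (logit scale), so animals simulated with
$F_i > 1$ are unreachable; the fit compensates by lowering those animals'
clearance (raising their intramuscular exposure the only way it can), which
depresses the typical clearance by ~5–10% and inflates its apparent
between-animal variability by ~10–20% at any study size. This is an
asymptotic model-mismatch bias of the stated world, not an optimizer
defect — removing the variability on $F$ alone removes it (clearance then
recovers to within 1%), which the test suite demonstrates. The recovery
acceptance bands (15% on clearance, 25% on its variability) absorb it. The
bootstrap-calibration checks are run in the correctly-specified variant of
the world (no variability on $F$) precisely so that they measure the
bootstrap, not this bias.

What a green test does *not* establish: the generator reproduces the
statistical structure the analysis assumes, not features of real data it
does not model — assay drift, anesthesia effects on clearance, BLQ
censoring, inter-occasion variability, or model misspecification of any
kind. Recovery tests are internal-consistency checks of the estimator, not
evidence about pigs.

## Non-compartmental analysis

Per profile: $\lambda_z$ by ordinary least squares of log concentration on
time over terminal windows; the window (ending at the last sample, at least
3 points, starting strictly after the observed peak) maximizes adjusted
$R^2$, with ties within 1e-4 going to the longer window — the source names
no rule, so the package mirrors common automated practice and is
deterministic. Areas use the linear/log trapezoid: linear on non-decreasing
(or non-positive) segments, logarithmic on strictly decreasing ones; the
first-moment curve uses the matching exponential-segment formula. The tail
beyond the last sample is `C_pred/λz` (and
`C_pred·t_last/λz + C_pred/λz²` for the first moment), with `C_pred`
taken from the regression line, and `t½ = ln 2 / λz` (the 0.693 shorthand is
display-only). Clearance, `Vss = CL·MRT`, `Vdarea = D/(AUC·λz)` and the
back-extrapolated initial volume are intravenous-only; availability is the
dose-normalized AUC ratio. The peak ties break to the earliest time.

A deliberate property of this design, reproduced by the tests: with the
study's own sampling (last IV sample at 24 h, under one terminal half-life)
the extrapolated area fraction exceeds 30–60%, which is exactly the caveat
the source study attaches to its NCA table and the reason the population
analysis is the primary method.

## Population estimation

Individual parameters live on a transformed scale
$\phi = (\log CL, \log V_c, \log CL_D, \log V_P, \log K_a, \mathrm{logit}F)$,
so positivity and the (0,1) bound hold by construction and the population
means enter linearly in the random effects — the intent of linear
MU-referencing in EM-based estimators, honored here by the parameterization
rather than as a separate feature. Variability is exponential
(diagonal $\Omega$ by default); the entries without estimated variability
are fixed at $\omega^2 = 0.0225$ and never touched by the optimizer (a
tested contract). Residual error is proportional in the final model;
additive and combined variants exist for the model-comparison step only. A
full covariance block across the estimated effects is available but off by
default — the source analysis abandoned it for instability, and the option
exists to reproduce that comparison.

The default estimator is SAEM: a Metropolis-within-Gibbs E-step (one
independent proposal from the current population distribution, two adaptive
joint random-walk passes, one adaptive componentwise pass per iteration, all
vectorized across subjects) and closed-form M-steps in smoothed sufficient
statistics, with step size 1 for the exploration phase and $1/k^{0.7}$
afterwards; variance updates are annealed during exploration to avoid early
collapse. Initial values are data-derived: curve stripping of the
geometric-mean intravenous profile, peak-time-based $K_a$, AUC-ratio $F$,
then a naive-pooled log-least-squares polish of all six parameters (the
sparse design leaves at most one distribution-phase point, so stripping
alone cannot place $CL_D$). Because observations end at 48 h — under two
terminal half-lives — the likelihood has a second, spurious basin in which
elimination vanishes and a large, slowly-equilibrating peripheral
compartment mimics the observed decline; the pooled objective sometimes
prefers it. The initializer therefore scores a small candidate set (the
pooled solution, a clearance-anchored stripping solution with
$CL = D/\mathrm{AUC}_\infty$, and a fast-equilibration reading built from
the first-sample volume and the moment-curve $V_{ss}$) by the hierarchical
Laplace deviance, which separates the basins decisively, and starts SAEM
from the winner.

The objective function reported (`mofv`) is $-2\log$ marginal likelihood by
importance sampling at the final estimates: per subject, 1000 draws from a
multivariate $t_4$ proposal centred at the empirical-Bayes mode with the
inverse joint-Hessian scale. It is seeded and reproducible; across seeds it
jitters by well under one unit, which is the resolution the $\chi^2$
comparison rule needs. Nested models are compared at $p < 0.005$
(ΔMOFV 7.879 for one degree of freedom); non-nested models by
AIC = MOFV + 2·parameters.

A deterministic Laplace estimator backs the stochastic one: per-subject
inner optimization of the joint density with batched finite-difference
gradients and Hessians, and an outer quasi-Newton loop. It provides (i) a
fallback fitting method, (ii) the observed-information standard errors
(finite-difference Hessian of the Laplace deviance over all estimated
parameters; relative standard errors on the natural scale by the delta
method), and (iii) the eigenvalue-ratio condition number of the fixed-effect
correlation matrix. Because SAEM estimates carry Monte-Carlo noise, the
deviance Hessian evaluated there is occasionally indefinite in near-flat
directions (the $CL_D$/$V_P$ axis); it is then eigenvalue-clamped and
flagged rather than discarded.

Empirical-Bayes shrinkage is `100(1 − SD(EBE)/ω)` per estimated effect and
`100(1 − SD(IWRES))` for the residual. Conditional weighted residuals use
the FOCE-style linearization around the empirical-Bayes mode (the
linearization point is not stated in the source; the EBE-conditional choice
is documented here and tested against its closed form on a linear toy
model). Bodyweight enters, when enabled, as a power covariate on flows
(exponent 0.75) and volumes (exponent 1) referenced to 70 kg, or with both
exponents estimated by the closed-form grouped regression inside the M-step;
as in the source analysis, the default pipeline excludes it.

## Model evaluation

The visual predictive check simulates replicate data sets (default 1000) on
the original design and compares observed percentiles per route and nominal
time with confidence bands of the simulated percentiles. The sparse fixed
schedule makes the nominal times themselves the bins. The interval is
parameterized (`pi_level`, default 0.95; band level 0.975) because the
source text states both a 95% and a 90% interval in different places —
both are producible, neither is guessed to be "the" one.

The bootstrap resamples subjects with replacement and refits. Refits default
to short-chain SAEM rather than Laplace: with the E-step vectorized across
subjects, SAEM is the faster engine in this implementation, which reverses
the usual speed argument; Laplace remains available through `method` (and is
what the identity test uses, because it is exactly deterministic). Failed
refits are counted and excluded; a success rate under 50% flags the result.

## Dosing simulation

Multiple-dose profiles use the running-sum recurrence of the single-dose
closed form. Steady state is declared when successive troughs change by
under 0.1%. Note a consequence of the 26-h terminal half-life: at τ = 8 h
and longer the detector converges within 30 intervals, but at τ = 4 h the
0.1% criterion mathematically requires ~45 intervals — the tests document
this rather than loosening the criterion. "Total removal" for the washout
utility is operationalized as 99.9% eliminated (configurable), computed by
root-finding on the closed-form cumulative AUC; at the published parameters
the intramuscular washout is ~12 days, consistent with the study's
recommendation of a 15-day margin.

Regimen selection against the 15–20 µg/mL window considered therapeutic in
other species is a transparent composite, in order: largest fraction of the
steady-state interval inside the window (rounded to 2 decimals so
numerically indistinguishable candidates tie), fewest administrations per
day, lowest dose. The published choice (4 mg/kg q24h intramuscular;
3 mg/kg q24h intravenous) falls out of this rule at the published parameters
because the steady-state average, $F \cdot \mathrm{rate}/CL$, lands inside
the window for exactly those candidates.

## Bioanalytical statistics

Linearity (least squares, pass at $R^2 > 0.99$), repeatability (sample SD
with the $n-1$ denominator — the source does not state the convention; its
printed values are consistent with either at 2 decimals), accuracy
(back-calculated recovery with the 80–120% band) and signal-to-noise limits
(LOD at S/N 3, LOQ at S/N 10 under a linear response). The tissue comparison
is an exact two-sided Mann-Whitney U test: mid-ranks for ties, full
enumeration of assignments for combined n ≤ 12, doubled smaller tail capped
at 1; a continuity- and tie-corrected normal approximation takes over for
larger samples. Two printed-value notes found while freezing the test
expectations: one accuracy-table RSD prints as 0.96 where the printed
mean/SD give 0.9546 (→ 0.95), and the per-kg steady-state volume prints as
0.306 L/kg where 9.62/31.5 = 0.3054; the package computes, it does not
reconcile.

## Acceptance surface and its limits

The original four-animal data set is unavailable, so the package's
acceptance criterion is parameter recovery: 200 virtual pigs simulated under
the stated design from the published generative values, re-estimated with
the package's SAEM fitter, with CL, F within 15%, Ka within 25%, residual
CV within 20% and CL variability within 25% of the generative values. The
published per-animal NCA means (and the figure-level curves) are from the
real animals and are not desk-reproducible; they are deliberately not
asserted. $CL_D$ and $V_P$ are recovered only to order of magnitude, for the
identifiability reason above — faithful to the published uncertainty, and
the reason they are not acceptance targets.
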