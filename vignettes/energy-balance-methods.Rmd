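---
title: "Energy-balance models of rat body composition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-balance models of rat body composition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratabolic)
```

This vignette explains the models the package implements, the assumptions
they rest on, the numerical choices made where the design was genuinely
open, and what the synthetic-data generator does and does not emulate.

## The two-compartment partition model

Body mass is split into fat mass $FM$ and fat-free mass $FFM$ (grams), and
the only exogenous driver is daily food-intake energy $I(t)$ (kcal/day).
Whatever energy is not expended is deposited:

$$\frac{dFM}{dt} = \frac{I - E}{\rho_{FM} + \alpha\,\rho_{FFM}},
\qquad \frac{dFFM}{dt} = \alpha\,\frac{dFM}{dt},$$

where $\rho_{FM} > \rho_{FFM} > 0$ are tissue energy densities (kcal/g) and
$\alpha = dFFM/dFM$ is the energy-partition slope. With constant $\alpha$
every solution is confined to the line
$FFM = FFM_0 + \alpha\,(FM - FM_0)$ through its initial condition — the
central structural assumption, and (in short drug studies) the central
limitation. $\alpha$ is the local linearisation of the empirical Forbes-type
FFM–FM relation; pooled rat restriction-study body composition shows no
clear curvature, so a constant slope fitted by total least squares is used.

Energy expenditure is

$$E = K + \beta\,(I - I_0) + (\lambda + \gamma_{FM})\,FM +
(\lambda + \gamma_{FFM})\,FFM + \eta_{FM}\frac{dFM}{dt} +
\eta_{FFM}\frac{dFFM}{dt},$$

with basal offset $K$ (kcal/day, may be negative), diet-induced thermogenesis
fraction $\beta$ applied to intake above baseline $I_0$, physical-activity
coefficient $\lambda$ (kcal/g/day, applied to every gram of body weight),
mass-specific metabolic rates $\gamma$, and deposition costs $\eta$ (kcal per
gram of tissue laid down). During a treatment window a Hill dose-response
term $d(X) = D_0 + D_{max} X/(ED_{50}+X)$ is added; $D_0$ captures handling
stress and therefore applies to the vehicle arm too, and the whole term
vanishes outside the window.

**Resolving the implicit expenditure equation.** The derivative terms in $E$
themselves contain $E$ through the partition equations. Rather than iterating
inside the ODE right-hand side, the equation is solved algebraically (it is
linear in $E$): with $E_0$ collecting all terms free of derivatives and
$c = (\eta_{FM} + \alpha\,\eta_{FFM})/(\rho_{FM} + \alpha\,\rho_{FFM})$,

$$E = \frac{E_0 + c\,I}{1 + c}.$$

The test suite verifies this closed form against a damped fixed-point
iteration to $10^{-10}$ kcal/day on random parameter draws.

## The α-free model

Differentiating the mass balance $BW = FM + FFM$ and substituting into the
energy balance $I - E = \rho_{FM}\,dFM/dt + \rho_{FFM}\,dFFM/dt$ eliminates
the partition assumption in favour of a measured body-weight input:

$$(\rho_{FM} - \rho_{FFM})\,\frac{dFM}{dt} = I - E - \rho_{FFM}\,\frac{dBW}{dt},
\qquad FFM(t) = BW(t) - FM(t).$$

The expenditure equation is again implicit and again linear in $E$; with
$c' = (\eta_{FM} - \eta_{FFM})/(\rho_{FM} - \rho_{FFM})$,
$E = (E_0 + \eta_{FFM} B' + c'(I - \rho_{FFM} B'))/(1 + c')$ where
$B' = dBW/dt$. The model degenerates when $\rho_{FM} = \rho_{FFM}$ (the
parameter constructor forbids it). The instantaneous partition ratio

$$\frac{dFFM}{dFM} = -\,\frac{I - E - \rho_{FM}\,B'}{I - E - \rho_{FFM}\,B'}$$

is reported along every trajectory; where fat mass is stationary (denominator
near zero, threshold $10^{-8}$ kcal/day) it is reported as `NA` rather than
an infinity.

The two models are algebraically consistent: feeding a partition-model
body-weight curve back into the α-free model must reproduce the partition
model's fat mass. This round-trip is the α-free module's primary oracle; the
package checks it to 0.1 g over 45-day horizons across random parameter
draws, using `bw_from_trajectory()` — an exact piecewise-cubic Hermite
representation whose nodal derivatives come from the model right-hand side
itself (computed per interval, so intake discontinuities at day boundaries
keep the correct one-sided derivatives).

## Body-weight smoothing

For real (noisy) weights the α-free model needs a smooth, differentiable
input. `fit_bw_spline()` implements the natural cubic smoothing spline in the
classical convention

$$\min_f\; p \sum_i (y_i - f(x_i))^2 + (1-p) \int f''(t)^2\,dt,$$

so $p = 0$ is the least-squares line and $p = 1$ the natural interpolant,
with $p = 0.2$ as the working default for daily arm-mean weights. This
convention is **not** numerically interchangeable with other ecosystems'
smoothing parameters (e.g. `stats::smooth.spline`'s `spar`); to transfer a
setting across conventions, match effective degrees of freedom rather than
copying the number. Outside the knot range the spline extrapolates linearly,
consistent with its natural boundary conditions. Splines are fitted to
per-arm daily mean body weight, matching the mean-data objective.

## Calibration

Fitting compares simulations to arm-mean data with

$$\mathrm{Error} = \frac{\sum (BW - \widehat{BW})^2}{N_{BW}} +
\frac{\sum (FM - \widehat{FM})^2}{N_{FM}}$$

(units g²), body weight on every measurement day, fat mass only on the DXA
days; fat-free mass never enters directly because DXA studies derive it as
$\widehat{BW} - \widehat{FM}$. Multi-arm studies sum the value over arms with
equal weight — one joint fitting problem per study. Each arm is initialised
at its first body-composition measurement and simulated to its last.

* **Partition slope α** — total least squares (orthogonal regression) on
  pooled body-composition points, computed from the principal eigenvector of
  the centred second-moment matrix. Degenerate scatter (isotropic, or a
  vertical principal direction) is an error, not a silent answer. A
  brute-force orthogonal-distance search over line angle and offset serves as
  the independent oracle in tests.
* **Metabolic rates** — `kleiber_translate()` carries mouse per-gram rates to
  the rat with the $m^{-1/4}$ per-gram form of the 3/4-power law, using a
  350 g lean-rat reference. The shipped defaults
  ($\gamma_{FM} = 0.01$, $\gamma_{FFM} = 0.1$ kcal/g/day, and the densities
  and deposition costs in `inst/extdata/params_rat.toml`) are literature
  placeholders, clearly labelled for override from study-specific sources.
* **Activity coefficient λ** — λ and $K$ enter expenditure as jointly
  intercept-like terms and cannot be identified simultaneously from BW/FM
  data; `lambda_k_surface()` exposes the diagonal low-error valley (nodes
  within 5 % of the minimum correlate at $|r| > 0.9$). Following the
  restriction-study convention, $K$ is pinned at 0 and λ estimated by Brent
  minimisation on $[0, 0.5]$ kcal/g/day (tolerance $10^{-8}$); a
  one-dimensional smooth problem needs nothing stronger.
* **Drug quartet $(K, D_0, D_{max}, ED_{50})$** — seeded simulated annealing:
  geometric cooling $T_k = 0.95^k\,T_0$ with $T_0$ set to the starting
  objective, 100 temperature levels, 200 Gaussian proposals per level scaled
  to 5 % of each box width, inside bounds $K \in [-100, 100]$,
  $D_0 \in [0, 100]$, $D_{max} \in [0, 200]$ kcal/day,
  $ED_{50} \in [0.5, 100]$ mg/kg, followed by two Nelder–Mead polish
  restarts. The objective is smooth in four dimensions, so any reasonable
  schedule reaches the same basin and the polish makes the reported optimum
  schedule-independent; the same seed reproduces the fit bitwise. Dose and
  $ED_{50}$ are both in mg/kg. The washout and pre-treatment phases separate
  $K$ from $D_0$; $ED_{50}$ is the least identifiable of the four under
  observation noise, as the dose-response correlation between $D_{max}$ and
  $ED_{50}$ predicts.
* **α-free calibration** follows the identical protocol (λ from the
  restriction study with $K = 0$, quartet from the dosed study), with per-arm
  splined body weight as input. Where the original workflow was ambiguous
  about whether the α-free refit re-estimates λ, the package re-runs the same
  two-stage protocol for both models.

Baseline intake $I_0$ is study-specific: the restriction design establishes
it as the mean of the four pre-study measurement days; the drug design uses
the day-0 measurement. Missing intake between the first body-composition day
and intervention start is filled with $I_0$; missing intake after the last
measured day is carried forward from the final measurement; interior gaps
(which neither design produces) are carried forward with a warning.

## Numerical integration

Fixed-step classical RK4 at 10 steps/day, restarted at every day boundary so
the piecewise-constant intake (and the per-day drug effect) never straddles a
step. A fixed-step scheme was chosen over adaptive solvers deliberately:
results are bit-reproducible across platforms and the daily intake
discontinuities are respected exactly rather than smoothed over. At this step
size the α-free round-trip agrees to well under 0.1 g over 45 days, far below
measurement noise. The simulator also accumulates $\int (I-E)\,dt$ with the
same RK4 stage weights, making the energy-bookkeeping identity
$\rho_{FM}\Delta FM + \rho_{FFM}\Delta FFM = \int (I-E)\,dt$ hold to
rounding error for the partition model — a genuine consistency check between
the right-hand side and the expenditure function, not a tautology. For the
α-free model the same identity holds to about $10^{-3}$ relative on
schedules with daily intake jumps (the stage at a day boundary sees the
right-limit spline derivative); its exact structural invariant is instead
the mass balance $FM + FFM = BW$, which holds identically. Fat mass is
floored at 0 g with a warning; the studies modelled never approach this
regime.

## The synthetic-data generator

`generate_study()` emulates the two study designs: caloric restriction
(ad-libitum control plus 10/20/30/40 % restriction of baseline intake for
26 days; DXA at days −3, 12, 22; daily weights through day 26; baseline
intake established over four pre-study days; baseline weight
$\mathcal N(640, 62^2)$ g; $n = 10$/arm) and the CB1-antagonist design
(vehicle plus 3/10/30 mg/kg for 23 daily doses with a 15-day washout; DXA at
−3, 24, 42; daily measurements through day 37; baseline weight
$\mathcal N(695, 75^2)$ g; $n$ = 9 vehicle / 10 dosed). Generating-parameter
defaults are the fitted values of the corresponding analyses
(λ = 0.087 kcal/g/day; for the drug design $K = -16.6$, $D_0 = 13$,
$D_{max} = 37$ kcal/day, $ED_{50} = 10$ mg/kg), so parameter recovery runs
probe exactly those study conditions.

Choices the designs do not pin down, made once and documented here:

* **Baseline composition.** Baseline fat and fat-free mass lie on the
  population partition line (slope α) anchored at a mean fat fraction of
  0.30 of the design's mean weight, with composition scatter at fixed body
  weight of SD `fm_frac_sd` × BW (default 0.03). Drawing fat fraction
  independently of size would put the population off every partition line
  and make the pooled TLS stage inconsistent with the generating model even
  without noise; anchoring to the line gives pooled body-composition data
  the structure the constant-α analysis assumes, which is the generator's
  purpose.
* **Baseline intake** is each animal's own expenditure equilibrium (so
  control arms are weight-stable up to jitter), times a between-animal
  lognormal-style fraction (SD 3 %). Restricted rations are exact fractions
  of the animal's baseline; ad-libitum intake gets day-to-day lognormal
  jitter (CV 4 %).
* **Drug-arm intake suppression** (measured, not modelled, in real studies —
  the shape here is a synthesis choice): a dose-dependent dip, Hill in dose
  with the drug's $ED_{50}$, maximal (35 % at saturating dose) in week one
  and decaying with a 7-day time constant to a 30 % tolerance plateau, with
  full recovery during washout.
* **Between-animal physiology**: basal offset SD 5 kcal/day.
* **Observation noise**: body weight SD 5 g, fat mass SD 8 g — chosen so
  synthetic SEMs resemble published error-bar scales qualitatively;
  explicitly not anchored to any reported variance.

The generator reproduces measurement-era realism only partially: no
within-day intake patterning (dark/light cycle), no extracellular-water
compartment, no pharmacokinetics (dose acts directly through the Hill term),
and Gaussian noise throughout. Passing recovery tests therefore demonstrates
the estimation machinery under the assumed error model, not robustness to
physiological misspecification — with one deliberate exception:
`generate_alpha_violating_study()` integrates the generator with a time- and
dose-dependent partition slope, producing worlds where the constant-α model
can match body weight while misfitting composition (the drug-study failure
mode) and the α-free model fits both. The end-to-end comparison (constant-α
FM objective more than 3× the α-free FM objective) is part of the acceptance
suite.

## Problem sizes and reproducibility

The recovery experiments use the full study designs (5 restriction arms ×
10 animals; 4 dose arms × 9–10 animals) over their native horizons
([−3, 22] and [−3, 42] days). Noisy-recovery summaries use 25 seeds per
experiment with observation noise at the defaults above and between-animal
variability off — the stated perturbation is measurement error, and the
median relative error is the reported statistic. The partition-violation
comparison uses 5 seeds. All stochastic stages (generation, annealing) are
driven by explicit integer seeds, and `run_full_analysis()` is
bit-reproducible given (config, seed).

## Known limitations

* Constant-α and α-free models share the expenditure form; errors in the
  placeholder constants (ρ, η, β, γ) are absorbed into λ and K rather than
  detected.
* The α-free model inherits whatever bias the body-weight spline has at the
  chosen smoothing level; no uncertainty from smoothing is propagated into
  the fat-mass estimates.
* Point estimates only — no confidence intervals or bootstrap.
* The identifiability valley means λ (and K) values are meaningful only
  under the stated pinning convention, not as free-standing physiology.
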