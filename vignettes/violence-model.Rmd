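---
title: "Modelling gender-segregated violence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gender-segregated violence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(violdyn)
```

## The model and its assumptions

`violdyn` treats severe interpersonal violence as a transmission-like
process. The population splits into aggressors $A$, susceptibles $S$, male
victims $V_M$ and female victims $V_F$ (all in millions; non-susceptible
people are assumed not to influence the dynamics and are left out). The
base system is

$$
\begin{aligned}
\dot A &= r_A A\,(1 - A/k_A)\\
\dot S &= r_S S\,(1 - S/k_S) - \beta_M A S - \beta_F A S\\
\dot V_M &= \beta_M A S - \alpha_M V_M\\
\dot V_F &= \beta_F A S - \alpha_F V_F.
\end{aligned}
$$

The assumptions that matter:

* **Logistic growth for $A$ and $S$.** Both classes contain both sexes and
  grow toward carrying capacities $k_A$, $k_S$; explicit birth/death is not
  modelled. The aggressor equation is *uncoupled* — aggressors are not
  affected by anyone else. That is a deliberate simplification, and it is
  what makes two-stage estimation possible.
* **Mass action.** Victimization flux is $\beta A S$ under homogeneous
  mixing, exactly as in classical epidemic models. The $\beta$'s carry
  units 1/(million·year): they absorb contact rates and per-contact
  aggression probabilities, which is why their absolute scale is small
  ($10^{-6}$–$10^{-5}$) when $A$ and $S$ are tens of millions.
* **Victims only exit by removal.** $\alpha_M$, $\alpha_F$ are per-capita
  death rates (violent or natural). In the base model nobody returns from
  the victim compartments.

Two nested intervention extensions are activated at a *recovery year*
(a hard switch; the state is handed over exactly, so trajectories are
continuous with a kink): female victims return to $S$ at rate $\gamma_F$,
and — in the complete model — aggressors are rehabilitated into $S$ at rate
$\delta_A$. With $\gamma_F = \delta_A = 0$ all three systems coincide
exactly, which the test suite asserts as an identity.

A consequence worth naming: the transfer terms cancel in column sums
($\dot S + \dot V_F$ is $\gamma_F$-free; $\dot A + \dot S + \dot V_F$ is
also $\delta_A$-free), so the recovery mechanisms move people between
compartments rather than creating or destroying them.

## Parameters

| Parameter | Meaning | Units | Typical (family violence) |
|---|---|---|---|
| $r_A$, $r_S$ | logistic growth rates | 1/year | 0.055 |
| $k_A$, $k_S$ | carrying capacities | millions | 30.3, 61.7 |
| $\beta_F$, $\beta_M$ | victimization interaction rates | 1/(million·year) | 2.8e-5, 3e-6 |
| $\alpha_F$, $\alpha_M$ | victim removal rates | 1/year | 0.35, 0.56 |
| $\gamma_F$ | female victim recovery rate | 1/year | 0 (off) |
| $\delta_A$ | aggressor recovery rate | 1/year | 0 (off) |

All ten live in one `model_params` object so a single parameter set drives
any of the three systems. `family_violence_params()` and
`nonfamily_violence_params()` carry the published point estimates for the
Mexican series under the 20%/40% scenario.

## Data and scenarios

The observed quantity is the annual count of people treated in medical
units, by injury intentionality and sex (2010–2023, bundled as
`incidence_fixture()`; counts are divided by $10^6$ before use). Aggressors
and susceptibles are unobserved; a *scenario* posits them as fixed
percentages of the national population (default 20% and 40%), applied to
the population interpolated at each observation year. The population enters
as sparse census anchors (a config input — the package bakes no national
population into any computation path; `inst/extdata/population_mexico.yaml`
documents the census values) interpolated piecewise-linearly, with linear
extrapolation beyond the last anchor for projection years. Whether the
original analysis interpolated linearly is unknowable from the published
material; linear is the assumption least likely to inject curvature into
the targets.

## Estimation

Stage 1 exploits the uncoupled aggressor equation: its solution is the
logistic closed form, and $(r_A, k_A, A_0)$ are estimated by least squares
on that curve against the aggressor target series — no integration
involved. A constant series is the degenerate logistic: $k_A$ is the
constant, the growth rate is flagged unidentifiable.

Stage 2 freezes $(r_A, k_A, A_0)$ and estimates
$(r_S, k_S, \beta_F, \beta_M, \alpha_F, \alpha_M)$ plus the initial
conditions $(S_0, V_{M0}, V_{F0})$ by bounded Levenberg–Marquardt least
squares (`minpack.lm`) on the integrated trajectory. Choices that were
genuinely open, and how they were settled:

* **Residual composition.** The objective stacks the $S$, $V_M$ and $V_F$
  blocks, each divided by the mean of its own observations
  (`normalization = "mean"`). Without block scaling the susceptible series
  (~50 M) would drown the victim series (~0.1 M and ~0.006 M) a thousandfold;
  with it, each compartment contributes proportionally. Victims-only
  objectives are supported via `residual_blocks` but leave a scale family
  unidentified — rescaling $(S_0, k_S) \mapsto (cS_0, ck_S)$,
  $\beta \mapsto \beta/c$ changes nothing the victim blocks can see — so the
  $S$ block is in by default.
* **Parameter scale.** Rates are optimized on the log scale: the $\beta$'s
  span orders of magnitude and sex-asymmetric data make their ratio, not
  their difference, the meaningful quantity.
* **Initial conditions.** $S_0, V_{M0}, V_{F0}$ move within $[0.25, 4]\times$
  the first observation — enough to absorb early-series noise, not enough to
  let the initial state carry the fit. $A_0$ stays at its stage-1 value
  since nothing in stage 2 feeds back into $A$.
* **Bounds.** Death rates are capped at 1/year (`alpha_max`); without that
  cap, scenarios with strongly unequal aggressor/susceptible percentages
  admit degenerate fits with extreme removal rates. Interaction rates live
  in $[10^{-9}, 10^{-2}]$.
* **Multistart.** One data-driven start (quasi-equilibrium victim balance at
  $\alpha = 0.5$) plus Latin-hypercube draws within bounds, 8 starts by
  default under a fixed seed. The best local optimum wins; integration
  failures during a trial are penalized, not fatal. Fits are bit-for-bit
  reproducible given (config, seed).

Validation holds out 2023: the model is integrated forward from the fitted
state with no refitting, and per-compartment relative errors are reported.
Fit quality across violence types is compared by the RMSE of victim
residuals with each sex block normalized by its own observed mean — the
same scaling as the objective. This matters for the negative control: the
self-inflicted series (where aggressor and victim coincide, violating the
compartment separation) ranks worst under this metric, while a pooled-mean
normalization would let the large female family-violence block dominate
and blur that comparison.

## Equilibria and stability

With $\delta_A = 0$ the aggressors saturate at $k_A$ and the susceptible
equilibrium is closed-form, $S^* = k_S(1 - (\beta_M+\beta_F)k_A/r_S)$
(floored at zero on the extinction branch), giving victim saturation levels
$V_M^* = \beta_M k_A S^*/\alpha_M$ and
$V_F^* = \beta_F k_A S^*/(\alpha_F+\gamma_F)$. The ratio identity
$V_F^*/V_M^* = \beta_F\alpha_M / (\beta_M(\alpha_F+\gamma_F))$ is
independent of the capacities and is the quantity all equality analyses
reduce to. With $\delta_A > 0$, $A^* = \max(0, k_A(1-\delta_A/r_A))$ and
the susceptible steady state solves a scalar quadratic balance; the
implementation brackets the outermost sign change on $[0, 2k_S]$ over a
1000-point scan and bisects to $10^{-12}$ (robustness over elegance — the
closed form is used where it exists, and the two agree exactly in the
reduction case). Stability comes from the analytic $4\times4$ Jacobian;
at the origin the spectrum is $\{r_A, r_S, -\alpha_M, -\alpha_F\}$
(unstable — violence invades), and at the interior equilibrium of the
published parameters all real parts are negative.

Computed from the published family-violence estimates, the saturation
levels are ~146,993 female and ~9,825 male victims — within ~1.6% of the
levels quoted alongside those estimates (145,262 and 9,988). The residual
mismatch is expected: the interaction rates are published to one or two
significant figures, and $V^*$ is linear in $\beta$. The non-family female
level lands ~10% from its quoted value for the same reason ($\beta_F$ there
has a single significant figure), so the package documents rather than
enforces it.

## Recovery projections

`project_with_recovery()` integrates the base model to the recovery year
and the chosen extension afterwards; `sweep_recovery()` maps grids of
$(\gamma_F, \delta_A, \text{recovery year})$ to terminal victim levels and
the minimum gap $V_F/V_M$. Two equality criteria are reported, because
"equality" is otherwise underspecified: finite-horizon ($V_F(t) \le V_M(t)$
at any point within a window, default 10 years, after the switch — found by
bisection on $\gamma_F/\alpha_F$) and asymptotic (the closed form
$\gamma_F^* = \alpha_M\beta_F/\beta_M - \alpha_F$ from the ratio identity,
cross-checked by long-run integration either side of $\gamma_F^*$). Under
the published family-violence parameters both land near
$\gamma_F \approx 14\,\alpha_F$: female-victim recovery alone must outrun
the death rate by an order of magnitude to reach equality even
asymptotically, whereas modest aggressor rehabilitation ($\delta_A$ a
fraction of $r_A$) collapses both victim classes — $\delta_A \ge r_A$
empties the aggressor compartment entirely.

## The synthetic generator

`generate_synthetic()` integrates a chosen ground truth and emits an
incidence table (counts $= 10^6 V$, rounded), a population trajectory, and
a truth record. Noise models: none, multiplicative lognormal on victim
levels (default choice for realism — the male and female series differ by
two orders of magnitude, so additive noise would be ill-scaled), or Poisson
on counts. An optional underreporting window multiplies counts by a
reporting fraction, emulating the pandemic-era dip in the real series; a
noiseless fit on such data rides above the deflated window observations,
reproducing the overestimation signature seen in the real fits.

One design point deserves emphasis. The emitted population anchors are
$A(t)/p_A$, so rebuilding the scenario from the emitted files reproduces
the true aggressor series exactly; but the susceptible target in the truth
record is the model's own $S(t)$, not $p_S \times$ population. Forcing
$S_{\text{obs}} = (p_S/p_A)A(t)$ would make the generating parameters *not*
the least-squares optimum of their own data (the model's $S$ is not exactly
proportional to its $A$), and parameter-recovery benchmarks would then
measure that structural gap rather than estimator quality. The
`recovery_harness()` therefore fits the truth series. Corollary: passing
recovery tests shows the estimator inverts the model under the assumed
observation process; it says nothing about whether real aggressor and
susceptible populations are census percentages — that assumption is
untestable from these data and is inherited, not validated.

## Numerical choices

* Integration: `deSolve::lsoda`, `rtol = 1e-8`, `atol = 1e-10` (exposed).
  The aggressor component agrees with the logistic closed form to better
  than $10^{-8}$ relative over 25-year horizons, and closed-form equilibria
  agree with 500-year integrations to $10^{-6}$ relative.
* Nonnegativity: the right-hand side is evaluated on states clamped at 0 so
  solver round-off cannot flip the sign of mass-action fluxes; trajectory
  values in $[-10^{-10}, 0)$ are clamped to 0, anything below errors.
* Time origin: calendar year 2010 = $t_0$; annual observations at integer
  offsets.
* Degenerate inputs that are handled, not crashed on: constant aggressor
  series (flagged unidentifiable), $\alpha = 0$ with positive inflow
  (unbounded-equilibrium error), $r_S = 0$ (degenerate-parameter error),
  no sign change in the equilibrium bracket (diagnostic report).

Problem sizes in the tests and acceptance script: 14 annual observations
(13 fit + 1 holdout), 500-year equilibrium verifications, 20-replicate
noise studies, 50-replicate stage-1 noise study, 100-draw invariance
sweeps — sizes at which every property checked is well-resolved.

A calibration note: with $r_A \approx 0.05$ the 13 annual aggressor points
cover only the early logistic rise ($A$ reaches ~25 of $k_A = 30$), so
$k_A$ is an extrapolation. Under 5% multiplicative noise its sampling error
has median ~13–18% (verified against a brute-force multistart oracle) — an
identifiability fact about short series, not an optimizer deficiency. The
victim-side parameters, which the asymmetry conclusions rest on, recover to
within 1% noiseless and a few percent median bias under 5% noise.

## Limitations

The model pools both sexes in $A$ and $S$, ignores age, geography and
institution structure, takes aggressors as dynamically autonomous, and sees
only violence severe enough to require medical attention — so all levels are
lower bounds on true victimization. The 2020 reporting collapse is not
mechanistically modelled; it can be emulated (and its effect on fits
studied) through the generator's underreporting window. Parameter
uncertainty is not quantified: fits are point estimates, and the published
comparisons above are equilibrium-level, not digit-level.
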