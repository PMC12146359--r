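# violdyn

Compartmental dynamics of gender-segregated violence.

`violdyn` models the annual number of people injured severely enough by
violence to require medical attention, segregated by sex, as the output of a
four-compartment system of ordinary differential equations. It was built
around the Mexican 2010–2023 surveillance series of individuals treated in
medical units by injury intentionality (family, non-family and self-inflicted
violence), which ships with the package, but every stage — model, estimation,
equilibrium analysis, intervention projection, synthetic benchmarking — is
exposed as reusable functions.

It is aimed at quantitative public-health researchers who want to (i) test
whether a minimal mass-action mechanism can reproduce an observed
gender-segregated victim series, (ii) read the gender asymmetry off the
fitted interaction rates, and (iii) ask what recovery (rehabilitation)
effort would be needed to close the gap between female and male victims.

## The model

Populations are measured in millions, time in years. Aggressors `A` and
susceptibles `S` (both sexes pooled) grow logistically; victimization is a
mass-action interaction; victims `V_M`, `V_F` are removed at per-capita
death rates:

    dA/dt   = r_A A (1 − A/k_A)
    dS/dt   = r_S S (1 − S/k_S) − β_M A S − β_F A S
    dV_M/dt = β_M A S − α_M V_M
    dV_F/dt = β_F A S − α_F V_F

Two nested extensions add intervention pathways that switch on in a chosen
*recovery year*: female victims returning to the susceptible class at rate
`γ_F` (`+γ_F V_F` into `dS/dt`, `−γ_F V_F` into `dV_F/dt`), and aggressor
rehabilitation at rate `δ_A` (`−δ_A A` into `dA/dt`, `+δ_A A` into `dS/dt`).

Because the aggressor equation is uncoupled, estimation is two-stage:
`(r_A, k_A, A0)` by least squares on the logistic closed form against an
aggressor target series (a configurable percentage of the national
population), then the remaining six rates and the initial conditions by
bounded Levenberg–Marquardt least squares on the integrated trajectory, with
death rates capped at 1/year. Long-run saturation levels follow in closed
form: with `A* = k_A` and `S* = k_S (1 − (β_M+β_F) k_A / r_S)`,

    V_M* = β_M k_A S* / α_M,    V_F* = β_F k_A S* / (α_F + γ_F).

## Worked example

```r
library(violdyn)

# Saturation levels implied by the published family-violence estimates
round(victim_equilibria(family_violence_params()) * 1e6)
#>    V_M    V_F
#>   9825 146993

# Refit the bundled surveillance series: aggressors 20% / susceptibles 40%
# of the interpolated national population, fit 2010-2022, holdout 2023
tab <- load_incidence()
pop <- read_population_config(
  system.file("extdata", "population_mexico.yaml", package = "violdyn"))
fit <- fit_violence_model(tab, pop,
                          scenario_config(violence_type = "family"),
                          fit_config(seed = 42))
fit
#> Two-stage violence model fit (family, 13 fit years from 2010)
#> Gender-segregated violence model parameters (millions, 1/year):
#>         r_A         k_A         r_S         k_S      beta_F      beta_M
#> 5.46062e-02 3.03295e+01 2.00000e+00 4.90044e+01 2.52918e-05 2.79824e-06
#>     alpha_F     alpha_M     gamma_F     delta_A
#> 3.14831e-01 5.13112e-01 0.00000e+00 0.00000e+00
#> ...
#> holdout relative errors:
#>         2023
#> A   -0.00214
#> S   -0.05547
#> V_M -0.09271
#> V_F  0.23050
```

The fitted female interaction rate (`2.5e-05`) sits an order of magnitude
above the male one (`2.8e-06`): interactions with aggressors produce far
more female than male victims of family violence. The 2023 forward
prediction overshoots female victims by ~23%, consistent with the
underreporting seen in the series from 2020 onward.

How much female-victim recovery would equalize the sexes? With the published
family-violence rates,

```r
et <- equality_threshold(list(params = family_violence_params(),
                              state0 = fit$state0, t0 = 2010),
                         recovery_year = 2023)
#> asymptotic gamma_F*: 4.891 /year (14.0 x alpha_F)
```

so even asymptotic equality needs a recovery rate ~14 times the female death
rate — female-victim support alone cannot close the gap on realistic scales,
which is what motivates the aggressor-rehabilitation extension
(`project_with_recovery()`, `sweep_recovery()`).

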