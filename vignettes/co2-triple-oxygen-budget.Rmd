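---
title: "The triple-oxygen-isotope budget of tropospheric CO2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The triple-oxygen-isotope budget of tropospheric CO2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripleoxy)
```

## The problem

Oxygen has three stable isotopes, and almost every low-temperature process
fractionates $^{17}$O and $^{18}$O in a fixed mass-dependent proportion
$\lambda \approx 0.52$. Stratospheric CO$_2$–O$_3$ photochemistry does not:
it endows CO$_2$ with an *anomalous* $^{17}$O excess. Near the surface that
anomaly is continuously erased by isotope exchange with leaf, soil and ocean
water, so the standing anomaly of tropospheric CO$_2$ measures how fast the
atmosphere's CO$_2$ oxygen is being cycled through the biosphere and
hydrosphere. `tripleoxy` implements that inference end to end: from
per-flask $\delta^{17}$O/$\delta^{18}$O tables to the gross terrestrial
cycling flux, the oxygen-isotope residence time of CO$_2$, and gross primary
productivity (GPP).

## Two anomaly conventions

The anomaly is defined in a logarithmic form, used for reporting
measurements,

$$\Delta'^{17}\mathrm{O} = \ln(1+\delta^{17}\mathrm{O})
  - \lambda \ln(1+\delta^{18}\mathrm{O}),$$

and a linear form $\Delta = \delta^{17}\mathrm{O} - \lambda\,
\delta^{18}\mathrm{O}$. Only the linear form is conserved under mixing of
CO$_2$ pools, so the flux budget is solved entirely in the linear
convention; `log_to_linear()` converts at a stated $\delta^{18}$O, and the
two directions round-trip to $<10^{-9}$‰. The reference exponent is
$\lambda_0 = 0.516$, chosen because it equals the plant-transpiration slope
at 75 % relative humidity, which makes transpiration invisible in anomaly
space and leaves water–CO$_2$ equilibration (slope 0.5229) as the process
that sets the terrestrial endmember. `rescale_lambda()` moves anomalies
between conventions exactly, e.g. from the meteoric-water-line exponent
0.528.

## Endmembers and the budget

Each CO$_2$ source carries a characteristic anomaly
(`build_endmembers()`):

```{r endmembers}
build_endmembers()
```

The terrestrial value follows from meteoric water ($-0.046$‰) equilibrated
at 15 °C ($\alpha^{18} = 1.043$):
$(0.5229-0.516)\ln(1.043) - 0.046 = 0.244$‰; the ocean value from ocean
water (0.000‰) at 20 °C gives 0.284‰; combustion CO$_2$ inherits the air-O$_2$
anomaly ($-0.21$‰). The *linear* endmember values default to the
established constants ($\Delta_l = -0.009$, $\Delta_r = \Delta_s = 0.019$,
$\Delta_o = 0.075$, $\Delta_{anth} = -0.286$‰) because the $\delta^{18}$O
values behind the terrestrial ones are not independently known; a
"computed" mode derives them from the logarithmic values at assumed,
reverse-engineered $\delta^{18}$O per pool and agrees with the constants to
$\le 0.002$‰. The soil value is a documented inconsistency we do not try to
reconcile: equilibration of mean meteoric water at 15 °C would imply a soil
CO$_2$ $\delta^{18}$O near 36‰ and a linear value near 0.09‰, not the
published 0.019‰; the published constant is used as-is.

At steady state the anomaly-weighted fluxes balance:

$$F_{land}\frac{(\Delta_l-\Delta_a)+(\Delta_s-\Delta_a)}{2}
 + F_{ao}(\Delta_o-\Delta_a) + F_{anth}(\Delta_{anth}-\Delta_a)
 + F_{st}(\Delta_{st}-\Delta_a) = 0,$$

where the stratospheric term enters only as the product
$F_{st}(\Delta_{st}-\Delta_a) = 50 \pm 3$‰ PgC yr$^{-1}$ (an external model
result, taken as given). The terrestrial flux is split 2:1:1 into leaf
exchange, respiration and soil invasion; kinetic-fractionation terms are
dropped, and `kinetic_bound()` verifies they stay below
$\sim$1‰ PgC yr$^{-1}$ even for extreme pathway exponents (0.529) when the
leaf term uses the *net* leaf flux, which is how the balance equation is
written — for a 500 PgC yr$^{-1}$ gross flux the bound would not hold, an
ambiguity we surface rather than resolve.

```{r budget}
sol <- solve_budget(budget_inputs())
sol
```

With the observed tropospheric anomaly of 0.326‰ (converted at
$\delta^{18}\mathrm{O}_a = 41$‰) this yields $F_{land} \approx 339$
PgC yr$^{-1}$ and $\tau = M/F_{sur} \approx 1.9$ yr. The conversion
$\delta^{18}$O is genuinely uncertain (the observed Taipei mean is 40.65‰,
marine background nearer 41.5‰); across 40.65–41.5‰ the solved flux moves
by under $\pm 25$ PgC yr$^{-1}$, well inside the $\pm 70$ standard error,
and the value used is echoed in all outputs. Solving in the logarithmic
convention is available as a clearly-labelled diagnostic only; it shifts
the flux far outside the linear-convention answer, which is why the linear
form is mandatory.

## GPP inversion

Net leaf uptake removes only the CO$_2$ that is not retro-diffused after
equilibrating with leaf water: with $\kappa_c = C_c/(C_a-C_c)$ the
stomatal-conductance measure and $\theta_{eq}$ the degree of hydration,

$$0.88\,\mathrm{GPP} = \frac{F_{land}-F_s}{\theta_{eq}\kappa_c+1},$$

and closing with $\mathrm{GPP} = \mathrm{NEP} + F_s$ (soil invasion as
large as respiration, the "best estimate" closure) gives the closed form
$\mathrm{GPP} = (F_{land}+\mathrm{NEP})/(0.88(\theta_{eq}\kappa_c+1)+1)$.
The factor 0.88 accounts for leaf respiration.

```{r gpp}
solve_gpp(345, uptake_scenario(kappa_c = 1.33, theta_eq = 0.78, nep = 10))
```

`gpp_given_fs()` is the decoupled mode (prescribed $F_s$, no closure) used
by the soil-invasion scan. The literature bounds are
$\kappa_c \in [1.33, 2.97]$ and $\theta_{eq} \in [0.70, 0.78]$; the
$\kappa_c$ upper bound is quoted as both 2.93 and 2.97 in the source
literature and we adopt 2.97, the value used in the scenario sampling. If
$F_{land}$ is so close to NEP that the closure would imply negative soil
invasion, the result is clamped to the physical edge and flagged
`degenerate` rather than silently returned.

## Uncertainty

`propagate_se()` implements first-order propagation
$\sigma_f^2 = \sum_i (\partial f/\partial x_i)^2 \sigma_i^2$ with central
differences (relative step $10^{-6}$; the budget is smooth and nearly
linear at this scale, so the step is uncritical). The budget error model
distinguishes standard errors of sample means from single-measurement
standard deviations. Two modelling choices deserve note:

* the transpiration relative-humidity term (0.017‰ per 0.05 RH — the error
  budget uses this value; 0.015‰ is the value quoted for the source
  process itself) enters as a common shift of both terrestrial endmembers,
  as does their quoted 0.006‰ error — treating the leaf and soil errors as
  fully correlated is the conservative reading;
* only the tropospheric anomaly has an independently known
  single-measurement spread (0.039‰); the other inputs fall back to their
  standard errors, so `single_measurement_error()` is a lower bound on the
  single-measurement inhomogeneity, and we do not attempt to reproduce any
  particular published value for it.

The result is a standard error near 60 PgC yr$^{-1}$ on $F_{land}$, with
the transpiration and stratospheric terms dominating the variance — the
contribution table reports each share explicitly.

```{r err}
budget_standard_error()$contributions
```

`run_monte_carlo()` propagates the scenario ranges:
$\kappa_c \sim U(1.33, 2.97)$, $\theta_{eq} \sim U(0.70, 0.78)$,
$F_{land} \sim N(345, 70)$ in the default joint mode. We replaced a
$500^3$ full-factorial layout with 125,000 independent joint draws —
statistically equivalent for means and standard deviations, and the
factorial mode remains available (default $50^3$) for layout-fidelity
runs. A coupled mode instead re-solves the budget from normal draws of
every uncertain input. Draws with $F_{land} \le$ NEP (or a degenerate
budget in coupled mode) are rejected and counted; the summary reports the
rejection fraction, full/half-sample convergence against 2 Monte Carlo
standard errors, and is bit-for-bit reproducible at a fixed seed.

```{r mc}
run_monte_carlo(seed = 1, n_draws = 20000)
```

The Monte Carlo means sit near 110 and 100 PgC yr$^{-1}$ — inside the
published $120\pm30$ / $110\pm30$ bands but below the single-scenario
130/120 values, because averaging $1/(\theta_{eq}\kappa_c+1)$ over the full
conductance range pulls the mean down relative to the
$\kappa_c = 1.33$ scenario.

## Sensitivity scans

Four standard scans re-run the inversion with one quantity varied and all
else frozen: the ocean flux (a 50 % change moves $\tau$ by only
$\approx 0.1$ yr — the oceanic isoflux is an order of magnitude below the
terrestrial one), the stratospheric isoflux (a 10 % change moves $\tau$ by
$\approx 0.17$ yr, i.e. $\sim$0.2 yr at one decimal), the soil-invasion
flux at fixed $F_{land}$ (GPP spans roughly 0–200 PgC yr$^{-1}$ across the
two bracketing uptake scenarios), and the southern-hemisphere anomaly.

The hemispheric scan needs a caveat, which the function also emits as a
warning: the only recipe the steady-state framework supports is averaging
the two hemispheric anomalies into a global value before the standard
inversion. Under that recipe a *higher* southern-hemisphere anomaly lowers
the solved terrestrial flux and GPP and lengthens $\tau$. Published
statements of the opposite sign imply a hemispherically-resolved mechanism
(e.g. in how the stratospheric term partitions) that is not specified
anywhere we can implement from; the scan therefore reports what the
averaging recipe computes, flags every off-baseline row, and asserts
nothing about the published 170/200 PgC yr$^{-1}$ figures.

## Station statistics and the synthetic generator

`site_summary()` gives per-variable means/sds/ses, the triple-isotope
regression of $\ln(1+\delta^{17}\mathrm{O})$ on
$\ln(1+\delta^{18}\mathrm{O})$ (reduced major axis, appropriate since both
axes carry error; OLS alongside), and the mean log-ratio. A
$\delta^{18}$O threshold (the observational choice is 38.5‰) excludes
outliers from the regression only, never from the means, and both filtered
counts are reported. "1-σ standard deviation of the range" in the source
literature is read as the ordinary sample standard deviation.
`multi_site_average()` is the unweighted mean of site means (each site one
vote regardless of n) with $se = sd/\sqrt{n}$; whether the published
four-site value 0.326‰ used unrounded site means is unknowable from the
rounded ones (which give 0.32525‰), so we report three decimals and treat
0.325–0.326 as agreement.

The synthetic generator (`generate_station()`,
`generate_four_site_suite()`) emulates exactly the structure the pipeline
consumes: two-endmember conservative CO$_2$/δ$^{13}$C mixing (background
395.4 ppmv at $-8.47$‰; added CO$_2$ from a scaled Beta distribution
standing in for the diurnal cycle; a $-28$‰ fossil/respired endmember — a
typical value, not an observational constraint), Gaussian $\delta^{18}$O
about the site mean, and $\ln(1+\delta^{17}\mathrm{O})$ on a slope-0.518
line whose intercept is set so the expected site-mean anomaly hits the
target, plus instrument noise (0.05‰ on $\delta^{18}$O, 0.01‰ on the
anomaly). The four default sites target the observed means (0.335, 0.335,
0.310, 0.321‰) with 210/85/120/40 samples (455 total; the split across
sites is not published and is configurable). What the generator does *not*
reproduce: the observed within-site anomaly spread (0.03–0.06‰, which is
natural variability, not instrument noise), day-time CO$_2$ drawdown below
background, seasonality, and any real covariance between CO$_2$ load and
the isotope line. Passing round-trip tests therefore demonstrates that the
estimators recover what the generator encodes — not that real-station
systematics are absent.

## Numerical choices and problem sizes

All algebra is double precision with no intermediate rounding; permil
values are converted to fractions only inside logarithms (`log1p`/`expm1`
for accuracy near zero). The budget solver is closed-form and is checked
against a brute-force root search in the tests; solutions with a
numerator cancelling to within $10^{-9}$ PgC yr$^{-1}$ of zero are
reported as exactly zero flux. Degenerate inputs (anomaly at or below the
land composite, negative solved flux) raise structured errors; scan and
curve functions flag such rows instead of dropping them. The test suite
runs the Monte Carlo at $2\times10^4$–$1.25\times10^5$ draws and synthetic
stations at $n \le 800$, sizes at which every stochastic check has
comfortable margin while the whole suite completes in seconds.

## Limitations

The model is a steady-state, well-mixed single box: no seasonality, no
time-dependent solution, no resolved interhemispheric transport (only the
averaging scan above), and the stratospheric isoflux is an external input,
not computed. GPP rests on the scalar $\kappa_c$/$\theta_{eq}$
description of plant uptake and on the $F_s = F_r$ closure; where those
assumptions fail, so does the inversion's central value, though the scan
and Monte Carlo machinery quantify exactly how.
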