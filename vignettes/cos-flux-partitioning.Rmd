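---
title: "Joint CO2-COS flux partitioning: models, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint CO2-COS flux partitioning: models, priors, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Eddy-covariance towers measure the *net* ecosystem exchange of CO2 (NEE),
the small difference between two large opposing gross fluxes: photosynthetic
uptake (GPP) and ecosystem respiration (Reco). Neither gross flux is
observable directly, so GPP is conventionally inferred by flux-partitioning
(FP) models that lean entirely on the CO2 record. Carbonyl sulfide (COS), a
trace gas at ~500 ppt, diffuses into leaves through the same stomata as CO2
and is destroyed irreversibly by carbonic anhydrase, so its canopy flux is a
one-way proxy for gross uptake. `cosflux` implements a partitioning model
(FP+) in which NEE and the ecosystem COS flux jointly constrain GPP, plus
everything needed to exercise it: soil COS flux handling, a synthetic
campaign generator with known truth, a multichain MCMC sampler, and
reporting utilities.

## Process model

All measured fluxes use the micrometeorological sign convention (negative =
uptake); GPP, Reco and the modelled canopy COS uptake are non-negative
magnitudes, negated only at comparison boundaries.

Respiration follows the Lloyd–Taylor temperature response
$$R_{eco} = r_b\,\exp\!\left[E_0\!\left(\tfrac{1}{T_{ref}-T_0} -
\tfrac{1}{T_{air}-T_0}\right)\right],$$
with $T_{ref} = 15\,^\circ$C and $T_0 = -46.02\,^\circ$C fixed. Daytime GPP
is a rectangular hyperbola in PAR,
$$GPP = \frac{\alpha\beta R_{PAR}}{\alpha R_{PAR}+\beta},$$
and NEE is their difference, $NEE = R_{eco} - GPP$. The canopy COS flux is
tied to GPP through the leaf relative uptake ratio (LRU):
$$F_{COS} = GPP \cdot LRU \,/\, (\chi_{CO_2}/\chi_{COS}),
\qquad LRU = \iota\, e^{\kappa/R_{PAR}}.$$
The mole-fraction ratio is formed on a common mol/mol scale from the native
units (ppm for CO2, ppt for COS) and is taken per record; a campaign-mean
variant would change results only marginally since the generator's diel
ripple is ±1%.

Two points deserve comment. First, the exponent of the LRU model is
$\kappa/R_{PAR}$: $\kappa$ carries the units of PAR, the ratio tends to
$\iota$ at high light, and it diverges as light vanishes — which is also why
nighttime COS uptake under incomplete stomatal closure does not break the
proxy logic. A form with $\kappa \cdot R_{PAR}$ in the exponent would be
dimensionally inconsistent with these limits. Second, no vapour-pressure-
deficit limitation of $\beta$ is included; the parameter controlling that
effect is deliberately out of scope. LRU operations never clamp at low
light: fitting simply excludes records at or below the daytime PAR
threshold (10 µmol m⁻² s⁻¹ by default).

## Soil COS fluxes

Soils can emit or take up COS; the ecosystem flux must be corrected to a
canopy flux before it can constrain GPP. Chamber measurements give the soil
flux through the steady-state mass balance $F = q\,(C_2-C_1)/A$ (flow
$q$ in mol s⁻¹ via the ideal gas law from L min⁻¹, chamber area default
0.032 m²); only readings flagged stable are computed. A random forest
(500 trees, one third of features per split, minimum node size 5, out-of-bag
scoring) regresses the chamber fluxes on shortwave radiation at the soil
surface, soil temperature and soil moisture, and extrapolates them to the
half-hourly tower timescale; one model per site, never pooled across sites.
A random forest is a pragmatic choice here: the drivers interact (radiation-
driven abiotic emission vs. moisture/temperature-driven microbial uptake)
and the sample is small. Predictions outside the training hull warn but do
not error, since forests extrapolate flatly rather than wildly.

## Two-stage Bayesian inversion

The temperature sensitivity $E_0$ is estimated first, from nighttime NEE
(pure respiration) by RMSE minimization; since the model is linear in
$r_b$ at fixed $E_0$, $r_b$ is profiled in closed form and $E_0$ searched in
1-D with a coarse grid multi-start. $E_0$ is then held fixed, and the
remaining parameters are sampled over the daytime records: $\alpha, \beta,
r_b, \sigma_{NEE}$ for FP, plus $\iota, \kappa, \sigma_{COS}$ for FP+. The
likelihood is iid Gaussian per stream with the noise scales free nuisance
parameters, so the NEE and COS streams weight themselves; their sum (FP+)
treats the streams as independent.

Default priors: uniform with generous physical bounds for $\alpha$ (0–0.3),
$\beta$ (0.1–100 µmol m⁻² s⁻¹), $r_b$ (0.01–50), $\kappa$ (0–500 µmol m⁻²
s⁻¹) and the $\sigma$s; for $\iota$ a truncated normal (mean 1.7, sd 1.4,
support 0–10) centred on the leaf-level literature median, with a uniform
alternative on the same support for prior-sensitivity checks — on
well-identified synthetic data the switch moves the posterior median by far
less than its credible width.

The sampler is a differential-evolution multichain Metropolis
(DREAM-style): proposals are $x' = x + \gamma(x_a - x_b) + \epsilon$ with
$\gamma = 2.38/\sqrt{2d}$ and 10% full-$\gamma{=}1$ jumps; the symmetric
proposal keeps plain Metropolis acceptance detailed-balance correct. Chains
(at least $d+1$, default $\max(4, d+1)$) are initialized by scoring a prior
sample; when the likelihood is informative the best candidates are refined
by Nelder–Mead and the chains seeded in a small cloud around the mode,
which avoids the stuck-outlier pathology of cold-started DE-MC without any
outlier-resetting machinery; when it is flat the chains start at prior
draws, so a flat posterior returns the prior exactly. Burn-in is the first
half of the iterations (shortened only to guarantee at least 2,950 retained
draws, the reporting convention used throughout); convergence requires the
Gelman–Rubin $\hat R$ of every parameter below 1.1 on the retained draws,
and anything else is explicitly flagged unconverged — summaries are still
produced, but `partition_series()` refuses unconverged fits unless forced.

## The synthetic campaign generator

Scenarios emulate four campaign archetypes — mountain grassland (GRA),
Mediterranean savanna (SAV), beech forest (DBF), soybean crop (CRO) — with
high-light LRU values 1.02, 2.27, 2.22, 0.89, peak canopy COS uptake near
30–40 pmol m⁻² s⁻¹ (roughly double at DBF), and soil terms that make the
savanna a net daytime COS emitter under high radiation load while shaded
sites stay net sinks. Campaign length defaults to 30 days. Meteorology is a
deterministic diel skeleton: half-sine PAR, sinusoidal air temperature
lagged 2 h behind solar noon, a damped soil-temperature copy, near-constant
soil moisture, shortwave at the soil surface as transmission × PAR/2.1, and
±1% ripples on the ambient mole fractions; timestamps are CET. Truth fields
are exact forward-model evaluations; observations add iid Gaussian noise
(defaults $\sigma_{NEE} = 1$ µmol m⁻² s⁻¹, $\sigma_{COS} = 3$ pmol m⁻²
s⁻¹). Nights receive a residual canopy COS uptake of 20% of the mean
daytime uptake, emulating incomplete stomatal closure, so the
daytime-only fitting is tested against realistically contaminated nights.
Chamber campaigns are generated by inverting the chamber equation with
ppt-scale noise.

What the generator does *not* emulate: synoptic weather (PAR and
temperature are perfectly diel, hence more collinear than in real
campaigns), gaps and QC flags, heteroscedastic or autocorrelated instrument
noise, and footprint/advection artefacts. Passing tests therefore
demonstrate the correctness of the estimation machinery under the model's
own assumptions, not robustness to every property of field data.

## Numerical choices

Daytime is PAR > 10 µmol m⁻² s⁻¹; nights are the complement. The $E_0$
search spans 0–600 °C with a 25-point multi-start grid and warns within 1%
of a bound; near-isothermal nights (sd < 0.5 °C) are an error rather than a
silently absurd estimate. Credible intervals are equal-tailed 95%
quantiles; the MAP is the highest-posterior retained draw. Percent
differences between campaign GPP sums are $100(\Sigma_b -
\Sigma_a)/\Sigma_a$ with the spread the sd of the same statistic per day
(weekly optional). The limit-of-detection multiplier is 1.96 (two-sided
95%), configurable. Campaign sums integrate half-hourly values × 1800 s.
Test and example problem sizes (12–30-day campaigns, 1,500–4,000
iterations, 8 chains) were chosen so the whole suite exercises every stage,
including four end-to-end campaigns, at desk scale.

## Known limitations

The single whole-campaign fit mirrors the one-parameter-set-per-site
reporting of the method; moving-window variants are out of scope, and the
nighttime-extrapolation reference (`partition_series_nighttime()`) is a
deliberately simplified whole-campaign rendition, not a faithful standard
implementation.

The most consequential limitation is structural to the two-stage design:
the GPP credible band propagates the MCMC posterior of $(\alpha, \beta)$
while $E_0$ enters as a fixed plug-in estimate. The nighttime $E_0$ has
appreciable sampling error under realistic noise, and its error is
compensated during the daytime fit mainly by $\alpha$ — so in campaigns
where the $E_0$ draw is poor, the (tight) GPP band can sit beside the true
curve for most daytime records at once. In repeated synthetic campaigns the
all-record band coverage averages a little below nominal (~85–90% rather
than 95%), bimodally: most campaigns are fully covered, occasional ones
largely missed. Propagating $E_0$ uncertainty into the daytime inversion
would repair the coverage but would change the two-stage method this
package implements. Users comparing FP and FP+ campaign sums should treat
the bands as conditional on $E_0$.

Soil-model extrapolation beyond the chamber sampling hull is flat; chamber
campaigns should span the diel cycle. And because both models here are fit
to data generated from the same functional forms, synthetic FP vs FP+
differences are near zero — the interesting real-world differences arise
precisely where the functional forms are imperfect, which no synthetic test
can certify.
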