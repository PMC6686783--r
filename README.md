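# cosflux

Joint CO2–COS eddy-covariance flux partitioning in R.

Eddy-covariance towers observe only the *net* ecosystem CO2 exchange (NEE);
the gross fluxes behind it — photosynthetic uptake (GPP) and ecosystem
respiration (Reco) — must be inferred. Carbonyl sulfide (COS) enters leaves
through the same stomata as CO2 and is destroyed irreversibly by carbonic
anhydrase, making its canopy flux an independent proxy for gross uptake.
`cosflux` is for ecosystem scientists who measure both gases: it implements
the classical daytime light-response partitioning model (**FP**) and its
joint CO2+COS extension (**FP+**), in which the leaf relative uptake ratio
(LRU) is an adjustable, light-dependent parameter fitted together with the
photosynthesis and respiration parameters.

The process model, in the field's standard notation (fluxes negative =
uptake; GPP, Reco as magnitudes):

- Respiration (Lloyd–Taylor):
  `Reco = rb * exp(E0 * (1/(Tref − T0) − 1/(Tair − T0)))`,
  `Tref = 15 °C`, `T0 = −46.02 °C`
- Light response: `GPP = α β R_PAR / (α R_PAR + β)`; `NEE = Reco − GPP`
- COS coupling: `F_COS = GPP · LRU / (χ_CO2 / χ_COS)` with
  `LRU = ι · exp(κ / R_PAR)` (ι = LRU at high light; κ governs the
  low-light increase)

`E0` is estimated from nighttime NEE by RMSE minimization and held fixed;
the remaining 4 (FP) or 7 (FP+) parameters — including per-stream Gaussian
noise scales — are sampled with a differential-evolution multichain MCMC
sampler with Gelman–Rubin convergence checks. Ecosystem COS fluxes are first
corrected to canopy fluxes by subtracting a soil COS flux modelled from
chamber measurements with a random forest on radiation, soil temperature and
moisture. A synthetic-campaign generator with four site presets (grassland
GRA, savanna SAV, beech forest DBF, cropland CRO) provides half-hourly data
with known truth for testing the whole chain.

## Worked example

```r
library(cosflux)

scen     <- site_scenario("GRA", n_days = 12, seed = 42)
campaign <- simulate_campaign(scen)                        # half-hourly tibble
chambers <- simulate_chamber_campaign(scen) |> chamber_flux()

soil     <- fit_soil_model(chambers, seed = 42)            # soil COS model
campaign <- predict_soil_flux(soil, campaign) |> canopy_cos_flux()

fp  <- fit_fp(campaign,     n_iter = 2500, seed = 42)      # NEE only
fpp <- fit_fpplus(campaign, n_iter = 2500, seed = 42)      # NEE + COS
fpp
#> <cos_fit FP+: E0 = 141.4 degC (n_night = 228), 348 daytime records>
#> # A tibble: 7 × 6
#>   param      median    mean   ci_lo   ci_hi  rhat
#>   <chr>       <dbl>   <dbl>   <dbl>   <dbl> <dbl>
#> 1 alpha      0.0507  0.0507  0.0466  0.0553  1.01
#> 2 beta      30.2    30.2    29.3    31.1     1.01
#> 3 rb         4.15    4.14    3.42    4.92    1.01
#> 4 iota       1.03    1.03    0.984   1.07    1.01
#> 5 kappa     46.7    46.4    25.2    65.8     1.00
#> 6 sigma_nee  1.01    1.01    0.938   1.08    1.01
#> 7 sigma_cos  3.07    3.07    2.84    3.34    1.01

campaign_report(campaign, fp, fpp, site = "GRA")
#> <campaign_result GRA: 576 half hours>
#>   GPP sums (mol m-2): FP 11.80, FP+ 11.79
#>   FP+ vs FP: -0.14% +- 0.00% (sd over 12 days)
```

The fit table is the joint posterior summary: this 12-day grassland
campaign was generated with α = 0.05, β = 30, rb = 4, ι = 1.02, κ = 50 and
noise σ_NEE = 1, σ_COS = 3 — every generating value sits inside its 95%
credible interval, all R-hat < 1.1, and the recovered ι (1.03) is the
high-light LRU the COS stream contributes. The report compares campaign GPP
sums of the two models with the day-to-day spread of the difference; on
synthetic data, where both models are correctly specified, the difference
is near zero by construction.

`autoplot()` methods give posterior marginals (`autoplot(fpp)`), chain
traces (`autoplot(fpp$chains)`) and the GPP band comparison
(`autoplot(report)`); `tidy()`/`glance()` return the summaries as tibbles.
A thin command-line wrapper covers the same pipeline
(`inst/cli/cosflux simulate|soilfit|fit|report ...`).

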