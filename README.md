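# dielmetab

Single-station stream metabolism from high-frequency dissolved-oxygen
records.

Headwater streams breathe: photosynthesis pushes dissolved oxygen (DO)
above saturation by day, respiration draws it down at night, and gas
exchange with the atmosphere pulls it back toward equilibrium.  A single
well-placed oxygen logger therefore carries enough information to estimate
whole-reach gross primary production (GPP), ecosystem respiration (ER) and
reaeration — the core quantities of stream ecosystem metabolism.
`dielmetab` is for aquatic ecologists and biogeochemists who run such
sensor campaigns: it turns raw logger exports into daily metabolic rates
with uncertainty, quality control and the standard downstream analyses.

## The model

Over each measurement interval *i* (nominally 5 minutes) the change in DO
(mg L⁻¹) is the balance of three processes:

```
Δ[DO]ᵢ = A·Iᵢᵖ − R·θ^(Tᵢ−T̄) + K_O2·Δt·1.0241^(Tᵢ−T̄)·Dᵢ
```

* `A·Iᵢᵖ` — photosynthetic production per quantum of light; `Iᵢ` is PAR
  (µmol m⁻² s⁻¹), `p` (default 1) the light-saturation exponent.
* `R·θ^(Tᵢ−T̄)` — respiration at the daily mean temperature `T̄`, scaled by
  the temperature coefficient `θ` (default 1.072, ≈ Q₁₀ of 2).
* `K_O2·Δt·1.0241^(Tᵢ−T̄)·Dᵢ` — reaeration: the first-order erasure of the
  saturation deficit `Dᵢ = DOsat − DOᵢ`, with `K_O2` in d⁻¹ and the
  saturation concentration from the Benson–Krause solubility equations
  (with salinity and barometric-pressure corrections).

Daily totals follow the summation convention: a day's GPP (ER) is the sum
of its per-interval values, in mg O₂ L⁻¹ d⁻¹, and NEP = GPP + ER with ER a
negative flux.

For each calendar day the free parameters `(A, R, K_O2, σ_obs)` are
estimated by MCMC (adaptive random-walk Metropolis on log-parameters,
4 chains, split-chain R̂ reported) under a Gaussian observation model, and
every day receives a posterior-predictive p-value: days with ppp outside
[0.1, 0.9] are flagged as implausible and rejected from downstream
summaries.

Downstream analytics implement the field's standard toolkit: seasonal
grouping and trophic classification, Arrhenius/metabolic-theory fitting of
ln|ER| against inverse temperature (activation energy in eV),
light–temperature regression of instantaneous GPP, Spearman screening,
diel DO amplitude, the temperature–pH scaling-law DO predictor, and the
gas-transfer/NEP hypoxia-risk region (`K_O2 × depth < 10` m d⁻¹ and
NEP < −10 mg O₂ L⁻¹ d⁻¹).

## Worked example

A three-day synthetic summer campaign with known truth (daily GPP target
18, |ER| 17 mg O₂ L⁻¹ d⁻¹, `K_O2` 9.8 d⁻¹, 5-minute sampling, observation
noise 0.1 mg L⁻¹), fitted and summarised:

```r
library(dielmetab)

fs  <- generate_scenario(scenario_preset("summer", n_days = 3, seed = 42))
fit <- metab(fs, seed = 42)
summary(fit)
#> Daily metabolism: 3 day(s), 3 accepted by the ppp band
#> Trophic state: 3 autotrophic, 0 heterotrophic day(s)
#> Worst split R-hat: 1.021
#>
#>        date    GPP GPP_lo GPP_hi      ER   ER_lo   ER_hi   NEP  K_O2  ppp accepted
#>  2023-07-01 20.510 20.254 20.805 -16.906 -17.198 -16.643 3.604 9.755 0.49     TRUE
#>  2023-07-02 16.951 16.672 17.229 -16.946 -17.253 -16.652 0.006 9.787 0.48     TRUE
#>  2023-07-03 18.609 18.315 18.904 -16.914 -17.229 -16.587 1.694 9.918 0.47     TRUE
```

Day-to-day light variation moves realised GPP around the preset target
(the generator's truth for these seeds is 20.6, 17.0 and 18.7); the
posteriors track it closely, the reaeration coefficient lands on 9.8 d⁻¹,
and all three days pass the posterior-predictive check.

The fitted respiration series gives the activation energy via the
metabolic-theory regression, and the daily table feeds the risk screen:

```r
k1  <- fs$day_index == 1
arrhenius_fit(er_increment(coef(fit)[1, "R"], fs$temp[k1], mean(fs$temp[k1])),
              fs$temp[k1])
#> Arrhenius fit (n = 288): slope -6159.5 K, E_A = 0.531 eV, R2 = 1.000, p = 0

risk_report(fit$daily, fs, depth = 0.5)[, c("date", "K_gas_transfer", "NEP",
                                            "at_risk", "hypoxic_intervals")]
#>         date K_gas_transfer         NEP at_risk hypoxic_intervals
#> 1 2023-07-01       4.877624 3.604149057   FALSE                 0
#> 2 2023-07-02       4.893501 0.005524527   FALSE                 0
#> 3 2023-07-03       4.958967 1.694459505   FALSE                 0
```

`E_A ≈ 0.53 eV` is exactly what a θ = 1.072 respiration model implies near
25 °C.  Gas transfer is below the 10 m d⁻¹ risk threshold in this shallow
reach, but NEP stays positive, so no day falls in the hypoxia-risk region
and no observation drops below 2 mg L⁻¹.

Raw logger files come in through `read_sensor_file()` (miniDOT/HOBO/EXO2
style delimited exports, illuminance converted to PAR with the 0.0185
factor) and `assemble_forcing()`; see `inst/extdata/` for synthetic
examples.  The same pipeline is scriptable through a YAML config with
`run_simulate()` / `run_fit()` / `run_report()` or the thin `exec/dielmetab`
command line.

## Package layout

* `R/forcing.R`, `R/io.R` — forcing containers, logger parsing, unit
  conversion, gap-aware grid assembly, CSV round trips.
* `R/solubility.R`, `R/do-model.R` — O₂ solubility, the three process
  terms, forward simulation.
* `R/inference.R`, `R/metab.R` — priors, log-posterior, MCMC, ppp QC,
  daily summaries; the `metab_fit` interface and its methods.
* `R/synthetic.R` — seasonal scenario presets and the seeded generator.
* `R/analytics.R`, `R/risk.R` — seasonal/trophic/Arrhenius/regression/
  correlation analytics and the oxygen-risk toolkit.
* `R/pipeline.R`, `exec/dielmetab` — config-driven batch interface.
* `vignettes/stream-metabolism.Rmd` — the methods vignette (model,
  assumptions, priors, QC, generator design, limitations).
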