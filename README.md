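# paleopH

Boron-isotope paleo-pH reconstruction from annually banded crustose
coralline algae, built for coastal records like the Gulf of Maine where
short instrumental series cannot distinguish long-term ocean
acidification from natural water-mass variability.

The package covers the whole analysis chain:

* **Carbonate system** — total-scale equilibrium constants (Lueker
  carbonic acid, Dickson boric acid, Weiss CO₂ solubility, Uppström total
  boron) and deterministic solvers between {ALK, DIC, pH, pCO₂} pairs.
* **Boron proxy** — the borate equation
  pH = pK\*_B − log₁₀[ −(δ_sw − δ_b) / (δ_sw − α_B δ_b − 1000(α_B − 1)) ]
  with α_B = 1.0272, chained with the species calibration
  δ¹¹B_skeletal = 1.46 δ¹¹B_borate + 6.91 for *Clathromorphum compactum*,
  and Monte-Carlo propagation of measurement, calibration, seawater-δ¹¹B,
  temperature and salinity uncertainties into 68%/95% envelopes.
* **Screening** — Theil–Sen B/Ca–δ¹¹B trend with a MAD-scaled residual
  rule that flags bands contaminated by boron-rich, isotopically light
  secondary carbonate (serpulid worm infill).
* **Chronology** — calendar-year assignment by counting seasonal Mg/Ca
  cycles back from the collection year.
* **Mixing models** — conservative water-mass (Warm Slope / Labrador
  Slope / Scotian Shelf) and river–seawater mixing with carbonate-system
  pH evaluation of every mixture.
* **Synthetic data** — a forward model generating complete datasets
  (δ¹¹B, B/Ca, Mg/Ca transects, environment series) from a prescribed pH
  history, so every stage is testable against known truth.

## Worked example

The modern reference band: a skeletal δ¹¹B of 28.7 ‰ with the default
local seawater δ¹¹B (39.73 ‰) and the mean pK\*_B of 8.82 converts to

```r
library(paleopH)
ph_from_skeletal(28.7, pkb = 8.82)
#> [1] 7.872707
```

i.e. seawater pH 7.87 — in line with modern coastal observations.

A water-mass scenario: 70% Warm Slope Water against 30% Labrador Slope
Water at 11 °C mixes conservatively and solves to

```r
em <- gom_endmembers()
mix_waters(list(em$WSW, em$LSW), c(0.7, 0.3), temperature = 11)
#> Seawater state (total pH scale)
#>   T = 11.00 degC  S = 35.75 psu
#>   ALK = 2322.5 umol/kg  DIC = 2050.0 umol/kg
#>   pH = 8.200  pCO2 = 263.2 uatm
```

versus pH 8.050 at 20% Warm Slope Water — a 0.15-unit swing from
circulation alone.

A full synthetic round trip: generate a century of bands from a pH
history carrying a +0.2 ramp over 1980–2000, then reconstruct it with
full uncertainty propagation:

```r
ds  <- generate_dataset(scenario_spec(seed = 1))
rec <- reconstruct_ph(ds$bands, ds$env, n_draws = 2000, seed = 1)
rec
#> Monte-Carlo pH reconstruction: 202 band(s), 2000 draws, seed 1
#>  specimen_id year_ce ph_median  ci68_lo  ci68_hi  ci95_lo  ci95_hi
#>        SYN01    1920  7.867854 7.792551 7.941739 7.708575 8.006844
#>        SYN01    1921  7.897378 7.820975 7.963606 7.734788 8.018034
#>   ...

pre  <- rec$year_ce <= 1980
post <- rec$year_ce >= 2000
mean(rec$ph_median[post]) - mean(rec$ph_median[pre])
#> [1] 0.1998128
```

The injected +0.2 step is recovered. The per-band envelopes reflect the
measurement-error curve 2σ = 1.61 e^(−0.22 [B]) + 0.17 e^(−0.002 [B]),
so low-boron bands carry visibly wider intervals.

The whole pipeline (simulate → date → screen → reconstruct → mix →
report) also runs from one configuration:

```r
run_pipeline(run_config(out_dir = "run1", seed = 1))
```

or from a shell via `inst/cli/paleoph.R`.

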