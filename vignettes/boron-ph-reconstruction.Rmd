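---
title: "Reconstructing coastal seawater pH from coralline-algae boron isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing coastal seawater pH from coralline-algae boron isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleopH)
```

## The proxy model

Boric acid and the borate ion exchange boron isotopes with an equilibrium
fractionation factor $\alpha_B = 1.0272$, and the relative abundance of the
two species is set by pH through the boric-acid dissociation constant
$K_B^*$. Marine carbonates incorporate the charged borate ion, so the
$\delta^{11}\mathrm{B}$ of skeletal carbonate records the
$\delta^{11}\mathrm{B}$ of borate, which rises with seawater pH:

$$
\mathrm{pH} = \mathrm{p}K_B^* - \log_{10}\!\left(
  -\frac{\delta_{sw} - \delta_b}
        {\delta_{sw} - \alpha_B\,\delta_b - 1000(\alpha_B - 1)}\right)
$$

with $\delta_{sw}$ the seawater and $\delta_b$ the borate
$\delta^{11}\mathrm{B}$ (both in permil). Crustose coralline algae
(*Clathromorphum compactum*) calcify from an internal fluid at elevated pH,
so their skeletal $\delta^{11}\mathrm{B}$ sits well above ambient borate
values; a species-specific culture calibration,

$$
\delta^{11}\mathrm{B}_{skeletal} = 1.46\,(\pm 0.06)\;
\delta^{11}\mathrm{B}_{borate} + 6.91\,(\pm 0.72) \quad (2\sigma),
$$

maps between the two. `ph_from_skeletal()` chains the inverted calibration
and the borate equation:

```{r}
ph_from_skeletal(28.7, pkb = 8.82)
```

Skeletal values below roughly 24.7 permil put the logarithm's argument
outside its domain — no seawater pH can produce them through this model —
and are reported as uninvertible rather than silently clamped.

## Carbonate-system solver

Water-mass scenarios and the pK$_B^*$ calculation need a seawater
carbonate-system equilibrium model. `carb_constants()` assembles, all on
the total pH scale at surface pressure: the Lueker et al. (2000) carbonic
acid constants, the Dickson (1990) boric acid constant, the Weiss (1974)
CO$_2$ solubility, the DOE (1994) water self-ionisation, and Uppström
(1974) total boron proportional to salinity. `ph_from_alk_dic()` finds pH
from total alkalinity and DIC by Brent bracketing of the alkalinity
balance

$$
\mathrm{ALK} = [\mathrm{HCO_3^-}] + 2[\mathrm{CO_3^{2-}}]
 + [\mathrm{B(OH)_4^-}] + [\mathrm{OH^-}] - [\mathrm{H^+}]
$$

on pH $\in [2, 12]$ with a $10^{-10}$ pH tolerance; the residual of a
solved state is far below 0.01 µmol/kg. No nutrient alkalinity terms are
carried: every scenario in this package is specified by ALK/DIC/T/S alone.
The Lueker constants are characterised down to 19 psu; dilute mixtures
below that trigger a warning and proceed with extrapolated values, never a
silent clamp. The test suite cross-checks the solver against a
brute-force pH grid-scan oracle (three-stage refinement to $10^{-6}$ pH)
on 1,000 random states.

## Uncertainty propagation

`reconstruct_ph()` propagates every quantified error source by Monte-Carlo
simulation, drawing independently per band:

| source | 1σ | note |
|---|---|---|
| measurement | $\tfrac{1}{2}\left(1.61\,e^{-0.22[B]} + 0.17\,e^{-0.002[B]}\right)$ ‰ | published 2σ-vs-[B] reproducibility curve, halved |
| calibration slope | 0.03 | published 2σ = 0.06, halved |
| calibration intercept | 0.36 ‰ | published 2σ = 0.72, halved |
| seawater δ¹¹B | 0.1 ‰ | conservative estimate |
| temperature | 1 °C | conservative estimate |
| salinity | 1 psu | conservative estimate |

pK$_B^*$ is recomputed per draw from the perturbed temperature and
salinity (a constant-8.82 mode reproduces the worked example). Slope and
intercept are sampled independently because their covariance is not
published; this overstates calibration uncertainty slightly. Draws that
land below the invertibility threshold are dropped and counted, and a band
losing more than half its draws is excluded as uninvertible. Medians and
16/84 and 2.5/97.5 percentiles form the reported 68% and 95% envelopes.
`mc_coverage()` checks the propagation end to end by forward-modelling
bands whose true nuisance values are drawn from exactly these
distributions: the 68% envelope covers truth for close to 68% of bands
(the residual over-coverage of a few percent comes from the mild
nonlinearity of the pH map across the draw range).

## Screening for non-primary carbonate

Primary coralline-algae carbonate shows a positive B/Ca–δ¹¹B trend;
serpulid worm infill is boron-rich (B/Ca ≈ 400 µmol/mol) and isotopically
light (< 20 ‰), so contaminated bands fall below the trend at high B/Ca.
The original exclusions were partly visual (proximity to worm borings);
`screen_records()` replaces that with a reproducible rule: a Theil–Sen
trend of δ¹¹B on B/Ca, then a flag wherever the vertical residual is below
$-k \cdot \mathrm{MAD}$ *and* B/Ca exceeds the dataset median. The
threshold default is $k = 5$, calibrated on the synthetic twin of the
study's two-specimen contamination layout: genuine worm contamination sits
15–25 MAD below the trend while analytical scatter stays within about 4,
so $k = 5$ reproduces exactly the seven known exclusions with no noise
false positives, and still catches mixtures as dilute as 10% worm
carbonate (about 8 MAD). Flagging is one-pass — order-invariant and
idempotent — with an optional two-pass refit mode off by default.
`contamination_fraction()` inverts the two-endmember mass balance for
flagged bands.

## Chronology

Years are assigned by counting seasonal Mg/Ca cycles back from the known
collection year. The transect is smoothed with a centred moving mean
(default window: 1/8 of the dominant cycle length from a periodogram),
linearly detrended, and local maxima with topographic prominence above
0.25 × IQR are taken as annual summer anchors. Two boundary conventions
matter and were genuinely open choices:

* a summer truncated by the growth surface still anchors the collection
  year, but only if the surface value reaches typical summer heights — a
  record that merely starts declining began just after a summer that was
  never recorded;
* a rising tail at the deep end of the transect belongs to a summer the
  transect never reached and is not counted.

With these rules the count is exact on noise-free seasonal signals for
any phase offset, and invariant under uniform rescaling of the distance
axis. `assign_years()` maps milled bands to the year interval holding the
larger share of the band, ties resolving to the younger year.

## Mixing models

Alkalinity, DIC and salinity are conservative and mix linearly by mass
fraction; pH is re-solved for each mixture at a fixed scenario
temperature. The Gulf of Maine endmembers are Warm Slope Water
(2375/2050/36.5), Labrador Slope Water (2200/2050/34) and Scotian Shelf
Water (2150/2000/32) (ALK µmol/kg / DIC µmol/kg / psu). `wsw_sweep()`
trades Warm Slope Water against Labrador Slope Water — the observed
post-1960s exchange — at 8 and 11 °C; `ternary_grid()` covers the full
three-way simplex, optionally at fixed salinity as in contour-plot
presentations.

The river model mixes Penobscot-like river water (ALK 230 µmol/kg) into
seawater (2200/2050/33; pH 8.0 unmixed at the default 10 °C, which is why
10 °C is the default — the paper leaves the temperature unstated). River
DIC defaults to the published pH–DIC pairs (428 µmol/kg at river pH 6.6,
261 at 7.2, linearly interpolated); recomputing DIC from (ALK, pH) with
this package's marine constant set is available but disagrees at pH 6.6
(≈ 333 µmol/kg), because a dilute-water constant formulation was
evidently used for the published values — hence the published pairs are
the default. `river_sensitivity()` repeats the analysis under ±50% river
alkalinity.

One caveat the package surfaces deliberately: with the stated endmembers,
the between-era pH shift (river pH 6.6 → 7.2) reaches 0.2 units at a
river fraction near 29%, well above the 20% the mixing budget argument
requires but below the 50% sometimes quoted; the 50% figure follows only
from linearly extrapolating the 5% response, which ignores the loss of
buffering in dilute mixtures. The package reports the full
carbonate-chemistry answer.

## The synthetic-data generator

`generate_dataset()` forward-models everything the pipeline consumes from
a prescribed pH history, so each stage can be validated against known
truth. The default scenario encodes the study conditions: years
1920–2020; baseline pH oscillating between 7.7 and 7.9 with a
quasi-decadal period drawn once per scenario from 8–12 yr (the archive
describes but does not parameterise this variability, so a fixed-amplitude
sinusoid is used); a +0.2 pH linear ramp over 1980–2000; temperature near
8 °C rising to 11 °C by 2020 with 0.5 °C interannual noise, kept inside
5–13 °C; salinity 30.3 ± 0.5 psu; solution boron concentrations uniform
on 4–40 ng/g; and measurement noise exactly per the published
reproducibility curve. B/Ca is generated on a positive linear trend
against δ¹¹B (slope 0.05 ‰ per µmol/mol, placing primary B/Ca near
210 µmol/mol, scatter 5 µmol/mol — free parameters chosen to resemble
published coralline-algae ranges). Contamination mixes a chosen fraction
of bands toward the worm endmember with a default mass fraction of 0.3:
the observed contaminated sub-samples were frequently too low in δ¹¹B to
invert at all, which requires roughly a third worm carbonate given a
~28 ‰ primary and an 18 ‰ contaminant. Mg/Ca transects are seasonal
sinusoids (150 ± 30 mmol/mol, 280 µm/yr growth, ±30% per-year growth
jitter, noise at 20% of the seasonal amplitude, 20 points per year).

What the generator does *not* emulate — and what passing tests therefore
cannot certify about real archives — includes vital-effect drift,
light/flow modulation of internal pH, non-stationary B/Ca trends between
specimens, spatially correlated growth hiatuses, and real instrumental
series. Parameter-recovery results on synthetic data bound the method's
self-consistency, not its field accuracy.

## Numerical and reproducibility choices

Root finding is deterministic Brent bracketing; all randomness flows from
explicit integer seeds, with per-record draw layouts fixed so results are
bit-stable for a given seed. All pH values are on the total scale;
concentrations in µmol/kg; no pressure correction is applied (samples
were collected at ≤ 10 m). The test suite sizes its simulations to stay
quick while keeping estimates stable: 1,000 random states for the solver
oracle, 200 records × 1,000 draws for envelope coverage, about 10,000
clean synthetic bands for the false-positive bound, and 40–80-year
transects for dating; these sizes are the package's own validation
choices.

## Known limitations

* The calibration covariance is unpublished; independent sampling of
  slope and intercept is an assumption that widens envelopes slightly.
* The seawater δ¹¹B default (39.73 ‰, the local measurement mean) differs
  from the open-ocean compilation value (39.61 ‰) by ~0.02 pH in the
  worked example; both are supported, the local value is the default.
* Screening is calibrated on a synthetic twin of the study layout, not on
  the original measured file.
* Cycle counting has an irreducible ±1-year ambiguity when both transect
  ends truncate a season; the boundary conventions above resolve it
  deterministically and are validated on synthetic transects only.
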