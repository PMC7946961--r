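---
title: "Modelling subdermal solar energy harvesting from ground irradiance data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling subdermal solar energy harvesting from ground irradiance data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subsolar)
```

## The problem

Active implants such as cardiac pacemakers run on primary batteries whose
depletion forces replacement surgery. A photovoltaic module implanted a few
millimetres under the skin can harvest energy from sunlight: the skin blocks
the ultraviolet that ages solar cells, and a modern single-chamber pacemaker
needs less than about 10 µW. Whether such a module actually collects enough
energy depends on where the patient lives, the weather over the year, how
often the implant site sees the sun, the patient's skin pigmentation, and the
spectral response of the cell. `subsolar` chains these pieces into one
pipeline:

1. **Ground irradiance** — measured global horizontal irradiance (GHI) time
   series at minute cadence (generic CSV, a documented subset of the BSRN
   station-to-archive format), or a seedable synthetic-weather generator.
2. **Solar geometry** — the sun's zenith angle $\theta$ from the NOAA
   low-precision formulas, and the relative atmospheric path length
   $\mathrm{AM} = 1/\cos\theta$.
3. **Spectral shape** — a normalized clear-sky spectral shape as a function
   of AM, scaled so its 400–1200 nm integral equals the measured broadband
   GHI.
4. **Skin optics** — the fraction $\zeta(\lambda)$ of surface irradiance
   reaching the implant plane, by Monte Carlo photon transport through a
   layered skin model (dark, phototype VI) or from a measured transmission
   table (light, phototype I/II).
5. **Photovoltaics** — short-circuit current from the EQE-weighted photon
   flux, irradiance-dependent open-circuit voltage, and
   $P_\mathrm{out} = FF \cdot V_{OC} \cdot I_{SC} \cdot A$.
6. **Exposure and aggregation** — daily time-slot profiles decide when the
   implant is irradiated; instantaneous powers aggregate into monthly and
   yearly means normalized to full elapsed time, with pacemaker-threshold
   flags.

## The model, step by step

### Solar geometry

`solar_zenith()` implements the NOAA *General Solar Position Calculations*
Fourier-series approximation (fractional year → equation of time,
declination, hour angle), valid 1901–2099 to a few hundredths of a degree —
far below the granularity that matters here. All computation is in UTC; the
"local civil time" used by exposure slots is UTC + `round(longitude/15°)`
hours with no daylight-saving rule. This keeps results reproducible without
a timezone database; slot clock times are nominal behavioural assumptions
anyway, so a constant sub-hour offset is immaterial.

`air_mass()` is the plain plane-parallel secant, $1/\cos\theta$, not a
refraction-corrected formula such as Kasten–Young. Past the default cutoff
of $\theta = 85°$ the secant diverges while real irradiance becomes
negligible, so the result carries a "no direct sun" flag instead of a
number; pipeline records with positive GHI but a flagged AM (twilight,
purely diffuse light) are skipped with a warning rather than modelled.

### Clear-sky spectral shape

Ground stations report broadband power only, so the spectral composition
must be modelled. The pipeline deliberately uses the atmosphere model *only
as a shape source*: every emitted shape is normalized to unit integral over
400–1200 nm and then multiplied by the measured GHI, so broadband energy is
conserved record by record (this closure is tested to 10⁻⁶ relative). Two
providers are available:

* **parametric** — $E_\mathrm{ext}(\lambda)\,
  T_\mathrm{Rayleigh}^{AM}\, T_\mathrm{aerosol}^{AM}\,
  T_\mathrm{abs}(\lambda, AM)$ with a 5772 K Planck extraterrestrial shape,
  the SPCTRAL2 Rayleigh optical depth, an Ångström aerosol term
  ($\alpha = 1.14$, $\beta = 0.1$), and a simplified ozone-Chappuis +
  water-band absorption model with the SPCTRAL2 saturating band form
  (precipitable water 1.4 cm, ozone 0.34 atm-cm). These defaults describe a
  generic mid-latitude clear atmosphere; they are assumptions, not fits.
* **table** — linear interpolation in AM between normalized shapes at nodes
  AM ∈ {1, 1.5, 2, 3, 5, 10}, renormalized after interpolation. The default
  table is generated once from the parametric model; users with externally
  computed spectra (e.g. from a full radiative-transfer code such as SMARTS)
  can supply their own table. Above the last node the shape is clamped with
  a warning — at AM > 10 the absolute irradiance is tiny, so the shape error
  is inconsequential.

Cloudy skies reuse the clear-sky shape. This is a known limitation of the
approach: clouds redden/flatten spectra, but the broadband level (which
clouds dominate) always comes from the measurement. The diffuse/direct split
is likewise ignored; the scaled shape represents global irradiance on the
horizontal plane, matching pyranometer geometry.

### Skin optics

The skin is a laterally infinite 1-D layered slab — the measured quantity is
a planar transmission fraction under uniform irradiance, so no finite-beam
radial tracking is needed. The bundled dark-skin (phototype VI) model has
epidermis 0.1 mm, dermis 1.4 mm, subcutis 1.0 mm (total 2.5 mm, the
published total; the split is a documented default), with per-layer
absorption from chromophore volume fractions,
$\mu_a = \sum_i VF_i\, \mu_{a,i}(\lambda)$, reduced scattering
$\mu_s' = a(\lambda/500\,\mathrm{nm})^{-b}$, anisotropy $g = 0.9$
(Henyey–Greenstein), and refractive indices 1.34/1.41/1.41. The published
subcutis volume fractions sum to 1.0945 > 1; they are used exactly as
printed and a validation warning surfaces the fact. Chromophore spectra
(whole blood at 150 g/L haemoglobin and 75% saturation, water, fat,
melanosome, pigment-free baseline) are tabulated/parametric approximations
from the standard tissue-optics compilations, bundled in code and
overridable per-chromophore by CSV.

Transport is classic weighted-photon MCML: collimated normal launch with
specular Fresnel loss at the air interface, exponential steps with
$\mu_t = \mu_a + \mu_s$ where $\mu_s = \mu_s'/(1-g)$, fractional absorption
deposition, Fresnel reflection/refraction at internal index mismatches, and
Russian roulette below weight 10⁻⁴ with survival chance 0.1. The implant at
depth `scd` (default 2.5 mm) is a perfectly absorbing plane; $\zeta$ is the
weight fraction absorbed there, with a per-wavelength standard error from
photon-level variance. A free-passage (first-crossing) scoring mode is
available behind `plane = "transparent"` for users who prefer a fluence
reading. Each wavelength runs on its own counter-seeded xoshiro256+
substream, so a spectrum is bit-reproducible for a given seed and
wavelengths are statistically independent.

Russian roulette conserves weight only in expectation. The returned ledger
therefore carries an explicit `roulette_net` term; including it, every run's
ledger sums to the launched weight to floating-point accuracy, and the four
physical categories alone (specular, diffuse reflection, tissue absorption,
plane absorption) agree with unity to the roulette noise floor, which at the
default 10⁵ photons is below 10⁻⁶.

The light-skin route bypasses the Monte Carlo entirely:
`skin_type_i_ii()` loads a bundled *synthetic* transmission table — a smooth
curve matching the qualitative behaviour of published phototype I/II
measurements through 2.5 mm (a few percent in the blue rising to tens of
percent in the near infrared, with a water dip near 970 nm). It is labelled
synthetic in its filename and should be replaced with measured data for any
quantitative patient-specific use.

### Photovoltaic model

$$I_{SC} = \int_{400}^{1200} \phi(\lambda)\, EQE(\lambda)\, q\, d\lambda,
\qquad \phi(\lambda) = \frac{E(\lambda)\,\zeta(\lambda)\,\lambda}{h c},$$

integrated by trapezoid on the wavelength grid (default 5 nm; refining to
1 nm moves $I_{SC}$ by < 0.5% for smooth spectra). $V_{OC}$ interpolates the
cell's voltage-vs-irradiance curve linearly in $\log$ irradiance — the
diode-physics scaling — evaluated at the *broadband subdermal fluence* of
each record; below the lowest node the slope is extrapolated and floored at
0 V, above the highest node the value is clamped, and zero fluence gives
0 V. Temperature dependence is ignored (the implant is near-isothermal).
Fill factor defaults to 0.8 and active area to 3.6 cm², the reference
implantable module. Whether to re-evaluate $V_{OC}$ per time step or use a
fixed representative value was an open choice; per-step evaluation was
selected as the physically faithful reading, and its only effect is the mild
sub-linearity of power in GHI.

The two bundled cells (standard monocrystalline silicon; double-junction
GaAs-GaInNAs with enhanced 650–1200 nm response, better matched to the
red-shifted subdermal spectrum) ship as synthetic CSV approximations of
published datasheet/figure shapes and are fully user-replaceable.

### Exposure profiles and aggregation

Seven canonical daily routines are bundled: five weekday profiles
(workaholic 10 min/day in the dark margins of the day; office worker with
only a 30-min commute; office worker with a 10-min midday lunch walk; the
same plus an evening free-time hour; outside worker 4.5 h/day) and two
weekend profiles (active 4.5 h/day, passive 5 min/day). Only the daily
totals are normative from the published sources; the clock times are
documented approximations, replaceable via `load_profiles()`. Saturday and
Sunday are the weekend everywhere (proleptic Gregorian).

Mean powers are **energy over full elapsed time** — nights, weekends and
unexposed hours included — via trapezoid integration over the record
cadence; a month with under 50% of its expected records is flagged missing
and excluded (the 50% rule is this package's convention; archives do not
state one). The yearly mean is total energy over the full year, not the
mean of monthly means. This convention is what makes weekday and weekend
profile means additive: `mix_weekend()` combines them as
`weekday + (n_active·active + (n_weekend−n_active)·passive)/n_weekend`, and
with the published Payerne 2015 yearly means (48.87/58.60 µW weekday,
102.61/1.08 µW weekends, 104 weekend days of which 12 active) it reproduces
the published combined values 61.66 and 71.39 µW to two decimals — the
validation that fixed the convention.

### Synthetic weather generator

`synthesize_series()` emulates a BSRN-like station at 1–3-min cadence:
$GHI(t) = E_0 \cos\theta(t)\, \tau^{AM(t)}\, c(t)$ with $E_0 = 1361$ W m⁻²,
broadband clear-sky transmittance $\tau = 0.75$ (a typical clear-sky
beam+diffuse fraction at AM 1), and a cloud factor $c(t) \in (0,1]$:
a first-order autoregressive Gaussian on the log scale, exponentiated and
capped at 1, with mean clearness 0.7, log-sd 0.5 and a 120-min correlation
time — values chosen once as a plausible temperate-climate texture. The
generator is exactly zero when the sun is below the horizon, never exceeds
$E_0$, and is bit-reproducible per seed. What it does **not** emulate:
spectral effects of clouds, direct/diffuse partitioning, sensor artefacts
beyond the negative nighttime offsets the readers clamp, and real
inter-annual weather statistics. Tests passing on synthetic years therefore
validate the pipeline's mechanics and scalings, not climatological accuracy
at any real site.

## Numerical choices

* Trapezoid quadrature everywhere (wavelength and time), via `pracma::trapz`
  or its explicit weight form; grids are validated strictly increasing with
  exact 400/1200 nm bounds.
* Linear interpolation in AM between table shapes, renormalized afterwards,
  so normalization is exact at every query point and shapes vary
  continuously in AM.
* VOC interpolation in log-irradiance, with the floor/clamp rules above;
  ties and degenerate single-node curves return that node's voltage.
* MC defaults: 10⁵ photons per wavelength, roulette threshold 10⁻⁴ with
  survival 0.1, one substream per wavelength derived from
  `seed * 100003 + index`. Photon counts below 10³ are rejected.
* Exposure slots are half-open `[start, end)` minutes, so abutting slots do
  not double-count and a full day of flags sums exactly to the declared
  daily total.
* Problem sizes used in the shipped tests: coarse wavelength grids
  (25–100 nm) and 10³–10⁵ photons for MC properties; one full synthetic year
  at 3-min cadence (175,200 records) for the aggregation properties. A full
  year times seven profiles evaluates in a few seconds on one core.

## Known limitations

* Clear-sky spectral shape under all skies; no cloud spectral model.
* No refraction, horizon masking, or tilt geometry; the implant is assumed
  sun-facing whenever its profile says "exposed" — deliberately short
  exposure slots compensate for this optimistic assumption.
* The bundled EQE/VOC/transmission curves are synthetic approximations for
  demonstration and testing; quantitative device studies must substitute
  measured curves.
* 1-D slab optics: no lateral heterogeneity, vessels, or curvature;
  no polarization, fluorescence or thermal transport.
* Indoor/artificial light is out of scope, which biases harvested energy
  low for mostly-indoor routines.

## A worked example

```{r example, eval = FALSE}
meta <- station_meta("SYN", 46.82, 6.94, 490)
series <- synthesize_series(meta, 2015, step = 3, seed = 1)

tab <- series |>
  run_station(skin_type_i_ii(), bundled_cell("mono_si"), default_profiles()) |>
  power_summary()

threshold_report(tab)   # pass/fail against the 10 uW pacemaker requirement
autoplot(tab)           # monthly means per profile, log scale
```
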