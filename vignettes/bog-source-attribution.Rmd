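---
title: "Attributing bog CO2 fluxes to microforms and encroaching birch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing bog CO2 fluxes to microforms and encroaching birch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bogflux)
```

## The procedure and its assumptions

`bogflux` joins two observation scales of peatland CO₂ exchange. An eddy
covariance (EC) tower integrates the net flux over its footprint every half
hour but cannot say which surface unit produced it. Closed chambers resolve
individual microforms — hummocks, hollows, their near-tree (T) and distant
(nT) variants — and enclosed birch branches, but only on campaign days. The
package's central move, the *source contribution*, uses the chamber side
only for **relative** information: campaign-wise empirical models per
source are integrated to daily flux densities, multiplied by the source's
areal share (or, for the branch source, the current leaf area index, LAI),
normalised to relative weights, and those weights distribute the day's EC
gross primary production (GPP) and ecosystem respiration (Reco).

The method therefore assumes:

1. the chamber plots are representative of their microform within the EC
   footprint (areal shares are inputs, not estimated here);
2. temperature and light are the dominant short-term controls, so a
   Lloyd–Taylor respiration curve and a rectangular-hyperbola light
   response capture the campaign-scale behaviour of each source;
3. relative differences between sources are more robust than absolute
   chamber fluxes — the EC total is taken as authoritative and the
   partition conserves it exactly, by construction, every day;
4. the two methods are sufficiently correlated, which the package checks
   explicitly (`build_groups()`, `match_ec()`, `compare_methods()`) before
   partitioning is trusted.

Signs are atmospheric everywhere: NEE = GPP + Reco, GPP ≤ 0, Reco ≥ 0.

## Model forms and fitting

Respiration per source follows Lloyd–Taylor with the classical fixed pole,

$$R_{eco}(T) = R_{ref}\,\exp\!\Big(E_0\big(\tfrac{1}{T_{ref}-T_0} -
\tfrac{1}{T-T_0}\big)\Big),\qquad T_{ref}=283.15\,K,\; T_0=227.13\,K,$$

with soil temperature driving ground microforms and air temperature the
branch source (its environment is only measured at chamber level). GPP
follows the rectangular hyperbola
$GPP(PAR) = -\alpha\,PAR\,GP_{max}/(\alpha\,PAR + GP_{max})$.
Both fits are nonlinear least squares with non-negativity constraints and
log-linearised (Reco) or slope-based (GPP) starting values. A campaign fit
is refused — not forced — when fewer than 3 observations or less than 2 °C
of temperature spread are available; refused campaigns inherit the nearest
successful campaign of the same source, flagged in the output. A source
with no successful fit at all receives a flagged zero model, which the
partition step then treats as zero weight (with an areal-share fallback if
the EC flux is nonzero, so conservation still holds). Between campaign
midpoints, parameters are interpolated linearly in time by default
(`interpolation = "constant"` selects per-campaign blocks); both ends are
held constant beyond the first/last campaign.

## Chamber flux computation

Concentration traces are regressed in a moving window (defaults: 60 s
window, 5 s step, 10 s deadband — chosen to fit the shortest 120 s traces;
the underlying closure protocol leaves them open), the window with maximal
r² wins, ties go to the earliest window. The ideal-gas conversion uses the
chamber's own headspace temperature and pressure; branch fluxes are
normalised to enclosed leaf area (`leaf_count` × a campaign-level mean leaf
area, default 12 cm²/leaf; per-leaf variance is deliberately ignored).

The minimal detectable flux (MDF) is the flux corresponding to
$z\,\sigma\sqrt{12(n-1)/(n(n+1)L^2)}$ — z times the exact OLS slope
standard error for n equidistant samples spanning L seconds of white
analyzer noise σ. The literature formula this parameterises is not fully
standardised, so z (default 1.96) and σ are configuration, and no
acceptance result depends on them. Sub-MDF fluxes are set to zero and
flagged, never dropped. A morning QC rule (transparent-chamber fluxes
before 10:00 exceeding 3 × the plot's campaign median magnitude) removes
implausible dew/turbulence artefacts; both numbers are configuration with
these documented defaults, since the underlying criterion is reported only
qualitatively in the field.

Transparent chambers attenuate PAR by 5%; the generator applies the
attenuation when producing traces and `process_traces()` corrects the
recorded PAR by the same factor, which makes the correction itself
testable.

## Pairing thresholds

Composites and EC matches obey a fixed rule set: PAR ≥ 150 W m⁻² for
light-dependent fluxes, relative ΔPAR ≤ 20%, ΔT_air ≤ 2 °C (NEE/GPP),
ΔT_soil ≤ 2 °C (Reco), 90 min chamber-chamber tolerance, ±4 days and ±2 h
time-of-day for EC pairing. Chamber PAR (µmol m⁻² s⁻¹) is converted with
4.57 µmol J⁻¹ where the W m⁻² threshold applies. Choices the rule set
leaves open, decided here: matching is greedy one-to-one ordered by match
quality (no observation reuse within a flux kind); "same daytime ± 2 h" is
clock-time difference; the relative PAR difference is taken against the
mean of the two values; a vegetation-period (May–October) composite at the
tree site requires a branch member by default (`strict = FALSE` keeps the
group without it). The rainbow linearity test is implemented in-package
(central 50% subsample, ordered by EC flux magnitude) since its settings
are not standardised either.

## The synthetic world

The generator emulates the statistical structure the analysis assumes, with
defaults stated once and not revisited:

* **Sites.** An open site (hollow 56.5%, hummock 43.5% of ground area,
  mean water level −0.14 m) and a tree site (four ground microforms,
  hummocks 61.9%, mean water level −0.21 m, plus a branch source weighted
  by a biweekly LAI series peaking at 1.0 in mid-July). Model parameters
  per source echo published annual magnitudes: hummocks respire roughly
  twice as much as hollows, near-tree variants respire more than distant
  ones, the branch source dominates uptake per unit leaf area.
* **Drivers.** Half-hourly sinusoidal annual and diurnal cycles with AR(1)
  noise; 9.9 °C annual mean air temperature, damped and lagged soil
  temperature, day-length-limited PAR with autocorrelated cloudiness
  (exactly zero at night), water level around the site mean.
* **EC records.** The area/LAI-weighted sum of the true source fluxes,
  with component-wise Gaussian noise (so NEE = GPP + Reco and the sign
  discipline survive noise), 0/1/2 quality flags, random gaps (default
  10%, echoing winter power losses) and a gap-free "gap-filled" twin that
  stands in for the out-of-scope gap-filling step.
* **Campaigns.** 14 campaigns over the hydrological year (monthly in
  winter, ~3.5-weekly in the growing season), four closure slots per plot
  from pre-dawn to mid-afternoon, transparent immediately followed by
  opaque in the same half-hour, 1 Hz traces of 120–180 s whose slope is the
  exact ideal-gas inverse of the true flux plus white analyzer noise.
  Branch closures are emitted year-round with the leaf count floored at
  one (emulating retained-leaf measurements); outside the vegetation
  period the LAI weight annihilates their contribution anyway. Chamber
  geometry defaults (0.3 m³ over 0.75 m²; 40 cm × 9.5 cm branch cylinder)
  are configuration because real closure protocols vary.

What the generator does **not** emulate: footprint heterogeneity and its
mismatch with plot placement, instrument drift and spectroscopic
cross-sensitivity, advection and storage errors in EC, non-linear chamber
saturation, plant phenology beyond the LAI series, and any water-level
control on CO₂ fluxes. A green end-to-end test therefore establishes that
the chain is implemented consistently — inversion, fitting, weighting,
conservation — not that the method is unbiased on real data, where the
chamber/EC correlation step exists precisely to measure that.

## Numerical choices

* Window tie-breaks are exact (earliest window at equal r²); a
  zero-variance window counts as perfectly fit.
* Fit refusals and fallbacks are flags, never silent repairs.
* Partition conservation is exact to floating point; the zero-weight
  fallback (areal shares) only triggers when the chamber models predict no
  flux while EC reports one, and flags the day.
* Percentage shares are computed on absolute values, so GPP shares are
  positive; with mixed-sign NEE columns the per-source NEE shares can
  individually exceed 100 within a site, which is the standard
  presentation.
* Balance mass ratios default to the integer molar ratios 44/12 and 16/12
  and GWP-100 = 27; both are configurable (28 is the other commonly used
  GWP value). N₂O is fixed at zero: the emulated system was never
  fertilised and is fully vegetated.
* Quadrature is used for all SD propagation; reported uncertainties
  therefore assume independent errors.

## Known limitations

* The published tables shipped as fixtures contain two internal
  inconsistencies (an open-site per-source Reco sum differing from the EC
  total, and one tree-site share cell); `validate_tables()` reports these
  informationally instead of asserting them — see `?validate_tables`.
* Campaign-parameter interpolation has no uncertainty band; annual
  partitioned sums carry no SD from the chamber side.
* CH₄ enters only as annual scalar inputs per microform; its modelling is
  out of scope.
* The EC "gap-filled" twin is an idealisation; real gap-filling adds
  structured uncertainty that the synthetic world does not represent.
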