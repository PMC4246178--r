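---
title: "A dynamic functional-structural model of a tomato canopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic functional-structural model of a tomato canopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tomcan` simulates a single-stem greenhouse tomato canopy day by day:
climate-driven organ growth, explicit 3D canopy geometry, Monte-Carlo light
transport, and light-use-efficiency-based dry-mass production. Its purpose
is the quantification of how architectural traits — leaf insertion angle,
midrib curvature, internode length, leaflet shape and arrangement — affect
canopy light interception and shoot dry mass under contrasting temperature
regimes.

## The model

### Organ growth

All growth is driven by daily means of air temperature $T$ (°C), vapour
pressure deficit VPD (kPa) and photosynthetic photon flux PAR
(µmol m⁻² s⁻¹). Thermal time $TS$ (°Cd) accrues per organ as
$\max(T - T_b, 0)$ from the day of its appearance.

The daily elongation of the leaf at rank $r$ is a product of three factors:

$$E_l = E_{l,\max}(T, \mathrm{VPD}) \cdot
        e^{-\tfrac12\left(\frac{TS - TS_{l,\max}}{h_l}\right)^2} \cdot
        e^{-\tfrac12\left(\frac{\min(r,13) - R_{\max}}{h}\right)^2}$$

with $E_{l,\max} = (T - T_b)\,(a_{El} + b_{El}\,\mathrm{VPD})$ between the
base temperature $T_b$ = 6.8 °C and the optimum $T_{opt}$; above the
optimum the rate declines at the same rate as it rises below it (the
temperature term mirrors about $T_{opt}$) and is clamped at zero. Leaves
above rank 13 elongate like rank-13 leaves. Leaf length maps to area
through a power law $A_l = a_{Al} L_l^{g}$; insertion angle follows a
saturating curve $\theta = a_\theta (1 - e^{-b_\theta L_l})$ and midrib
curvature a two-branch linear function of length with the upper branch's
intercept derived so the branches meet continuously at 50 cm.

Leaves appear at the rate $a_r \ln T - b_r$ (leaf d⁻¹), capped above
30 °C at its 30 °C value (the cap value is derived, not a free parameter,
so the rate is continuous). The number of emitted leaves is the integer
part of the accumulated rate; each new leaf brings its subtending
internode. Internodes elongate as
$(T - T_{bi})(a_{Ei} - b_{Ei}\,\mathrm{PAR})$ times their own thermal-time
bell, and thicken linearly in thermal time. A leaf whose thermal age
exceeds $TS_{l,sen}$ is flagged senescent: it stops producing dry mass but
keeps its area and continues to shade.

Within a day the order of operations is: thermal time first, then
elongation evaluated at the updated thermal age, then shape updates, then
senescence, and finally leaf emission (new organs start the next day at
zero thermal age). This order is a definitional choice; the test suite's
independent cumulative-sum oracle uses the same convention.

### Geometry

Each leaf is a four-segment rachis polyline leaving the stem at angle
$\theta$ from the stem axis and bending by the three curvature angles
$\alpha_1, \alpha_2, \alpha_3$ (reference ratio 1:2:2, base to tip) at the
lateral-leaflet nodes. Seven flat rhombus leaflets — three opposite pairs
plus a terminal leaflet — carry the lamina with reference area fractions
0.12 : 0.17 : 0.13 : 0.16 (laterals per side) and length:width ratio 1.33,
so the lamina mesh area equals the modelled leaf area exactly. Internodes
and rachis segments are open cylinders. Leaves stack with a 144°
phyllotaxis; the replicate protocol jitters each step uniformly in ±10°.

Leaves near the ground that would droop below it are handled by rigid
rotations: rachis segments rotate up just enough to rest on the ground and
leaflets tilt about their base axis, so lamina area is preserved rather
than clipped. The canopy is a 4 × 4 grid at 1 m spacing over a white
ground rectangle reflecting 80 % of incident light; only the four central
(focal) plants are analysed, which keeps edge effects out of the reported
means. Four fully absorbing 1 m² virtual sensors sit just above the ground
among the focal plants on designated sensor days only (days 28, 44, 56,
64), so they never shade the ground on other days.

### Light

A path tracer (C++, BVH-accelerated) launches a stratified or
low-discrepancy budget of rays downward from an emitter plane above the
scene. The default sky is an overcast uniform-radiance hemisphere
(cosine-weighted directions), which is the natural single-trace stand-in
for a daily light integral; a collimated mode exists for oracle tests. At
each hit the ray deposits $1 - R - T$ of its weight for the struck side
(adaxial 7.3 % reflectance / 2.4 % transmittance, abaxial 12.7 % / 2.5 %)
and continues by ideal-diffuse reflection or transmission; paths stop after
5 bounces or below a 10⁻³ weight floor, with the residual booked as
escaped so that emitted = absorbed + escaped holds to numerical precision.
Per-leaf absorbed flux $I_{abs}$ (J m⁻² d⁻¹) is the surface's absorbed
energy divided by its lamina area. Canopy transmission $Q_t/Q_0$ is the
mean sensor flux per m² over the incident flux per m², and the extinction
coefficient follows Beer–Lambert, $k = -\ln(Q_t/Q_0)/\mathrm{LAI}$.

The engine is validated against closed forms (full interception by a black
leaf, 20 % absorption by bare 80 %-reflective ground) and against the
classical Poisson-canopy limit: randomly scattered small horizontal black
leaves under vertical light must yield $k = 1$; the packaged test fits
$k$ over LAI ∈ {0.5, 1, 2} and requires 1.00 ± 0.05.

### Production

Daily leaf dry mass is
$W_l = I_{abs}\,\varepsilon(I_{abs})\,f_T\,A_l$ with the light-use
efficiency $\varepsilon(I) = \varepsilon_{\min} + (\varepsilon_{\max} -
\varepsilon_{\min})\,e^{-I/I_c}$ and the temperature response
$f_T = 1 - \kappa (T - T^*)^2$ ($\kappa$ = 0.0013 °C⁻², $T^*$ = 25 °C),
clamped at zero. Senescent leaves contribute nothing. Plant dry mass is
the running sum over leaves and days, and shoot mass is a fixed fraction
$W_s = \mu W_p$. For architectural trait analyses the temperature factor
is disabled, isolating the purely architectural signal. The published unit
of $\varepsilon$ mixes CO₂ and dry mass; rather than converting silently,
the factor `co2_to_dm` (default 1) exposes the ambiguity.

## Parameters: what is known and what is placeholder

The coefficients printed in the source literature ship as-is: $T_b$,
$\kappa$, $T^*$, the leaf optics, ground reflectance, phyllotaxis and its
jitter, the reference curvature ratio, leaflet fractions and length:width
ratio, the canopy layout and sensor days. Every fitted coefficient that is
not publicly printed is a documented placeholder, tagged `"placeholder"`
in the machine-readable provenance map and overridable through a YAML
file. Placeholders were chosen once against published, printed indicators:

* final rank-8 leaf length 35–45 cm and plant height 1.5–2.5 m at 77 days
  under the low-temperature regime;
* fewer than three leaves difference between the temperature regimes;
* an LAI trajectory consistent with inverting the published transmission
  and extinction table (LAI ≈ 0.56 → 2.5 between days 28 and 63);
* a strongly saturating daily light response ($I_c$ = 1.5 MJ m⁻² d⁻¹),
  as expected for canopy-level tomato photosynthesis.

Plants start with five emitted leaves (`initial_leaf_number = 5`),
matching the usual transplanting stage of greenhouse tomato at the
first-true-leaf clock origin.

## The synthetic climate

`synthesize_climate()` emulates two greenhouse regimes: LT (22/18 °C
day/night set points) and HT (32/28 °C). The daily mean is the 16 h/8 h
weighted set-point mean plus ventilation noise bounded in ±2 °C; VPD is
bounded in [0.5, 2.5] kPa; PAR ramps seasonally with bounded noise and is
identical across regimes for the same seed (the regimes differ in
temperature, not light). Noise substreams do not depend on the regime, so
the HT series is strictly warmer than the LT series day by day — by
construction, not by chance. `packaged_climate()` freezes the 77-day
fixture (seed 1) used by the packaged evaluation runs.

What the generator does *not* emulate: weather autocorrelation, cloudy-day
light collapses, hourly dynamics (the model runs on daily means by
design), and the correlation between temperature and VPD spikes during
ventilation. Tests passing on these fixtures therefore demonstrate model
mechanics and reproducibility, not predictive skill on measured greenhouse
data — evaluating against measurements requires loading a real climate CSV
and a fitted parameter file.

## Numerical choices

* Daily time step throughout; one light trace per day
  (20 000 rays by default; sweeps use reduced budgets of 4 000–8 000).
* Per-ray-seeded PCG32 streams make traces bit-reproducible and
  independent of scheduling; named substreams derived from the master seed
  separate the phyllotaxis jitter (varied across replicates) from the sky
  sampler (held fixed), mirroring the replicate protocol of randomized
  phyllotaxis.
* Monte-Carlo standard errors come from 16 interleaved ray batches.
* Cylinders tessellate at 6 facets (configurable); rhombus leaflets are
  exact, so lamina area carries no tessellation error.
* Degenerate inputs: zero-length leaves produce empty meshes; an empty
  climate yields an empty run; a zero-light day produces zero dry mass.

## Problem sizes

The packaged evaluation runs use the full 16-plant canopy over 77 days.
Five replicates at 20 000 rays/day complete in a few minutes on one core;
the twelve-scenario trait sweep at 4 000 rays/day takes a similar time.
These sizes were chosen so the full suite runs comfortably on a laptop
while keeping replicate noise of final shoot dry mass well below 1 %.

## Known limitations

* The internode-length sensitivity of shoot dry mass is muted compared to
  leaf angle. Under a daily-integrated overcast sky, rescaling the
  vertical spacing of leaves redistributes little diffuse light, and
  because growth is architecture-independent there is no compounding
  feedback. Sun-resolved (hourly, oblique-beam) light transport would be
  expected to strengthen this trait's effect; it is out of scope here.
* The temperature-regime interaction (the cool, denser canopy being more
  trait-sensitive than the warm one) is reproduced in direction but
  amounts to only about one percentage point of final shoot dry mass for
  leaf angle on the packaged fixtures, because the synthetic regimes
  contrast less in leaf area than measured greenhouses do; resolving the
  comparison requires the full ray budget.
* Trusses, fruits, side shoots, leaf abscission and light-quality
  (red:far-red) responses are not modelled.
* The light model is single-band (PAR); no spectral resolution.
* Growth does not respond to light interception, so carbon limitation of
  expansion under deep shade is not represented.
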