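---
title: "Modelling nonstomatal control of transpiration in the outside-xylem zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nonstomatal control of transpiration in the outside-xylem zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxzhydro)
```

## The problem

Classical gas-exchange analysis treats stomata as the only meaningful
resistance between the water inside a leaf and the atmosphere. Three linked
assumptions follow: the tissue upstream of the substomatal cavities (the
outside-xylem zone, OXZ — bundle sheath, mesophyll and intercellular air
spaces) is hydraulically transparent; the air inside the leaf is therefore
saturated at leaf temperature; and the symplasm and apoplasm of the
mesophyll sit near local equilibrium. Nanoreporter measurements of water
potential in the apoplast of intact transpiring maize leaves contradict all
three under moderate drought: the OXZ conductance collapses far above the
turgor loss point, the substomatal air undersaturates dramatically
(equivalent relative humidity near 0.92, i.e. around −12 MPa), and turgid
cells sit next to deeply dried cell walls — a symplasm–apoplasm
disequilibrium of ten megapascals across a plasma membrane.

`oxzhydro` packages the quantitative machinery needed to work with these
observations: the psychrometric conversions, the conductance analytics that
turn paired gas-exchange and water-potential readings into partitioned
resistances, a two-compartment transport model of the OXZ with a variable
membrane conductance, the fitting machinery for that membrane law, and a
synthetic-data layer (measurement campaigns and FRET-style images) so that
every stage is testable without access to raw instrument data.

## Psychrometrics

Water potential and equivalent relative humidity are tied by the Kelvin
relation $h = \exp(\psi \bar V_w / R T)$; at 25 °C the scale factor
$RT/\bar V_w$ is ≈137 MPa, so −10 MPa corresponds to $h \approx 0.93$.
Saturation vapor pressure uses the Tetens formula
$e_{sat} = 0.6108\,\exp(17.27\,T_c/(T_c+237.3))$ kPa — the standard choice
in leaf gas exchange; a Buck variant is available behind the `formula`
argument and differs by <0.3% in range. Ambient mole fraction follows from
the leaf-to-air vapor pressure deficit as $w_a = (e_{sat}(T_l) -
\mathrm{VPD})/P$. Small positive potentials (up to +0.1 MPa) are accepted
with a warning as measurement noise and never clamped.

A practical consequence worth knowing: campaign VPDs reach 4.82 kPa, which
exceeds saturation at 25 °C (3.17 kPa). Conversions therefore default to
25 °C only for standalone use; model runs default to 30 °C and the
synthetic campaign to 33 °C, the coolest round temperature at which the
entire VPD range stays below saturation.

## Conductance analytics

For each measurement the package computes, on mole-fraction driving forces:

* $g_{oxz} = (E_{ad}+E_{ab})/(w_{xyl}-w_{ssc}^{ad})$ — the effective OXZ
  conductance between the xylem-equilibrated reading (taped leaf region)
  and the substomatal reading (untaped region);
* $g_s = E\,(1-(w_i+w_a)/2)/(w_i-w_a)$ — stomatal conductance corrected
  for interior undersaturation, with the measured $w_i$ in place of
  $w_{sat}(T_l)$ and the standard cuvette mass-flow factor;
* $g_s^{sat} = E/(w_{sat}(T_l)-w_a)$ — the conventional (Gaastra)
  estimate, kept deliberately without the mass-flow factor, exactly as the
  classical formula is written.

From these, three phenotypes of nonstomatal control: the relative
undersaturation $\delta w = (w_{sat}-w_{ssc})/(w_{sat}-w_a)$, the relative
error of the conventional conductance $\delta g_s = (g_s - g_s^{sat})/g_s$,
and the relative gain in intrinsic water-use efficiency $\delta iWUE = 1 -
E/E_{sat}$ with $E_{sat} = g_s (w_{sat}-w_a)$, the transpiration a
saturated interior would sustain at the same corrected $g_s$. Assimilation
cancels from $\delta iWUE$ under this convention, which makes it
algebraically identical to $\delta g_s$; both equal $\delta w$ exactly when
the mass-flow factor is dropped and agree with it to within
$(w_i+w_a)/2 \lesssim 5\%$ otherwise. This residual is also why
$\delta g_s$ does not reach exactly zero at a saturated interior: the two
conventions it compares differ by that factor even then. The alternative
convention $iWUE = A/g_s$ is available behind the `iwue_convention` flag.

Records with physically impossible driving forces ($w_{xyl} \le w_{ssc}$ or
$w_i \le w_a$ — possible under measurement noise) yield missing metrics and
a warning, never a dropped row or an exception: batch analyses keep their
record count. Binned summaries use the campaign's stated edges (ψ_xyl from
0 to −2 MPa in 0.4 MPa steps; VPD 2.66/3.25/3.75/4.25/4.82 kPa), with
shared edges assigned to the lower-stress bin so a record at exactly
−0.4 MPa falls in the 0 to −0.4 bin.

## The two-compartment OXZ model

The transport model (`solve_steady_state()`) is a pseudo-one-dimensional,
isothermal, steady-state resistor network across the leaf thickness with
two coupled continua:

* a **cell-to-cell path** with axial conductivity $k_{c\text{-}c}$ (mol
  m⁻¹ s⁻¹ MPa⁻¹ per leaf area), Dirichlet-pinned to $\psi_{xyl}$ at the
  xylem plane (mid-thickness by default) and closed at both epidermes;
* an **apoplasmic/vapor path** with axial conductivity $k_{vap}$, fed only
  through the plasma membrane and drained through stomatal Robin
  conditions at each surface, flux $g_s\,(w(\psi)-w_a)$ per surface.

The paths exchange water at every depth through the membrane term
$a_{int}\,\kappa_{mem}\,(\psi_{cc}-\psi_{apo})$, where $a_{int}$ is the
symplasm–apoplasm interfacial area per leaf volume and $\kappa_{mem}$ is
the membrane conductance per interfacial area. $\kappa_{mem}$ follows a
bounded four-parameter logistic of the *upstream* xylem potential,

$$\kappa_{mem}(\psi_{xyl}) = \kappa_{min} +
  \frac{\kappa_{max}-\kappa_{min}}{1+\exp((\psi_{50}-\psi_{xyl})/s)},$$

evaluated once per solve — a deliberate choice that keeps the discrete
system linear and mirrors the idea that membranes respond to the plant's
source water status rather than to the local potential they straddle.

### Numerical choices

The discretization is vertex-centred finite volume on $2n+1$ nodes
($n$ = 50 layers per half-leaf by default), with half-cells at the
surfaces, so mass conservation is exact by construction: the summed
membrane exchange equals the summed surface flux to machine precision.
Inside the solver the vapor path uses the linearized humidity
$w = w_{sat}(1+\psi \bar V_w/RT)$, which is within 0.4% of the exact
Kelvin relation down to −10 MPa and makes the system a single sparse
linear solve (no iteration, no convergence failures; the Dirichlet pin
keeps the matrix non-singular even with both surfaces taped). Reported
humidities apply the exact Kelvin relation to the solved potentials;
the solution object carries both the exact-Kelvin conductance `g_oxz`
(the analogue of the measurement-side formula) and the
linearization-consistent `g_oxz_lin`, which the test suite uses for exact
oracle comparisons. One subtlety the tests make visible: for a fixed
network, `g_oxz_lin` is exactly independent of the forcing (a Thevenin
reduction), while the exact-Kelvin `g_oxz` varies by about 1% over a
2 MPa span purely through the curvature of the Kelvin map.

The unit bridge between conductivities on ψ-gradients and conductances on
mole fractions is $\beta = w_{sat}\bar V_w \cdot 10^6/(RT)$ (mole fraction
per MPa), applied in exactly one place (the Robin boundary and the
reporting layer).

### Scenario engine

Four architectures are implemented behind `scenario_spec()`:

* **uniform_membrane** (preferred): the law above at every interface.
  Produces the observed phenomenology — conductance collapse with xylem
  stress, deep undersaturation next to a turgid symplasm (symplasm stays
  above the −2 MPa turgor loss point), tens-of-MPa interfacial
  disequilibrium.
* **symplasm_conductance**: membranes stay at $\kappa_{max}$; instead
  $k_{c\text{-}c}$ declines with the same logistic shape (floor
  `kcc_min_frac`, default 1/25). Reproduces a conductance decline but
  cannot generate interfacial disequilibrium (the compartments stay within
  ~1 MPa) and drags the symplasm below turgor loss — both contrary to
  observation.
* **wall_air_layer**: uniform membrane plus an air-filled wall layer
  (default 200 nm) as a series interfacial resistance, with conductance
  $D_{wv} c_{air} \beta / t$ per area. At ~1.5 mol m⁻² s⁻¹ MPa⁻¹ this is
  three orders of magnitude above $\kappa_{max}$, so it changes the
  conductance curve by well under 5% — cavitating cell walls cannot
  explain the observations.
* **bundle_sheath_only**: membranes stay at $\kappa_{max}$ everywhere but
  the xylem pin is replaced by a variable bundle-sheath entry conductance
  (interfacial area per leaf area `bs_area_per_leaf_area`, default 10,
  times the membrane law). The whole downstream symplasm then falls below
  the turgor loss point under stress, contradicting the observed turgid
  mesophyll.

`scenario_compare()` runs all of them on shared inputs and tabulates the
discriminating diagnostics (conductance fold change, minimum substomatal
humidity, maximum disequilibrium, turgor flag).

## Default parameters and their provenance

Structural defaults are literature-plausible round values for maize:
thickness 200 µm, xylem plane at mid-thickness, $a_{int} = 4\times10^4$
m² m⁻³, $k_{c\text{-}c} = 10^{-6}$ and $k_{vap} = 3\times10^{-7}$ mol m⁻¹
s⁻¹ MPa⁻¹ (the vapor value corresponds to an effective IAS porosity near
unity at 30 °C, standing in for the parallel wall-film path). The membrane
law's four parameters are the package's calibrated fit: with the
structural parameters held fixed, they were adjusted once — by the same
least-squares-on-log-conductance procedure exposed in
`fit_membrane_law()` — so that the forward model reproduces the observed
anchor behaviour at fixed $g_s = 180$ mmol m⁻² s⁻¹: a resistance ratio
$g_s/g_{oxz} \approx 0.01$ when well-watered (VPD 3.8 kPa), substomatal
potential near −12 MPa at $\psi_{xyl} = -0.85$ MPa and VPD 4.2 kPa, a peak
resistance ratio near 0.15 at intermediate stress, and a roughly 25-fold
conductance decline by −1.8 MPa. The result —
$\kappa \in [3.5\times10^{-5}, 2.5\times10^{-3}]$ mol m⁻² s⁻¹ MPa⁻¹,
$\psi_{50} = -0.18$ MPa, $s = 0.17$ MPa — sits inside the conductance
range measured on maize leaf protoplasts (order $10^{-5}$–$10^{-3}$ on
this unit system).

One structural tension is worth recording: a single logistic tail cannot
simultaneously produce the very sharp conductance drop between −0.2 and
−0.85 MPa and a continuing steep decline from −1.4 to −1.8 MPa once
$\kappa$ approaches its floor. The calibrated law therefore lands the fold
decline near 20 rather than exactly 25 — within the order-of-magnitude
band the observations constrain, and an honest property of this model
class rather than a fitting failure.

`fit_membrane_law()` itself is bounded multi-start (5 seeded starts)
L-BFGS-B on transformed parameters, with a tight-tolerance polish of the
winning start; the loss is weighted least squares on log conductance,
because $g_{oxz}$ spans a >20-fold range and a linear loss would see only
the plateau. Confidence half-widths come from the Jacobian-based
covariance and are documented as approximate. Flat (constant-conductance)
data pin $\kappa_{max}\approx\kappa_{min}$ and are flagged
non-identifiable rather than reported as a meaningful sigmoid. Fits are
deterministic in their seed and invariant to row order. Parameter-recovery
behaviour at the default design (20 potentials, 5% lognormal noise):
$\psi_{50}$ within ±0.1 MPa and both $\kappa$ bounds within ±20%;
$\kappa_{max}$ is the weakest-identified parameter because the observable
saturates in $\kappa$ at the wet end.

## The synthetic-data layer

`generate_campaign()` emulates the study design it stands in for: 87
measurements on 37 plants (round-robin across three "days"), xylem
potential uniform on [−2, 0] MPa and VPD uniform on [2.66, 4.82] kPa,
drawn independently (|r| < 0.2). Each record is forward-solved through the
two-compartment model with a stomatal-closure schedule (total $g_s$ of
180 mmol m⁻² s⁻¹ dropping threefold around −1.6 MPa, which is what lets
substomatal humidity recover at the most stressed conditions).
Observation noise is applied after the physics: additive Gaussian with SD
0.15 MPa on both potential readings — the measurement uncertainty the
profile figures quote — and multiplicative lognormal with CV 5% on fluxes,
an order-of-magnitude instrument choice. The physical ordering
$\psi_{ssc} \le \psi_{xyl}$ is preserved under noise by clipping.
Assimilation is a fixed 0.05 µmol per mmol of stomatal conductance — a
placeholder for the carbon side, which the package deliberately does not
model (it cancels from $\delta iWUE$ anyway). All randomness flows from
one seed in a documented draw order, so campaigns are byte-reproducible.

What the generator does *not* emulate: plant-to-plant parameter variation,
day effects, drift, correlated instrument error, or any genotype other
than the modelled one. Passing tests on synthetic campaigns therefore
demonstrate that the analytics invert the forward model under realistic
noise — not that the model is true of any particular real leaf.

`generate_fret_image()` renders the imaging fixture: a pixel-wise
potential field (Gaussian, clamped to the calibration's valid range)
mapped through a monotone calibration curve with pixel noise, plus an
autofluorescence channel of mesophyll cells — smooth disks when turgid,
shrunken six-lobed outlines after turgor loss — and elliptical dark
substomatal cavities. The shipped calibration is a placeholder logistic
spanning [−20, 0] MPa and is explicitly non-physiological; real work must
inject the instrument's curve (parameterised or tabulated, both supported
with exact inversion).

## Imaging analytics

`zeta_to_psi_map()` inverts the calibration pixel-wise; out-of-range
pixels become NA and are counted, never silently filled. The histogram
mode uses fixed 0.25 MPa bins anchored at multiples of the bin width
(ties resolve to the less negative bin) — a deliberate choice over kernel
density estimates for reproducibility. Cell morphometrics segment the
autofluorescence channel with Otsu thresholding, hole filling and a
distance-map watershed (EBImage), or accept pre-made label masks;
border-touching cells are excluded. Perimeter is the arc length of the
sub-pixel level-½ iso-contour of each cell mask, smoothed with a 3-point
circular moving average to remove the half-pixel staircase bias: a
digitised disk then scores circularity ($4\pi A/P^2$, capped at 1) within
~2% of 1 and an axis-aligned square lands near π/4. Group differences use
one-way ANOVA with Tukey HSD and a compact-letter display, the standard
procedure for this comparison; degenerate within-group variance is
flagged instead of tested.

## Configuration and pipeline

`run_pipeline()` chains synthesis → analytics → membrane-law fit →
response curves → scenario comparison into a run directory with a
manifest of MD5 checksums; identical configurations reproduce identical
artifacts. Configuration is YAML with schema validation that names
unknown keys and their section. A thin command-line wrapper over these
functions ships in `inst/scripts/oxzhydro`.

## Problem sizes used by the test suite

The suite runs the full 101-node grid where the headline numbers are
checked and a 25-node (12 layers per half) grid inside fitting tests —
the conductance solution is grid-converged to better than 0.1% at that
resolution, so fits are insensitive to it. Property checks use 100 random
networks for conservation, 25 random draws for the two-node oracle, and
6–20 seeds for the stochastic recovery properties.

## Known limitations

The model is isothermal and one-dimensional: no energy balance, no
lateral heterogeneity, no transient dynamics, no CO₂ transport (assimilation
is an observed input or a generator placeholder). The soil-to-leaf path is
assumed non-limiting. The membrane law is a phenomenological logistic of
xylem potential — mechanism (aquaporin gating or otherwise) is out of
scope. Structural parameters are plausible but not anatomically fitted;
only their product with the membrane law is constrained by conductance
data, so the calibrated $\kappa$ values should be read jointly with
$a_{int}$ rather than as free-standing membrane permeabilities.
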