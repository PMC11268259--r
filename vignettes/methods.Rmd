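---
title: "Models and methods for characterizing protein-loaded mesoporous silica inhalation powders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for characterizing protein-loaded mesoporous silica inhalation powders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerosilica)
```

`aerosilica` implements the computational chain used to characterize a
protein-loaded mesoporous silica particle (MSP) carrier for dry powder
inhalation: pore structure from nitrogen sorption, protein loading and
pore-filling capacity, small-angle X-ray scattering (SAXS) wall-thickness
proxies, cascade-impactor aerodynamics, release/dissolution kinetics,
thermogravimetric composition, and dose-response viability. This vignette
explains each model, its assumptions, the tunable parameters, and the
numerical decisions that were genuinely open.

## Nitrogen physisorption

### BET surface area

The specific surface area comes from the linearized multilayer-adsorption
regression of $p/(q(1-p))$ against relative pressure $p$ over a low-pressure
window of the adsorption branch. Monolayer capacity $v_m = 1/(s+i)$ and the
energy constant $C = s/i + 1$ follow from the slope $s$ and intercept $i$;
the surface area is $v_m$ times a single conversion constant, 4.3525 m²·g⁻¹
per cm³ STP·g⁻¹, derived from the nitrogen cross-section (16.2 Å²) and the
molar STP volume (22 414 cm³/mol). All such constants live in one table
(`silica_constants`) shared with the synthetic generators, so round-trip
tests cannot drift apart through inconsistent constants.

The fit window defaults to $p/p_0 \in [0.05, 0.30]$, the conventional range
where the multilayer theory is valid for mesoporous silica; instrument
vendors vary in their exact choice, so the window is a parameter and the
$r^2$ of the linearization is always reported for audit.

### Total pore volume

The single-point (Gurvich) rule: the uptake at the highest relative
pressure above a threshold (default 0.98), converted to condensed liquid
with the nitrogen gas-to-liquid factor 0.0015468. On a nonporous,
high-area material this reading includes the multilayer film — that is a
property of the method, not a defect, and is why the BJH distribution
(below) is the appropriate tool for separating pores from film.

### BJH pore-size distribution

Classic Barrett–Joyner–Halenda stepwise accounting on the desorption branch
(standard for mesoporous silica): per pressure step, the lost volume is
split between capillary cores emptying — Kelvin radius
$r_K(\text{Å}) = 4.14/\log_{10}(1/p)$, hemispherical meniscus — and film
thinning on the walls of pores already emptied, with the Harkins–Jura
thickness law $t(\text{Å}) = \sqrt{13.99/(0.034 - \log_{10} p)}$ and
cylindrical geometry. The wall area of an emptied pore is reduced by
$(r - \bar t)/r$ in the thinning correction because the film sits at radius
$r - t$, not at the wall; omitting this second-order factor costs about 5%
of total volume in round-trips, which is why it is included.

One decision deserves emphasis: when both branches are available, the
accounting is **restricted to the capillary-condensation region**,
identified as the pressure range where the branches separate
(hysteresis, relative tolerance `hysteresis_rel_tol = 1e-3`). Outside that
region the uptake change is film growth only; feeding it to the Kelvin
machinery would invent large pores — most visibly for a nonporous,
film-only isotherm, which correctly yields an empty distribution under
this rule. With a single branch the full range is used, as classic BJH
does.

The average pore diameter is the volume-weighted mean by default, with
$4V/A$ as an option; reported pore metrics carry a $4V/A$ consistency
check.

## Protein loading

Loading is quantified indirectly from supernatant depletion,
$(c_0 - c_{eq}) \cdot m_{solution} / m_{sorbent}$, with concentrations as
mass fractions (mg per g of solution; buffer density taken as 1 g/mL).
Depletions below the assay's limit of quantification are reported as zero
with a flag rather than dropped, so datasets keep their design points.

Langmuir fits use the nonlinear form $q = q_{max} K c/(1 + K c)$ — not a
Lineweaver-style linearization, which distorts the error structure. The
default weighting is inverse-variance for proportional error
($w = 1/q^2$), appropriate for spectrophotometric quantification whose
uncertainty scales with the signal; unweighted least squares is available.
Under 5% multiplicative noise the weighted fit's nominal 2-SE interval
covers the true $q_{max}$ at close to the nominal rate, while the
unweighted fit understates its standard errors badly (about one miss in
four in simulation) — this, not aesthetics, is why weighting is the
default.

The pore-filling capacity model has two directions:

- **Ceiling**: $m = \rho_{protein}\,\varphi\,V_{pore}$ with lysozyme
  density 1.4 g/cm³ and the random-close-packing fraction of ellipsoids
  $\varphi = 0.74$ — the maximum protein the pore system could hold.
- **Achieved**: the loaded composite's pore volume is measured per gram of
  composite, so $V_{loaded} = (V_{unloaded} - m/\rho)/(1 + m)$; inverting,
  $m = (V_{unloaded} - V_{loaded})/(V_{loaded} + 1/\rho)$.

The operation takes both volumes explicitly because the correct "unloaded"
reference is a modelling choice: when buffer alone also occupies pore
volume, the buffer-treated placebo — not the pristine carrier — isolates
the protein's contribution, and that is the convention used in the worked
example (0.64 vs 0.40 cm³/g, giving 0.215 g/g).

## SAXS correlation-length model

$$I(q) = \frac{A}{q^n} + \frac{C}{1 + (q\xi)^m} + \text{bkg}$$

combines a Porod power law (interfacial scattering; $n \approx 4$ for
smooth interfaces, below 4 for fractal surfaces) with a Lorentzian whose
correlation length $\xi$ serves as a proxy for the average pore-wall
thickness of disordered silica. Units: $q$ in nm⁻¹ on disk and in fits;
$\xi$ stored and reported in Å with an explicit ×0.1 conversion at the
model boundary, matching how practitioners quote both.

Fitting is weighted (1/σ²) nonlinear least squares in linear intensity
space — not log space — matching common small-angle practice. Bounds are
wide and physical: $n \in [2, 5]$, $m \in [0.5, 4]$, $\xi \in [1, 500]$ Å;
an estimate pinned at a bound is flagged. The surface has local minima when
the Lorentzian shoulder is partially hidden under the power law, so the
automatic initialization ($n$ from the first half-decade log-log slope,
$C$ from the high-q region, $\xi$ from the crossover) is supplemented by a
small multi-start over $\xi$ and $n$, keeping the best weighted residual.
A curve with no identifiable Lorentzian component (pure power law) falls
back to a Porod + background fit and reports $C = 0$ rather than an
unidentifiable $\xi$.

## Cascade-impactor reduction

Stage cut-offs ship as the archival NGI calibration at 60 L/min with
per-stage flow exponents, scaled as $D_{50}(Q) = D_{50,60}(60/Q)^x$; users
may supply their own table. The impactor-sized mass (stages 1–7 + MOC) is
the basis of the cumulative undersize; inlet and pre-separator deposits
count toward the emitted dose but not the sized distribution, the standard
convention, since those deposits are not size-classified.

MMAD is the diameter at 50% cumulative undersize, interpolated linearly in
(probit, ln d) between the two bracketing stages; GSD is
$\sqrt{d_{84.13}/d_{15.87}}$. Local interpolation (rather than a global
probit regression) is the default because it reproduces the graphical
procedure exactly on perfectly log-normal data and does not let distant
stages bias the median; a global-regression mode is available. Quantiles
outside the table are extrapolated from the nearest segment and flagged.
The fine particle fraction interpolates the undersize curve at exactly
5.0 µm instead of summing stages below the nearest cut-off, removing the
grid dependence of the stage-sum shortcut.

## Release, dissolution and viability

Interval release fractions support two bookkeeping conventions, because a
withdrawal/replacement schedule makes the literal formula ambiguous about
carryover:

- `as_printed`: $\omega_i = C_i m_{vessel}/(\omega_{lys} m_{sample})$ —
  each sampling's concentration counted in full;
- `carryover_corrected`: the newly released mass is
  $C_i m_{vessel} - C_{i-1}(m_{vessel} - m_{withdrawn})$, subtracting the
  diluted residue of the previous interval.

Both are provided without guessing intent; on the synthetic generator —
which does exact dilution accounting — the corrected mode converges to the
true plateau to within 0.1%, which is the round-trip the tests enforce.

Silica dissolution percentages divide measured Si concentrations by the
theoretical Si content of the dose. The Si mass fraction defaults to
28.08/60.08 = 0.4674 from the Si and SiO₂ molar masses; any other ratio can
be passed for sensitivity analysis or to reproduce legacy calculations
performed with different constants. T₅₀% comes from an OLS line through all
points in the early linear window (default 0–8 h) — more stable than
two-point bracketing and exact on linear data.

Viability normalization is linear between blank and untreated controls.
The 4PL fit $y = d + (a-d)/(1+(x/c)^b)$ flags `ic50_beyond_range` when the
response never departs from the upper asymptote by more than a tolerance
(default 10 percentage points) across the tested range — reporting a
fitted inflection there would be noise, not signal.

## TGA segmentation

Residual weights at 25, 100, 200, 800 and 1000 °C are linearly
interpolated; losses are assigned as water (25–100), protein (200–800,
after subtracting the carrier's constant silanol condensation loss) and
salts (800–1000), with the remainder as carrier. The silanol correction
defaults to 2.2 wt%; because reported values for this correction vary
(2.2–2.5 wt% for the same material, depending on source), it is an explicit
parameter and the value used is echoed in the result. The loss in the
unassigned 100–200 °C window is attributed to the carrier remainder and
reported separately (`gap_100_200_pct`) so the audit trail is complete.
Negative corrected protein is floored at zero and flagged.

## Synthetic data: what it shows and what it does not

Each generator emits its truth parameters in the `truth` attribute and is
deterministic under a fixed seed (the caller's RNG stream is preserved).
Noise is multiplicative Gaussian by default, matching the relative-error
behavior of most of these instruments.

- `gen_isotherm` builds adsorption/desorption branches from a log-normal
  pore-volume distribution with the same Kelvin and thickness constants as
  the analysis; condensation uses the cylindrical-meniscus radius
  ($r_K/2$) on adsorption and the hemispherical $r_K$ on desorption, which
  produces hysteresis in the physical direction. The film inside an
  unfilled cylinder is the exact annulus volume. What it does *not*
  emulate: pore-blocking/cavitation hysteresis, micropores, networked
  pores, or surface heterogeneity — so a passing BJH round-trip
  demonstrates the accounting, not the trustworthiness of BJH on such real
  materials.
- `gen_impactor_run` partitions a log-normal aerosol by the scaled
  cut-offs; it does not model bounce, re-entrainment, or wall losses
  within sizing stages.
- `gen_release_series` does exact withdrawal/dilution bookkeeping over a
  first-order release; it does not model diffusion-limited or
  matrix-erosion kinetics.
- `gen_thermogram` uses logistic steps centered inside each window with
  widths chosen so boundary tails are negligible; real decompositions
  overlap windows, which is precisely the case the segmentation cannot
  resolve.

Test problem sizes: isotherms use 80 pressure points per branch and 400
pore bins; BJH round-trips span modes 40–120 Å; impactor recovery spans
MMAD 1–5 µm and GSD 1.3–2.5; SAXS fits use 120 points over 0.05–10 nm⁻¹ at
1% noise; TGA round-trips randomize water ∈ [0,5], protein ∈ [0,25],
salts ∈ [0,50] wt%. These sizes make the full suite run in seconds while
keeping every tolerance meaningful.

## Known limitations

- BJH here is the classic cylindrical-pore method; no t-plot micropore
  analysis or DFT/NLDFT models. Film on *external* surface inside the
  condensation region is not separated and would bias distributions of
  low-porosity, high-external-area samples.
- Instrument-reported pore metrics depend on the fit window and thickness
  law the vendor software used; when those are unknown, absolute agreement
  with printed tables can only be demonstrated on calibrated fixtures.
- The SAXS module consumes 1-D curves; radial averaging of detector images
  and q-calibration are out of scope.
- The correlation-length ξ is a proxy for wall thickness by analogy, not a
  measurement; comparisons are meaningful between samples fitted the same
  way.
- Release bookkeeping treats the measured concentrations as error-free
  inputs to the chosen convention; it does not deconvolve assay error.
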