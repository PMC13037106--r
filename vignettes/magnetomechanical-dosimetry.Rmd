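---
title: "Magnetomechanical dosimetry: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnetomechanical dosimetry: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnetodose)
```

## The problem

Magnetomechanical stimulation delivers piconewton-scale forces to cells
by loading them with superparamagnetic iron-oxide superparticles and
applying a gradient magnetic field. Unlike optical or acoustic
stimulation, the delivered dose cannot be measured directly: it must be
reconstructed from particle geometry, elemental-iron assays, field
characterization, and the exposure schedule. This vignette documents the
models this package uses for that reconstruction, the parameters that
matter, and the choices made where the design was genuinely open.

## From geometry to iron mass

A superparticle is modeled as a spherical core of diameter $d$ packed
with magnetite crystallites at volume fraction $\varphi$, surrounded by
an organic shell that is treated as magnetically and elementally inert.
The elemental iron per particle is

$$m_{\mathrm{Fe}} = \frac{\pi}{6} d^3 \,\varphi\, \rho_{\mathrm{Fe_3O_4}}
  \, w_{\mathrm{Fe}},$$

with $\rho_{\mathrm{Fe_3O_4}} = 5.18$ g/cm³ and the stoichiometric iron
fraction $w_{\mathrm{Fe}} = 3\cdot 55.845 / 231.533 \approx 0.7236$
(Fe₃O₄ contains three iron atoms per formula unit; the package never
hard-codes the rounded value). All internal arithmetic is SI; the
boundary accepts nm and emits pg, because those are the units
experimental tables use, and mixing pg/µg/pN/µN silently is the classic
failure mode of this arithmetic.

**Packing fraction.** The published characterization of the reference
particle gives the core diameter (56.60 nm) and a per-particle iron mass
(2.21 × 10⁻⁴ pg) but not the derivation linking them. A fully dense core
would carry 3.56 × 10⁻⁴ pg, so the implied crystallite packing is
$\varphi \approx 0.62$ — physically sensible for random close packing of
polydisperse nanocrystals with dye and surfactant in the interstices.
The default `packing_fraction = 0.62` is therefore declared a
*calibrated* constant, not a measurement, and is overridable in every
config.

```{r}
iron_mass_per_particle(particle_spec())
iron_mass_per_particle(particle_spec(packing_fraction = 1))
```

## Magnetization and force

Superparamagnetic particles follow the classical Langevin law
$M(B) = M_s\,L(x)$, $L(x) = \coth x - 1/x$, with argument
$x = m_c B / k_B T$ where $m_c$ is the moment of one crystallite (bulk
magnetization 4.8 × 10⁵ A/m × crystallite volume). $L$ is evaluated by a
series below $|x| < 10^{-4}$ to avoid cancellation. The default
temperature is 300 K, the magnetometry condition; physiological
scenarios can override to 310 K.

The force model is the scalar co-linear reduction of
$\mathbf{F} = (\mathbf{m}\cdot\nabla)\mathbf{B}$: moments align with the
field within milliseconds at these particle sizes, and only axial
gradients are characterized, so $F = m\,\partial B/\partial z$.

**Two moment modes.** The package computes the per-particle moment two
ways, and this is a deliberate design point:

* `"calibrated"` (default): moment = measured per-particle force divided
  by the gradient it was measured at. Bench characterizations report
  force–gradient pairs, not local flux densities, and the two reference
  pairs (1.59 × 10⁻⁵ pN at 3.25 T/m; 1.27 × 10⁻⁴ pN at 16.0 T/m) imply
  *different* moments (4.9 vs 7.9 × 10⁻¹⁸ A m²) — exactly what a
  field-dependent magnetization predicts when the local B differs
  between setups. Treating each pair as ground truth per scenario
  reproduces the measured dose chain without guessing B.
* `"model"`: Langevin moment at a user-supplied local field, for
  prospective design where no calibration exists.

## Field generators

The electromagnet is represented by its calibration line: a least-squares
fit through measured (current, gradient) points, pinned to exactly zero
at zero current, warning on extrapolation. The three reference points
(1 A → 1.25, 2 A → 2.25, 3 A → 3.25 T/m) are co-linear, so the fit
reproduces them to machine precision.

The ring array uses the closed-form on-axis field of an axially
magnetized annulus — the difference of two solid-cylinder expressions —
superposed over magnets with polarity signs, with the gradient obtained
analytically. Two oracles guard it: central finite differences
(agreement to 10⁻⁴ relative) and a point dipole of equal total moment in
the far field (5% at $|z| \gg R_{\text{outer}}$). The bundled geometry
(four rings, inner/outer radii 35/75 mm, 15 mm thick, two opposed pairs
15 mm apart, remanence 1.40 T assumed for N48-grade NdFeB) produces
~20 T/m at the center — the same order as the 16 T/m working value of
the reference apparatus. The exact arrangement and polarities of that
apparatus are unpublished, so the array is validated qualitatively
(symmetry, limits, oracles), and the dose chain takes 16.0 T/m from the
calibrated force pair rather than from this geometry model.

## Clearance kinetics and cumulative dose

Tissue iron time series are fitted with log-linear OLS:
$\ln m(t) = \ln m_0 - k t$. For the short (4-point) series this assay
produces, log-linear OLS is preferable to weighted nonlinear fitting —
it is closed-form, has no starting-value sensitivity, and its bias under
multiplicative noise is negligible at the observed noise level (the test
suite verifies < 5% mean error over 200 replicates at lognormal
$\sigma = 0.1$). Rates within $10^{-12}$ of zero are snapped to zero so
constant series report an infinite half-life rather than a
floating-point artifact.

```{r}
fit_clearance(iron_timeseries(c(1, 3, 7, 14), c(3.57, 2.13, 1.40, 0.34)))
```

Between measurement days the force follows the fitted exponential, not a
raw-point interpolation: dosing is continuous over the 14-day exposure
while measurements are day-end snapshots. The cumulative impulse
integrates the force over ON intervals only (adaptive quadrature per
interval, relative tolerance 10⁻¹⁰), since OFF periods deliver no force
by the superparamagnetic construction.

Day-3 and day-14 chain values are compared at 2% rather than 1% in the
tests: reference tables round intermediates to 3 significant figures,
and the drift that rounding induces is visible in exactly those two
entries.

## Stimulation protocols

Cyclic mode tiles ON/OFF pairs from time zero until the span is
exhausted, truncating (not dropping) a final partial ON interval — with
the reference parameters (15/15 min over 12 h) the division is exact and
24 full cycles result. Daily-session mode anchors sessions to naive
local clock times on a day grid; time zones and DST are deliberately out
of scope since the schedule times are nominal. Sessions may not overlap
and may not cross midnight.

## Bioassay metrics

All outcome formulas are implemented exactly as printed in the standard
references: SFI (Bain weights −38.3/109.5/13.3 and offset −8.8), CCK-8
viability with both the blank and the nanomaterial-absorbance
corrections, Oi = cos θ after folding angles to the acute range,
G-ratio, MNCV, F/G-actin. Two reporting conventions are worth noting:
ΔF/F₀ is reported ×100 (percent-like; group values near 60 make no
sense as unit ratios) while F<sub>max</sub>/F₀ is a plain ratio; and
F_stim defaults to the *mean* over the whole post-onset window because
the instantaneous-versus-averaged choice is not standardized — the
window is configurable via the trace's onset.

## Synthetic data: what it emulates, what it does not

Each generator reproduces the statistical structure its consumer
assumes: truncated-normal per-cell uptake (mean 2.05 pg, SD 0.64 pg —
the observed uptake distribution; clamping at zero biases the mean by
< 0.1% at these parameters), lognormal multiplicative noise on
exponential clearance, additive footprint noise around a record solved
to score an exact target SFI, von Mises orientation angles folded to
[0, π/2], a rise–plateau–decay calcium transient over a 50 s baseline
and 650 s span, and lognormal fiber diameters with the G-ratio drawn
around its target. One global seed derives a fixed per-generator
substream by string hash, so adding a generator never perturbs existing
draws.

What passing these tests shows: the *formulas and fits* are correct and
invertible on data with the assumed structure. What it does not show:
that real measurements have that structure — real footprints correlate
across limbs, real calcium traces bleach and drift, real uptake is
right-skewed rather than truncated-normal, and real clearance may be
bi-phasic. Biological outcome values (group SFI means, CMAP amplitudes,
G-ratio medians) depend on animals and cells and are not reproducible
from code; only the dosimetry chain is.

## Problem sizes

The test suite uses 200-replicate recovery simulations, 10⁴-draw
law-of-large-numbers checks, and 2 × 10⁴-draw median checks; the full
suite runs in a few seconds on one CPU, and the reference dose chain in
well under a second.

## Known limitations

* One effective particle diameter; no size distribution or hydrodynamic
  modeling (the 116 nm hydrodynamic diameter is metadata only).
* 1-D axial field model; no off-axis maps, no pole-tip finite elements,
  no hysteresis (the particles have negligible remanence and coercivity).
* Single-compartment clearance; no uptake-mechanism or spatial PK model.
* The ring-array remanence and magnet arrangement are assumptions; the
  16.0 T/m working gradient enters through calibration, not geometry.
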