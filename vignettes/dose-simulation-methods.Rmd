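---
title: "Methods: variance-stabilized dose-reduction simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance-stabilized dose-reduction simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosesim)
```

## The model

A raw ("for processing") mammogram from an energy-integrating a-Se
detector is, to good approximation,

$$ Y(x,y) = \theta + c(x,y)\,P(x,y), \qquad
   P(x,y) \sim \mathrm{Poisson}\{\lambda(x,y)\}, $$

where $\theta$ is a global additive offset, $\lambda$ the expected
quantum count (proportional to mAs and tissue transmission) and $c(x,y)$
the position-dependent scale left behind by the flat-field correction.
After offset subtraction the local noise variance is
$c^2\lambda = c \cdot \text{(local mean)}$: signal-dependent, and
nonuniform because $c$ varies across the field (variance-to-mean ratios
of roughly 0.1–0.3 are typical).

Reducing dose by a factor $\alpha$ scales the mean by $\alpha$ but the
variance only by $\alpha$ as well — whereas plain multiplication of the
image scales variance by $\alpha^2$. The missing noise,

$$ \sigma_\text{sim}^2(x,y)
   = \sigma^2_{H^L_\text{sim}}(x,y) - \sigma^2_{H^{L,S}_o}(x,y), $$

is measured from flat-field exposures at the target dose
($H^L_\text{sim}$, linearized) and at the full dose ($H^{L,S}_o$,
linearized and $\alpha$-scaled). Measuring at the actual target dose
means no assumption about how DQE varies with dose is needed.

The noise cannot simply be added in the count domain, because added
white noise would not acquire the signal dependence of quantum noise.
The Anscombe transformation $A\{g\} = 2\sqrt{g + 3/8}$ maps Poisson data
to approximately unit-variance Gaussian; in that domain noise is
signal-independent and additive, so a measured-variance mask can be
embedded correctly:

$$ Y_\text{sim} = A^{-1}\!\big( A\{\alpha(Y_o - \theta)\} + N_A \big)
   + \theta, \qquad
   N_A = A\{N + \bar H^L_\text{sim}\} - A\{\bar H^L_\text{sim}\}, $$

with $N$ a unit Gaussian field multiplied pointwise by
$\sigma_\text{sim}$. The DC level $\bar H^L_\text{sim}$ (the scalar mean
of the linearized target-dose flat) makes the forward transform
applicable to a zero-mean field and cancels exactly for a zero mask.

A first-order (delta-method) budget shows why this works: in the
Anscombe domain the scaled image carries noise variance
$\alpha c$, the embedded mask adds
$\sigma_\text{sim}^2 / \bar H^L_\text{sim} \approx c(1-\alpha)$, and the
inverse maps the total $c$ back to count-domain variance
$c \cdot \text{mean}$ — the variance of a genuine acquisition at the
reduced dose. The argument needs the local mean of the flat to be close
to its global mean, which is exactly what the flat-field correction
enforces; for strongly nonuniform flats a per-pixel DC variant is
available (`local_dc = TRUE` in `simulation_recipe()`, `dc =` in
`embed_noise_anscombe()`), but the scalar form is the default and the
formulation the method is specified with.

## Inverse transformations

Two inverses are provided. The algebraic inverse $(z/2)^2 - 3/8$ is the
exact functional inverse. As an estimator of the Poisson *mean* from the
expected Anscombe-domain value it is biased low by up to $1/4$ count —
a small-count effect (material below $\lambda \approx 10$). The
exact-unbiased inverse uses the closed-form rational approximation

$$ \hat\lambda(z) = \tfrac{z^2}{4} + \tfrac{\sqrt{3/2}}{4} z^{-1}
   - \tfrac{11}{8} z^{-2} + \tfrac{5\sqrt{3/2}}{8} z^{-3} - \tfrac18, $$

which is zero at $z_0 = 2\sqrt{3/8}$ (the transform of zero counts),
increasing beyond it, and removes the small-count bias: inverting the
exactly-summed $E[A\{x\}]$ at $\lambda \in \{1, 2, 5\}$ returns
$\lambda$ within 0.02, where the algebraic inverse misses by about 0.2.

The two differ by a persistent $1/4$ count at large $z$ (the closed form
tends to $z^2/4 - 1/8$). Mammographic pixels live at hundreds to tens of
thousands of counts, where a $1/4$-count adjustment to the *mean
estimate* is irrelevant but an exact round trip
(`inverse(forward(x)) == x`) is valuable — it makes the $\alpha = 1$,
identical-flats simulation reproduce its input to machine precision.
`anscombe_inverse_exact_unbiased()` therefore uses the closed form below
$z = 15$, the algebraic inverse above $z = 20$ (counts $\gtrsim 100$),
and a linear blend between; the blend's slope perturbation
($\sim 0.025$ against a local slope of $\sim 10$) keeps the map strictly
increasing. Noise *insertion* statistics are unaffected by the choice of
branch, since both have the same derivative to leading order.

## Calibration

`estimate_offset()` regresses windowed flat-field means on dose by
ordinary least squares; the intercept is $\theta$. Windowed (64 × 64)
rather than whole-image means are used so the field's spatial
nonuniformity appears in the fit's spread without biasing the intercept;
the intercept is invariant to linear rescaling of the dose axis (mAs or
mGy both work). The offset is treated as a single global constant —
per-pixel offset maps are a flat-fielding concern, out of scope here.
Linearization clamps at zero (counts cannot be negative), and
$\theta$ is restored as the very last pipeline step.

## Noise estimation choices

* **Window**: 64 × 64 pixels (0.45 cm at 0.07 mm pitch), the standard
  detector-characterization window; `tiled` mode (non-overlapping, the
  default) or `sliding` (per pixel, odd window, reflective padding).
* **Tile expansion**: tiled maps are expanded block-constant by default —
  interpolation would invent smoothness the estimate does not have; a
  bilinear option exists for users who prefer continuous maps.
* **Negative radicands** in $\sigma_\text{sim}$ (sampling fluctuation
  when the two variance fields are close) are clamped to zero and
  counted (`n_clamped`), with a message when any occur.
* **Replicate flats** at one dose are averaged at the variance-map
  level.
* The mask itself is *white* Gaussian modulated by $\sigma_\text{sim}$:
  anisotropy and spatial structure enter only through the measured
  variance maps. Detectors with strongly correlated noise (e.g. CsI/TFT)
  would need a colored mask and are out of scope.

## Validation metrics

The 2D noise power spectrum of $M$ ROIs is implemented in the discrete
form $\mathrm{NPS}(u,v) = \frac{\Delta_x \Delta_y}{N_x N_y}
\langle |\mathcal{F}\{\mathrm{ROI} - S\}|^2 \rangle_M$, pinned by the
Parseval property (spectral integral = noise variance, verified to 1%):
the factor placement in printed limit-form definitions is ambiguous, the
conservation law is not. NNPS divides by the squared large-area signal
$L^2$, making it invariant to gray-level rescaling. The noiseless-signal
estimate $S$ is the per-ROI mean for uniform images and an ensemble
average of realizations for structured images (`signal = "ensemble"`);
for structured images the "normalized PS" uses the ROI-set mean as $L$.

1D profiles average the 2D grid in annular bins of the grid's own
spacing, excluding the $u = 0$ / $v = 0$ axes (standard practice: axis
bins collect fixed-pattern leakage), restricted to 1.5–7.1 mm⁻¹ — below
the 7.14 mm⁻¹ Nyquist limit of 0.07 mm pixels, and the region where
mammographic noise spectra are nearly flat. Comparisons are made on
these 1D profiles rather than raw 2D bins: with $M \approx 64$ ROIs per
image a single 2D bin has ~18% sampling error, which would swamp any
method error, while a radial bin averages a few hundred 2D bins.

Crossed comparisons evaluate every image of the test set against every
image of the reference set (per window for variance, per frequency bin
for spectra), maximizing paired measurements from few exposures.
Relative errors are reported against the reference set; the 95% CI of
the mean difference is normal-theory ($\pm 1.96\,\mathrm{SE}$), the
method used being unstated in the sources that report such tables.

## The synthetic generator

`detector_model()` + `phantom_model()` exist so the whole chain is
testable with no clinical data. A draw is

$$ \mathrm{pixel} = \theta + g(x,y)\,
   \mathrm{Poisson}\!\left\{ \frac{q \cdot \mathrm{mAs} \cdot
   \mathrm{att}(x,y)}{g(x,y)} \right\} + \mathcal{N}(0, \sigma_r), $$

rounded to detector integers. The gain field $g$ — a smooth low-order
cosine ramp spanning [0.1, 0.3] by default — plays the role of the
flat-field correction residue: the offset-subtracted mean
$q \cdot \mathrm{mAs} \cdot \mathrm{att}$ is *uniform* on flats (as a
flat-fielded detector's is) while the variance-to-mean ratio equals $g$
and sweeps the field. Defaults: $\theta = 50$ (a typical manufacturer
offset value), $q = 10$ counts/mAs so a 160 mAs flat sits near pixel
value 1650, 14-bit depth, 0.07 mm pitch, $\sigma_r = 0$ so the noise
model is exactly the gain-scaled Poisson one the method assumes
(readout noise can be switched on to probe robustness). Phantom texture
is $1/f^3$ power-law filtered Gaussian noise mapped into transmission
[0.4, 0.9] — the standard mammographic texture exponent — with optional
disc-shaped microcalcification-like spots.

What the generator does **not** emulate: scatter and grid effects, the
heel effect's deterministic shading (only its noise signature via $g$),
detector glare/correlated noise, and anatomical realism. Passing tests
therefore demonstrate the statistical contract (moments, spectra,
linearity) — not clinical appearance.

## Study conditions and problem sizes

The validation tests mirror the geometry used for real detector
characterization: a 2048 × 512 analysis strip (14.3 × 3.6 cm), 64 px
variance windows (256 per image), 128 px (0.90 cm) spectral ROIs, five
phantom realizations per dose, two flats per dose, doses 160 and 80 mAs
($\alpha = 0.5$), offset calibration from 4 dose levels × 2 flats × 207
windows. On these conditions the end-to-end simulation reproduces
directly generated half-dose images with ~1.7% average local-variance
error and ~1.3% band-averaged NNPS error; the Monte-Carlo checks of the
transform use $10^5$–$10^6$ draws.

## Known limitations

* Dose reduction only ($\alpha \le 1$), driven by mAs; changes of kVp or
  target/filter alter the beam spectrum and are not modeled.
* The offset is global; systems with drifting or structured offsets need
  external flat-fielding first.
* The scalar-DC embedding assumes approximately uniform flat means;
  grossly non-flat-fielded inputs should use `local_dc = TRUE`.
* White-mask assumption: valid for a-Se detectors, not for detectors
  with significant noise correlation.
* Input images must be raw "for processing" data; display-processed
  images violate the linearity the calibration relies on.
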