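---
title: "Transmittance image decomposition: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmittance image decomposition: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biodecomp)
```

## The model

Light of wavelength $\lambda$ crossing a stack of homogeneous tissue layers
is attenuated exponentially in each layer (Beer–Lambert). At a pixel
$(x, y)$ the transmittance — the object image divided by a no-specimen
reference image of the same beam — is

$$T_\lambda(x,y) \;=\; \frac{I_\lambda(x,y)}{I_{0\lambda}(x,y)}
\;=\; \exp\!\Big(-\sum_{t=1}^{k} \mu_{\lambda t}\, d_t(x,y)\Big),$$

with $\mu_{\lambda t}$ the attenuation coefficient (cm⁻¹) of tissue $t$ at
wavelength $\lambda$ and $d_t(x,y)$ that tissue's path length (cm). Taking
the natural log of the inverse transmittance makes the system linear:
acquiring the same frame at $k$ wavelengths gives, per pixel,

$$\boldsymbol\mu\, \mathbf d(x,y) = \ln \mathbf T^{-1}(x,y),$$

with $\boldsymbol\mu$ the $k \times k$ attenuation matrix (rows =
wavelengths, columns = tissues). If $\boldsymbol\mu$ is invertible, one
linear solve per pixel recovers all $k$ tissue thicknesses; assembling each
component over the frame yields the per-tissue thickness images.

Assumptions worth stating plainly:

* **Strictly per-pixel.** No coupling between neighbours: no scattering
  blur, no regularization. A pixel's solution depends only on its own $k$
  transmittance values.
* **Known, spatially constant coefficients.** $\boldsymbol\mu$ comes from a
  separate characterization step and is assumed valid across the frame.
* **Aligned frames.** The $k$ exposures view the same scene; registration
  is out of scope.
* **Monochromatic, single-channel acquisition.** Color inputs are rejected
  rather than converted.

## Characterization

Each matrix entry is measured from homogeneous specimens of known uniform
thickness $d$: the per-pixel plane $\mu(x,y) = -\ln T(x,y)/d$
(`attenuation_plane()`) is averaged over a central crop
(`mean_attenuation()`). The crop (default the central 50% × 50% of the
frame) avoids the dim edge of the Gaussian beam where the dark floor
dominates.

Thin specimens are biased by the transparent case that holds them; the bias
vanishes as the specimen thickens. `fit_asymptotic()` models this as

$$\mu(d) = \beta_0 + \beta_1\, d^{-3},$$

and reports the asymptote $\beta_0$ as the case-free coefficient. The model
is linear in $(\beta_0, \beta_1)$, so the fit is exact linear least squares
on the regressor $d^{-3}$ — no iterative optimizer, no starting values. The
exponent 3 is an empirical choice exposed as a parameter; nothing in the
package depends on its particular value. The reported ± for a matrix cell
is the standard deviation of the per-pixel plane over the mask (or the
$\beta_0$ standard error when the asymptotic fit is used); these are
descriptive spreads, not calibrated confidence intervals.

## Conditioning: the method's central failure mode

The packaged chicken-tissue matrix (meat/bone/skin at 780/808/980 nm)
illustrates the method's key fragility:

```{r}
m <- chicken_attenuation_matrix()
matrix_diagnostics(m)
```

The three NIR wavelengths are spectrally close, so the rows are nearly
proportional: the determinant is small and the condition number is a few
hundred. Perturbations of size $\varepsilon$ in $\ln T^{-1}$ can become
$\kappa \varepsilon$-sized thickness errors. `matrix_diagnostics()` reports
both quantities and warns above a configurable condition threshold (default
$10^3$; the singularity cutoff is $|\det| \le 10^{-10}$). These thresholds
are reporting conventions, not physics: the honest guidance is to maximize
the spread of attenuation contrast when choosing wavelengths. The
conditioning property is verified as a monotone relationship in the test
suite: along a one-parameter matrix family approaching proportional rows,
mean thickness error under fixed noise increases with condition number.

## Numerical choices

* **Clamping.** Transmittance values above 1 (noise can make the object
  brighter than the reference) clamp to 1; values at or below
  $\varepsilon = 10^{-6}$ clamp to $\varepsilon$, keeping
  $\ln T^{-1}$ finite and nonnegative. Both events are counted and
  reported, never silent.
* **Validity.** Pixels with a saturated object or reference, or a reference
  at/below the dark floor (default 1% of the saturation count — the
  acquisition literature gives no floor, so it is configurable), carry no
  attenuation information. They propagate as no-data through every stage
  and render as a mid-gray sentinel.
* **One factorization.** `decompose_stack()` solves
  $\boldsymbol\mu\, D = B$ for all pixels at once rather than inverting
  $\boldsymbol\mu$ explicitly — identical mathematics, better numerics.
* **Negativity.** Noise can drive solved thicknesses negative. The default
  output clips to zero (negative thickness is unphysical) but the raw
  solution is preserved (`postprocess(..., "keep_raw")`) and summarized as
  `negatives_fraction`, counting components below $-10^{-12}$ cm so that
  float roundoff at genuinely zero-thickness pixels is not miscounted.
* **Ordering by label.** Wavelength rows and tissue columns are carried as
  labels and validated on every decomposition; mismatches are errors, never
  silently reordered. This is the method's most error-prone convention.
* **Rounding.** Quantization (rendering and the camera model) rounds half
  away from zero, the camera-like convention, not banker's rounding.
* **Rendering.** Thickness displays as darkness (0 cm = white). The display
  maximum defaults to the map's 99th percentile, since a fixed scale is a
  presentation choice the data cannot supply.

## The phantom generator

`phantom_preset()` ships two scenes used throughout the tests: three
side-by-side rectangular blocks of meat (0.5 cm), bone (0.3 cm) and skin
(0.2 cm); and the same scene completely covered by a 0.1 cm skin overlay —
the occluded-specimen scenario in which the decomposition's value is most
visible. Block thicknesses sit in the 0.2–0.5 cm range where the
characterization experiments operate.

Rendering emulates the acquisition: a circular Gaussian beam (peak 75% of
saturation at the frame center, σ half the frame side — bright enough that
no preset pixel falls below the dark floor), per-pixel exponential
attenuation, multiplicative lognormal speckle (median 1), additive Gaussian
read noise, clipping at saturation, and integer quantization. Object and
reference exposures draw independent noise. Defaults are speckle σ = 0.02
and read σ = 2 counts: a diffuser-suppressed coherent source and a cooled
CMOS camera; these are the package's realism choices, as no numeric noise
levels accompany the physical experiments the scenes emulate. Setting both
to zero and disabling quantization recovers the ideal model exactly, which
is what makes the phantom a usable oracle.

What the phantom does **not** model: spatial scattering (no point-spread
function, so edges stay perfectly sharp), case reflections, wavelength-
dependent beam shape, or misregistration between exposures. Perfect Dice
scores on noise-free phantoms therefore demonstrate the algebra closes, not
that real specimens — where scattering blurs boundaries and coefficients
vary within a tissue — will score as well. On real images the achievable
matching-area accuracy is expected to be well below 100% for exactly the
conditioning reasons above.

## Evaluation

Manual boundary marking is replaced by reproducible thresholding (Otsu on a
256-bin histogram by default; ties across an empty histogram gap break to
the plateau midpoint). Two overlap measures are reported side by side
because they answer different questions: the **matching-area ratio**
$|A \cap R|/|R|$ (asymmetric, reference-normalized — the fraction of the
true area recovered) and the **Sørensen–Dice coefficient**
$2|A \cap R|/(|A| + |R|)$ (symmetric; both-empty defined as 1). Continuous
recovery (RMSE, max error, bias in cm) is reported whenever ground truth
exists. The report takes no position on which overlap measure is "the"
accuracy; both are printed distinctly.

## Problem sizes used in the shipped checks

The unit tests exercise frames from 1×1 (closed-form pixels) to 64×64;
the end-to-end checks and the acceptance script use 256×256 phantoms, 200
regression replicates and
2000-pixel noise panels — sizes at which every property checked (exactness
to <10⁻⁶ cm, monotone degradation with noise and conditioning, unbiased
$\beta_0$) is comfortably resolved while the whole run stays in seconds.

## Known limitations

* $k$ wavelengths must equal $k$ tissues; a least-squares path for extra
  wavelengths exists in the solver design but square-exact is the default
  and the tested configuration.
* Characterized coefficients are assumed transferable from homogeneous
  specimens to the composite scene; humidity and specimen variation break
  this in practice.
* Otsu thresholding assumes a bimodal thickness histogram per tissue; maps
  without clear structure need a fixed threshold.
* The YAML/CSV/TIFF interfaces assume single-frame, single-channel data
  throughout.
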