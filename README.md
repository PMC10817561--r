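# biodecomp

Decomposes multispectral near-infrared (NIR) transmittance images of a
layered biological specimen into per-tissue **thickness maps** by inverting
the Beer–Lambert attenuation system pixel by pixel.

## The problem and the model

A transmittance image taken through a specimen superimposes every tissue
along the optical axis: meat, bone and skin all darken the same pixel. But
each tissue attenuates each wavelength differently. Photograph the same
frame at k monochromatic wavelengths and, at every pixel (x, y), the
Beer–Lambert law for stacked layers gives a linear system:

```
T_λ(x,y) = I_λ(x,y) / I0_λ(x,y) = exp( − Σ_t  μ_{λ,t} · d_t(x,y) )

⇒   μ · d(x,y) = ln T⁻¹(x,y)
```

where `μ` is the k×k **attenuation coefficient matrix** (rows = wavelengths,
columns = tissues, cm⁻¹), `d(x,y)` the unknown per-tissue thicknesses (cm)
and `ln T⁻¹(x,y)` the log-inverse-transmittance vector measured from the
object and no-specimen reference images. Solving the system at every pixel —
one LU factorization of `μ`, applied to all pixels — yields one thickness
image per tissue.

The package provides the full workflow:

* **characterization** — estimate each `μ_{λ,t}` from homogeneous specimens
  of known thickness (`attenuation_plane()`, `mean_attenuation()`), remove
  the thin-specimen case bias with the asymptotic regression
  `μ(d) = β₀ + β₁·d⁻³` (`fit_asymptotic()`), and assemble/diagnose the
  matrix (`build_attenuation_matrix()`, `matrix_diagnostics()`);
* **decomposition** — `transmittance_stack()` →
  `log_inverse_transmittance()` → `decompose_stack()` →
  `render_thickness_image()`;
* **phantom** — a synthetic-scene generator (`phantom_preset()`,
  `simulate_phantom()`) with Gaussian-beam illumination, multiplicative
  speckle, read noise, saturation clipping and quantization, carrying exact
  ground truth;
* **evaluation** — Sørensen–Dice and matching-area overlap of thresholded
  maps plus continuous recovery metrics (`accuracy_report()`);
* a CLI (`run_cli()`, installed script `inst/scripts/biodecomp`) tying the
  stages together with reproducible JSON manifests.

## Worked example

The packaged reference matrix holds NIR attenuation coefficients of chicken
meat, bone and skin at 780, 808 and 980 nm:

```r
library(biodecomp)
m <- chicken_attenuation_matrix()
matrix_diagnostics(m)
#> <matrix_diagnostics> determinant = 0.0869529, condition = 365.378, invertible: TRUE
```

The determinant is small — the three wavelengths are close together, so the
rows are nearly linearly dependent — which is exactly what the diagnostics
are there to surface: a condition number of 365 means measurement noise in
`ln T⁻¹` is amplified by up to that factor in the recovered thicknesses.

Simulate a three-block phantom, decompose it, and score the result:

```r
spec <- phantom_preset("side_by_side", frame_shape = c(256L, 256L), seed = 1,
                       noise = list(speckle_sigma = 0, read_sigma = 0),
                       quantize = FALSE)
out <- simulate_phantom(spec, m)
res <- decompose_phantom(out, m)
accuracy_report(res$thickness_maps, out$ground_truth)
#> Decomposition accuracy (per tissue):
#> tissue      overlap_ratio     dice    area_pred     area_ref    rmse_cm
#> meat               100.0%   100.0%         8192         8192  3.059e-16
#> bone               100.0%   100.0%         8192         8192  5.004e-16
#> skin               100.0%   100.0%         8192         8192  2.906e-16
```

With noise and quantization off, recovery is exact to machine precision and
every tissue's Dice and overlap ratio are 1.0: the forward rendering and
the per-pixel solve are exact inverses. With the default acquisition noise
(speckle σ = 0.02, read σ = 2 counts) accuracy degrades — more for the
tissues whose coefficients are most collinear — mirroring how the
ill-conditioned matrix behaves on real images.

The same chain from a shell:

```sh
biodecomp simulate --preset side_by_side --seed 7 --out sim/
biodecomp decompose --in sim/ --out dec/
biodecomp evaluate  --pred dec/ --truth sim/ --out report.json
```

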