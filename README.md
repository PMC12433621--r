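# btd — bone and tissue decomposition of single X-ray images

Bones in radiographs are wrapped in soft tissue that scatters X-rays and
washes out bony detail. `btd` virtually decomposes a single grayscale
radiograph `f` (intensities in `[0, 1]`, bones-bright convention) into a
smooth **soft-tissue image** `T` and a **bone image** `B` that live on the
same raster, under the nonlinear composition model

```
f(x, y) = (1/α) · B(x, y) · (1 − T(x, y)) + T(x, y),    α ≥ 1.
```

This is the scattered-light (dehazing) family of models rather than the
additive `f = f_tissue + f_bone` used in classical bone suppression. It is
aimed at researchers and tool builders working with skeletal radiographs:
bone-fracture reading, bone-age assessment, soft-tissue (e.g. pneumonia)
analysis, and training-data preparation.

## Method

1. **Mask.** A flexible binary mask `M` that merely *covers* the bones is
   obtained by thresholding plus morphology (`estimate_mask()`), or
   supplied by the user (`validate_user_mask()`). It need not align with
   bone boundaries.
2. **Tissue.** Inside `M`, `T` solves the Laplace equation
   `ΔT = 0` with Dirichlet data `T = f` on `∂M` (the pixels just outside
   `M`); outside `M`, `T = f`. Discretely: every mask pixel equals the
   mean of its 4 neighbors (`solve_tissue()`, sparse Cholesky in exact
   mode, a pyramid approximation in fast mode).
3. **Scale.** With the bone maximum normalized to one,
   `α = 1 / max_p [(f − T) / (1 − T)] ≥ 1` (`compute_alpha()`).
4. **Bone.** `B = α (f − T) / (1 − T)` (`compute_bone()`), so
   `max(B) = 1`, `B = 0` wherever `f = T`, and — because `α/(1−T) ≥ 1` —
   `|∇B| ≥ |∇f|` wherever the tissue is locally flat: the bone image has
   provably enhanced contrast.

`decompose()` runs the full pipeline and returns `T`, `B`, `α` and
diagnostics (stencil residual, clamp count, contrast report).

## Worked example

Phantoms generated by the forward model give ground truth to decompose
against:

```r
library(btd)
ph  <- generate_phantom(phantom_spec(height = 128, width = 128,
                                     alpha_true = 2.2, tissue_kind = "smooth",
                                     n_bones = 2, seed = 7))
dec <- decompose(ph$f, ph$M_true)
dec
#> Bone-tissue decomposition (128 x 128)
#>   alpha            : 2.06546
#>   max(B)           : 1
#>   mask pixels      : 1955
#>   max residual     : 1.67e-15
#>   clamped pixels   : 0
#>   fraction enhanced: 1.0000
str(evaluate_recovery(ph, dec))
#> List of 6
#>  $ rmse_T           : num 0.00532
#>  $ rmse_B           : num 0.0116
#>  $ max_err_T        : num 0.0316
#>  $ max_err_B        : num 0.0892
#>  $ alpha_rel_error  : num 0.0612
#>  $ fraction_enhanced: num 1
```

The recovered `α = 2.07` sits close to the true 2.2 even though this
phantom's tissue is *not* harmonic inside the mask (the model's smoothness
assumption only holds approximately); `max residual ≈ 2e-15` shows the
tissue solve is harmonic to machine precision, and `fraction enhanced = 1`
says every evaluated flat-tissue pixel gained contrast in `B`. On
`tissue_kind = "harmonic_in_mask"` phantoms the recovery of `(T, α, B)` is
exact to solver tolerance.

For real images:

```r
f   <- load_radiograph("hand.png")            # invert = TRUE for bones-dark data
m   <- estimate_mask(f)                        # Otsu + morphology, or load_mask()
dec <- decompose(f, m)
save_image(dec$tissue, "tissue.tif", "float")
save_image(pmin(dec$bone, 1), "bone.tif", "float")
```

A command-line front end wrapping the same functions ships in
`system.file("cli", "btd.R", package = "btd")` with subcommands
`decompose | recompose | phantom | selftest`.

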