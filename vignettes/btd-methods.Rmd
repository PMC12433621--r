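---
title: "Bone-tissue decomposition: model, solver, and phantom design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone-tissue decomposition: model, solver, and phantom design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btd)
```

## The model

A radiograph records differential X-ray attenuation: bone attenuates more
than soft tissue, and after the customary subtraction step bone appears
bright. Soft tissue scatters the beam much as fog scatters visible light,
which motivates a multiplicative, dehazing-style composition instead of
the additive `f = f_tissue + f_bone` of classical bone suppression. `btd`
decomposes an observed image $f \in [0,1]$ as

$$f = \tfrac{1}{\alpha} B\,(1 - T) + T,$$

with $T$ the soft-tissue image, $B$ the bone image, and $\alpha$ a single
global scalar. $f = T$ forces $B = 0$ (no bone at that pixel);
$T = 0$ gives $f = B/\alpha$ (pure bone). A *global* $\alpha$ is
deliberate: a spatially varying gain could look better locally but would
destroy the linear relationship between pixel intensity and physical
dose, which is what makes the outputs quantitatively interpretable.

The problem is ill-posed (three unknowns, one observation per pixel) and
becomes solvable under four assumptions:

1. $T \le f$ — tissue never exceeds the observation, so $B \ge 0$;
2. $0 \le T < 1$ — keeps the denominator $1 - T$ positive;
3. $T$ is smooth (second-order differentiable) — the physical
   configuration of soft tissue varies slowly;
4. $\max B = 1$ — fixes the scale and determines $\alpha$.

## Tissue: a masked Laplace problem

Given a binary mask $M$ that covers the bones, the tissue inside $M$ is
the minimizer of the Dirichlet energy $\int_M \|\nabla T\|^2$ subject to
$T = f$ on $\partial M$, i.e. the solution of $\Delta T = 0$ in $M$.
Discretely (5-point stencil, 4-neighborhood, row/column raster with
top-left origin) every mask pixel equals the mean of its four neighbors.
The mask itself is *flexible*: it only needs to cover bone, not trace its
boundary, and different reasonable masks give similar decompositions.
`estimate_mask()` implements threshold + morphology (Otsu by default,
closing radius 3, hole filling, minimum component area 64 px, dilation
radius 5 — generous over-coverage by design); hand-drawn masks enter via
`validate_user_mask()`.

Numerical choices:

* **Exact mode** assembles, per 4-connected mask component, the sparse
  symmetric positive-definite system and solves it by sparse Cholesky.
  This is the reference path; its 5-point residual at interior pixels is
  verified against the configured tolerance (default $10^{-8}$; the
  direct solve typically reaches $10^{-15}$).
* **Fast mode** is a coarse-to-fine pyramid: factor-2 restriction until
  the system has at most 512 unknowns, exact solve there, bilinear
  prolongation, then red-black Gauss–Seidel smoothing (capped by
  `max_iter` sweeps per level). It is an approximation — residuals are
  reported, never asserted — and the built-in `run_selftest()` harness
  rejects configurations too approximate to honor the exact-mode
  guarantees.
* **Border-touching masks** are allowed: a missing off-grid neighbor
  takes the edge-replicated Dirichlet value $f$ at the border pixel
  itself. Components are solved independently in deterministic order, so
  identical inputs give bit-identical outputs.
* **Clamps.** Assumption 2 is enforced by capping $T \le 1-\varepsilon$
  (default $\varepsilon = 10^{-6}$) *inside the mask only* — outside,
  $T = f$ exactly, and the closed-form ratio below treats the saturated
  $f = T = 1$ case as ratio 0. Assumption 1 is enforced after the solve
  by the pixelwise clamp $T \leftarrow \min(T, f)$, because the harmonic
  interpolant may overshoot $f$ at isolated pixels; the number of clamped
  pixels is reported in the diagnostics.

## Alpha and the bone image

With $\max B = 1$,

$$\alpha = \frac{1}{\max_p \frac{f - T}{1 - T}}, \qquad
  B = \alpha\,\frac{f - T}{1 - T}.$$

Since $f \le 1$ the ratio never exceeds 1, hence $\alpha \ge 1$ for every
valid input — the package's central guarantee. Negative numerators cannot
occur after the assumption-1 clamp. If the maximal ratio is below
`eps_alpha` ($10^{-6}$), $f$ is tissue everywhere and the decomposition
reports *no bone signal* rather than manufacturing a bone image.

Differentiating $B$ gives
$\nabla B = \alpha\left[\frac{\nabla f}{1-T} -
\frac{1-f}{(1-T)^2}\nabla T\right]$: wherever the tissue is locally flat
($\nabla T \approx 0$), $|\nabla B| \ge \alpha |\nabla f| \ge |\nabla f|$
— bone contrast is enhanced. `contrast_report()` quantifies this with
forward differences (zero-padded at the last row/column so no fictitious
edge appears), evaluated at mask pixels with $|\nabla T|$ at most
`flat_threshold` (default $10^{-3}$ intensity/pixel); ties count as
enhanced. The model also yields the nonlinear suppression formula
$T = \frac{f - B/\alpha}{1 - B/\alpha}$ (`tissue_from_bone()`), which
dominates the linear baseline $f - f_\mathrm{bone}$ pixelwise whenever
$f \le 1$; the sole exception in the clipped implementation is the corner
$f = 1, B = 0$, where the $\varepsilon$ ceiling on $T$ trims the
nonlinear estimate by exactly $\varepsilon$.

## The phantom generator

`generate_phantom()` runs the model forward so that every stage can be
tested against known ground truth:

* **Tissue** is a sum of four cosine modes with random orientation,
  phases, and frequencies of 0.25–1 cycles across the field of view,
  rescaled to $[0, 0.55]$. Soft tissue varies at the scale of the whole
  anatomy, so sub-cycle frequencies are the realistic regime; they also
  keep the field far from the $T < 1$ bound.
* **Bone** is a union of 1–3 random ellipses (semi-axes 8–18% of the
  short image dimension, placed with margins so the mask stays off the
  border) with a smooth $1-\rho^2$ profile times a cosine ripple
  (relative amplitude 0.2, wavelength 4–12 px) — the ripple gives bone
  interiors nonzero texture so gradient-based contrast checks are not
  vacuous. The union is rescaled so its maximum is exactly 1.
* **Mask** is the bone support dilated by 3 px, so the Dirichlet ring is
  bone-free and carries pure tissue values.
* Three tissue kinds control how hard recovery is:
  `"harmonic_in_mask"` replaces the field inside the mask by the discrete
  harmonic interpolant of its own boundary values — by uniqueness of the
  Dirichlet solution, the pipeline then recovers $(T, \alpha, B)$ exactly
  up to solver tolerance; `"constant_in_mask"` sets the field to the
  boundary mean on the mask *and* its boundary ring, making
  $\nabla T = 0$ exactly at every mask pixel (the regime where contrast
  enhancement is exact, and the reason the constant extends to the ring:
  a constant on the mask alone would leave near-threshold tissue
  gradients at ring crossings where $B = 0$); `"smooth"` leaves the
  non-harmonic field untouched, representing the model-mismatch regime
  where recovery errors are finite and reported, not asserted.
* Noise, when requested, is added to the observation only — ground truth
  stays clean, as with a physical sensor. All randomness flows from one
  recorded seed; generation restores the caller's RNG state.

What the phantoms *do not* emulate: Beer–Lambert ray physics, anatomy
(joints, trabeculae, overlapping bones), detector blur, scatter kernels,
or saturated regions. Passing phantom tests therefore demonstrates the
mathematical contract of the decomposition — harmonicity, $\alpha \ge 1$,
$\max B = 1$, exact recomposition, recovery under the model's own
assumptions — not clinical adequacy on real radiographs, where tissue is
only approximately smooth and masks are imperfect.

## Problem sizes and I/O conventions

The guarantee suites run on 64×64 phantoms (hundreds of unknowns per
mask; a hundred decompositions complete in seconds) plus a single
1024×1024 phantom (~150k unknowns) exercising the sparse solver at
realistic scale. Integer images are normalized by the *dtype* full-scale
maximum, never the per-image maximum, to preserve the intensity–dose
relationship; the pipeline works exclusively in the bones-bright
convention with an explicit `invert` flag (no auto-detection, which is
unreliable). Float TIFF output is lossless; integer output uses
round-half-up quantization.

## Known limitations

* Accuracy degrades when the mask contains strong non-harmonic tissue
  structure (the homogeneity assumption fails); artifacts then leak into
  the bone image. Use tighter masks or accept the reported residual
  errors.
* $\alpha$ is estimated from a single extremal pixel; a hot pixel inside
  the mask can deflate it. Phantom noise studies should use the reported
  `alpha_rel_error` rather than assuming exactness.
* Fast mode trades accuracy for speed and has no error bound; use exact
  mode (the default) whenever its runtime is acceptable.
* DICOM is out of scope; convert to PNG/TIFF first. PNG output is 8-bit;
  use TIFF for 16-bit or float.
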