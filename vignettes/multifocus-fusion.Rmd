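---
title: "Saliency-weighted multi-focus fusion with a gradient-domain fast guided filter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saliency-weighted multi-focus fusion with a gradient-domain fast guided filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mffuse)
```

## The problem and the model

A focal stack from a fixed-aperture camera contains, for every scene
region, at least one frame in which that region is sharp. Multi-focus
fusion estimates a per-pixel *focus decision* — which source is sharp
where — and composites accordingly. `mffuse` makes that decision with
three per-source saliency measures, hardens it with a winner-take-all
rule, and then relaxes it back into a spatially coherent, edge-aligned
weight field with an edge-preserving guided filter. Blending happens on a
two-scale decomposition so low-frequency shading and high-frequency
texture can carry different (independently refined) weights.

The assumptions are explicit and worth keeping in mind:

* sources are **co-registered** and photometrically consistent (same
  exposure, no motion); no alignment is attempted;
* defocus is the dominant difference between sources, so local gradient
  magnitude is a valid focus proxy;
* inputs live in `[0, 1]` after loading; 8-/16-bit integer files are
  rescaled on read.

### Stage by stage

**Two-scale decomposition.** `two_scale_decompose()` takes base
`B = I ∗ G(σ, r)` per channel and `D = I − B`. Reconstruction is exact by
construction, so the decomposition introduces no information loss; it only
routes frequency bands to different weight maps.

**Visual saliency (VS).** The product of a frequency prior (band-pass
energy over the three CIELAB planes), a colour-warmth prior on min–max
normalized a\*/b\*, and a centre-bias prior. The band-pass is a log-Gabor
transfer function applied in the frequency domain; a spatial
difference-of-Gaussians alternative (`bandpass = "dog"`) is provided for
workflows that need strictly finite support (it is also what the
shift-equivariance tests use, since the log-Gabor path is circular at the
borders).

**Gradient magnitude (GM).** Scharr derivatives of the opponent-space
luminance `L = 0.06R + 0.63G + 0.27B`, smoothed. This is the term that
actually separates sharp from defocused copies of the same content; VS
and CD are nearly identical across the sources of a focal stack and act
as stabilizers and colour-distortion guards.

**Chrominance (CD).** The per-pixel product `M·N` of the two opponent
chrominance channels is signed; it is rectified to `|M·N|` because the
weight-map exponent `γ` is fractional and fractional powers of negative
numbers are undefined. Each of the three maps is min–max normalized to
`[0, 1]` per source before combination — the maps have incommensurate
physical scales and a multiplicative combination is only meaningful on a
common one.

**Weight maps.** `W = VS^α · GM^β · CD^γ`, then per-pixel argmax across
sources, then normalization. An exponent of zero disables a map (`0^0` is
defined as 1 so that "ignore this map" holds at zero values too). The
argmax makes the subsequent normalization a no-op except at exact ties;
both steps are kept as separate composable operations.

**Refinement.** The binary maps are noisy at object boundaries. Each is
filtered with the gradient-domain guided filter guided by the source's
luminance: local linear models `Q = a·G + b` are fit per window with the
slope penalized toward an edge indicator `γₖ` (≈1 on edges, ≈0 in flat
regions) at strength `λ/Γ̂`, where `Γ̂` is an edge-aware weight built from
products of local standard deviations. Dividing by `Γ̂` weakens the
penalty on edges — that is what keeps the refined weight transition
aligned with the true occlusion/focus boundary instead of halo-ing across
it. The fast variant computes all window statistics on an `s`-fold
nearest-neighbour-subsampled grid (window radius scaled down by `s` so the
spatial footprint is preserved) and upsamples the averaged coefficients
bilinearly on a grid aligned with the decimation; `s = 1` is exactly the
full filter.

**Morphology.** Thresholding the refined base/detail maps at 0.5, filling
small holes on both the focus and defocus sides, and removing 8-connected
components below `min_area` snaps the decision back to clean regions.

**Blending.** One weight map per source, shared across R, G and B (a
per-channel decision would risk colour fringing at boundaries); clipping
to `[0, 1]` happens only after the base and detail sums, because detail
layers are signed and intermediate clipping would bias the blend.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha`, `beta`, `gamma` | 1, 0.89, 0.31 | – | exponents of VS/GM/CD in the weight product |
| `sigma_c` | 0.25 | – | colour-warmth prior width on normalized a\*/b\* |
| `sigma_d` | 114 | px | centre-bias width |
| `omega0`, `sigma_f` | 0.002, 6.2 | cycles/px, – | log-Gabor centre frequency and bandwidth |
| smoothing `σ, r` | 2, 7 | px | blur of each raw saliency map |
| `zeta1`, `eps` (×2 passes) | 4, 1e-6 | px, – | guided-filter window radius and edge-weight stabilizer |
| `lam` | `(0.001·L)²` | – | regularization strength, tied to the range constant `L = 9` |
| `s` | 4 | – | subsampling factor of the fast filter |
| decomposition `σ, r` | 5, 15 | px | base/detail split scale |
| `binarize_threshold` | 0.5 | – | morphology threshold on refined weights |
| `min_area` | 1% of pixels | px² | smallest surviving focus/defocus region |

The exponent and filter defaults are the reference operating point of the
method; the saliency prior constants are the published defaults of the
frequency/colour/location saliency detector the VS map follows. The map
smoothing (σ = 2) and decomposition scale (σ = 5) are not prescribed
anywhere: the first is the smallest blur that reliably stabilized the
per-pixel argmax in our tests, the second a moderate scale that puts
shading into the base layer and texture into the detail layer; both are
exposed in `fusion_config()`.

## Design choices that were genuinely open

* **Regularization form.** The gradient-domain filter is implemented with
  `λ/Γ̂` (weaker smoothing across edges), which is the form that realizes
  the halo-suppression intent; `reg_form = "multiply"` reproduces the
  alternative `λ·Γ̂` coupling for comparison.
* **Second-pass guidance.** The detail weight map is the refinement of
  the base weight map guided by the *source luminance* (the formula
  reading); `detail_guidance = "base"` selects the alternative of guiding
  by the base weight map itself.
* **Scharr pair.** The vertical derivative uses the transpose of the
  horizontal Scharr kernel — a gradient operator needs two orthogonal
  derivatives. With the 1/16 normalization, the response to a unit ramp
  is 2 (the kernel weights a two-pixel baseline), which is immaterial
  downstream because GM maps are min–max normalized.
* **Size-capped hole filling.** Unconditional hole filling would delete
  any in-focus region that does not touch the image border (a focused
  plant blob surrounded by defocused background is a "hole" of the
  defocus mask). Holes are therefore only filled when smaller than
  `min_area`; larger enclosed regions are treated as legitimate structure.
  This keeps blob-type focus masks intact while still removing pinholes
  and speckle.
* **Degradation monotonicity reference.** Progressively blurring a fused
  candidate should never raise its quality scores — *against a sharp
  reference*. Scored against the partially defocused sources themselves,
  the property is provably violated near the sources' own blur level (a
  blurred candidate matches their blurred halves better); the monotonicity
  tests therefore use the all-in-focus image as the reference pair.
* **Ties.** The argmax breaks ties toward the lowest source index —
  deterministic and order-stable. Swapping two generic sources changes
  the output only through tie pixels, which have measure zero for
  continuous-valued maps (asserted in the tests).

## Numerical and degenerate-input conventions

* Replicate padding for every convolution and windowed statistic; the
  Gaussian kernel is truncated at `r = ceiling(3σ)` unless given.
* A channel whose min–max range is below `1e-9` of its magnitude is
  treated as constant and normalizes to zero (prevents amplifying
  floating-point noise of flat a\*/b\* channels to full scale).
* Constant `χ` in the edge indicator (flat guidance) yields `γₖ = 0.5`;
  windows with zero variance in both sources give the QY weight 0.5;
  zero-entropy images contribute 0 to QMI with a warning; pixels with no
  gradient in source and fused image carry zero QAB/F weight.
* All-zero weight pixels normalize to the uniform `1/N`.
* QMI uses 256 histogram bins on 8-bit-quantized values. The plug-in MI
  estimator's upward bias is of order `bins²/(2n)`; the independence
  tests use images large enough (384²) for the asymptotic limit to show.

## The synthetic fixtures: what they do and do not show

`make_truth("plant-like")` composes elliptical green blobs with darker
rims over textured brownish ground plus fine grain — enough gradient
structure that every saliency map is informative. A multi-focus pair
blurs the truth outside a half-plane or blob mask (Gaussian, σ = 3 by
default), optionally with a feathered transition and seeded sensor noise
(off by default; recovery thresholds are calibrated noise-free).

These fixtures emulate *complementary regional defocus with known ground
truth*. They do not emulate: depth-dependent (spatially varying) blur, a
real lens PSF with bokeh, misregistration between frames, exposure
differences, or demosaicing artifacts. Passing the recovery tests
(fused PSNR over 30 dB and well above either source; refined weights
matching the true mask off-boundary; all three metrics beating the
average-fusion baseline) shows the decision and blending machinery works
when the focus signal is clean; performance on real stacks additionally
depends on registration quality and noise, which the tests deliberately
exclude.

Problem sizes used by the test-suite and the acceptance script: 512²
pixels for the five-pair recovery study, 256² for determinism and
monotonicity, 16²–32² for the brute-force oracle equivalences — small
enough to compare against explicit per-window loops, large enough that
border handling is exercised.

## Known limitations

* Runtime is dominated by the per-source saliency stack and the
  connected-component pass; a 512×512 pair fuses in a few seconds.
* The centre-bias prior is a static Gaussian; for imagery where the
  subject is off-centre it contributes a mild global tilt to VS (it
  cancels between sources, so focus decisions are unaffected).
* Exactly coinciding saliency products between sources fall back to
  source order; this only matters for artificially identical inputs.
* The morphology stage assumes the focus partition consists of regions of
  at least `min_area` pixels; genuinely fine interleaved focus patterns
  (e.g. a mesh in front of the subject) need `min_area` lowered or the
  stage disabled (`morph_params(apply = FALSE)`).
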