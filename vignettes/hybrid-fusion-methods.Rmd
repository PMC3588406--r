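---
title: "Methods: hybrid multiscale fusion of GFP and phase-contrast images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid multiscale fusion of GFP and phase-contrast images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sflctfuse)
```

`sflctfuse` fuses a registered pair of micrographs of the same cells — a
colour GFP fluorescence image and a grayscale phase-contrast image — into
one colour image that keeps the protein-localization signal of the first
and the structural detail of the second. This vignette documents the
model, the tunable parameters, the numerical choices, and what the
synthetic test data do and do not establish.

## The fusion model

The colour image is first separated with the triangle IHS model. Hue and
saturation are never modified: colour fidelity of the fluorescence signal
is an invariant of the whole pipeline, and all fusion happens on the
intensity plane. The intensity plane of the GFP image and the phase
image are decomposed with a multiscale directional transform, merged
coefficient-by-coefficient under three rules, and the inverse transform
plus inverse IHS produce the result.

The rules encode a simple prior about the two modalities. Coarse-scale
(approximation) structure should follow whichever modality has locally
more of it, measured by mean-removed window energy (MRE); in practice
that is the fluorescence distribution where the GFP image has structure,
because phase-contrast optics suppress low spatial frequencies. The
finest details should come from whichever image has the stronger edge at
that point (MAV), which is almost always the phase image. At the
intermediate scales the two images may genuinely disagree, so a
consistency score `Ψ` over an oriented coefficient neighborhood decides:
inconsistent neighborhoods (`Ψ < T`) are resolved by selection (the
higher-energy side wins), consistent ones (`Ψ ≥ T`) by a `Ψ`-weighted
blend that stays inside the per-position envelope of the two
coefficients.

Inputs are assumed registered; the package performs no alignment.

## The transform

The multiscale stage is a frequency-designed pyramid: a low-pass
response `L(ω)` equal to 1 inside the square `‖ω‖∞ ≤ ω_p`, 0 outside
`‖ω‖∞ ≥ ω_s`, with a raised-cosine transition, and `H = sqrt(1 − L²)`,
applied in the FFT domain with periodic boundaries. Because
`|L|² + |H|² = 1` holds exactly on the grid and `ω_s ≤ π/2` makes the
decimated low-pass branch alias-free, perfect reconstruction is a
mathematical identity rather than a numerical approximation; observed
round-trip errors are at the 1e-15 level. The transform is
energy-preserving (tight frame): coefficient energy equals image energy,
and a constant image `c` appears in the approximation as `c·2^J`.

The directional stage is realized directly in the frequency domain. The
DFT grid is partitioned into `n` equal-count bowtie wedges whose
boundaries lie on the axes and diagonals of the frequency square
(uniform bins in a slope coordinate, so areas are equal); each wedge is
packed into a small rectangular spectrum by an integer lattice fold
(rows by 2 and columns by `n/2` for wedges near the row-frequency axis,
transposed for the others; sheared quincunx-kernel folds for the
two-channel fan). Each subband is therefore the decimation of a
wedge-band-passed signal: real, spatially coherent, and shift covariant.
Exactness is enforced when the packing plan is built: every frequency
bin is assigned to exactly one wedge, every packed slot carries at most
one bin (an augmenting-path matcher resolves boundary-line collisions by
moving boundary bins to the adjacent wedge), Hermitian pairs stay
together, and the few self-paired bins that fold onto a single
self-conjugate slot store their real part there and route the imaginary
part to an otherwise-empty slot with energy-preserving scaling. The
stored coefficient count equals the pixel count exactly, and the
directional stage is itself a tight frame.

Two consequences are worth noting. First, the wedge masks are sharp in
frequency, so individual subbands show spatial ringing; this does not
affect reconstruction (exact by construction) and is immaterial to the
selection-style fusion rules. Second, because wedge boundaries sit *on*
the axes and diagonals, no subband is centered exactly on an image axis;
direction labels are anchored to the lower edge of each wedge's
orientation support, so label 0 covers orientations starting at
horizontal. The neighborhood-class map derives from these labels: a
subband whose support edge lies within 22.5° of an image axis uses the
oriented cross-arm (Nhd I), all others the rotated diamond (Nhd II).
Both shapes are bounded by the NCM window and are configurable through
`fusion_config(neighborhood_model = ...)`, since the empirical
assignment is a convention, not a derived quantity.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `levels` | 4 | — | pyramid depth; approximation is `size / 2^levels` |
| `dirs_per_level` | 4, 8, 16, 16 | — | directions, coarsest → finest |
| `omega_p` | 4π/21 | rad | low-pass passband corner |
| `omega_s` | 10π/21 | rad | low-pass stopband corner (≤ π/2) |
| `mre_window` | 3 | px | MRE window side |
| `ncm_window` | 5 | px | bound on NCM neighborhood offsets |
| `threshold_T` | 0.75 | — | NCM switch; admissible interval (0.5, 1), default its midpoint |

`dirs_per_level` is stored coarsest-to-finest: finer scales carry more
orientations. The `abs_compare` flag switches the NCM blending branch
from signed max/min (the default, as the rule is written) to a
magnitude-based variant discussed in the fusion literature.

## Numerical conventions and degenerate inputs

* IHS: exact black gets `S = 0, H = 0`; achromatic pixels get `H = 0`;
  the arccos argument is clamped to [−1, 1]. The sector inverse is the
  standard triangle inverse, verified by the round-trip identity (1e-9
  over a 17³ RGB grid). Out-of-gamut inverse values are clipped to
  [0, 1] and counted; clipping is a real phenomenon when a bright
  intensity meets high saturation, and is exactly what degrades the
  substitution baseline.
* Rule ties: MRE ties select B (the rule's inequality is `≤` on the B
  branch), MAV ties select A, the NCM selection branch resolves
  `ρ_A = ρ_B` to A. `Ψ := 1` when both neighborhoods are identically
  zero (0/0 avoided; the blend then returns 0 either way). `Ψ` may be
  negative and is never clamped; since `T > 0.5`, negative values always
  route to the selection branch.
* All windowed rules use symmetric padding, so border windows see
  reflected data instead of the opposite border.
* Images not divisible by `2^levels` are symmetrically padded to the
  next multiple and cropped after reconstruction.
* Otsu: 256 bins on [0, 1], candidate cuts at interior bin edges,
  smallest maximizing cut returned; constant-histogram images are an
  error. On a well-separated bimodal histogram the between-class
  variance is flat across the empty valley, so any cut in the valley is
  optimal — comparisons with other implementations should compare
  achieved variance, not the cut.
* VIF: the pixel-domain variant — Gaussian-windowed local statistics at
  4 dyadic scales (window sides 17, 9, 5, 3; sd = side/5), additive-noise
  channel model with `σ_n² = 2` on the 0–255 scale. Region restriction
  includes windows whose center pixel is in the region; the mask is
  decimated alongside the images. Scores are comparable within this
  implementation only; the published region-wise scores for the real
  117-pair dataset use external data and are not reproduction targets.

## What the synthetic generator emulates

`make_pair()` draws a shared ellipse geometry and renders it twice.
The GFP modality has a near-black, green-tinted background whose dark
pixels keep noticeable, noisy saturation (as real fluorescence
backgrounds do), faint smooth autofluorescent cell bodies, bright green
blobs with a wide out-of-focus halo in the fluorescent cells, and a mild
darkening vignette. The phase modality is bright, with dark edge rings
and outer halos at cell boundaries, strong band-limited intracellular
texture, and truncated Gaussian sensor noise; its low frequencies are
deliberately flat, mimicking phase-contrast shade-off. Defaults: 256²
pixels, 8 cells, half of them fluorescent, background intensity 0.05,
noise 0.01, texture at 0.25 cycles/pixel, phase background 0.6.

These choices were fixed from the qualitative description of the real
data before any benchmark was run, and they are what make the
method-ordering property reproducible in silico: substitution pushes the
bright phase intensity through the noisy background saturation,
overflows the gamut, and loses texture where channels clip, while the
hybrid keeps the background near the darker GFP approximation level.
Passing these tests shows the pipeline behaves as designed under that
mechanism; it does not certify performance on real micrographs, which
add registration error, uneven illumination, shot noise, and optical
artifacts the generator does not model.

Determinism: every stochastic fixture flows from one Mersenne-Twister
seed through a private RNG scope, so generated data are bit-identical
across calls and platforms.

## Design choices made where the design was open

* The directional bank is a single frequency-domain realization rather
  than a spatial ladder filter network; the `"pkva"` filter identifier
  selects it. Perfect reconstruction and critical sampling are enforced
  at the index level and verified by property tests (reconstruction,
  Parseval, orientation selectivity, linearity) rather than by a second
  implementation.
* Pyramid normalization is tight-frame (energy preserving), asserted by
  Parseval tests; the same prototype filter pair, resampled on the
  current grid, is used at every level.
* The substitution baseline replaces the intensity by the phase image
  directly — the conventional component-substitution reading.
* NCM applies to every detail level except the finest (which uses MAV);
  the approximation uses MRE.

## Problem sizes used by the tests

The suite exercises 256² images for end-to-end contracts (transform
round trips, self-fusion identity, and 20-pair method comparisons) and
8²–128² fixtures for rule-level oracles and metric properties; the full
suite runs in well under a minute on one CPU. These sizes match the
256×256 working resolution the pipeline is designed around.

## Known limitations

* No registration: misaligned pairs produce ghosting; alignment is the
  caller's responsibility.
* The directional bank requires even dimensions compatible with the
  direction counts; arbitrary sizes are handled by padding at the
  pyramid stage only.
* Sharp frequency wedges mean individual subbands are not ringing-free;
  applications that interpret single subbands visually may prefer smooth
  masks, which would trade exactness of the packing for smoothness.
* VIF absolute values depend on the variant and its constants; only
  within-implementation comparisons (between methods on the same pair)
  are meaningful.
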