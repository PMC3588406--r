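# sflctfuse

Hybrid multiscale fusion of GFP fluorescence and phase-contrast microscopy
images in R.

Fluorescence and phase-contrast imaging answer complementary questions
about the same living cells: a GFP micrograph shows *where* a labelled
protein is (bright green blobs on a nearly black background), while the
phase-contrast micrograph shows *what the cell looks like* (fine,
high-contrast structural detail on a bright background). Overlaying them
naively either drowns the structural detail in darkness or destroys the
colour information that localizes the protein. `sflctfuse` merges a
registered pair into a single colour image that keeps both.

## Method

For a registered pair — GFP image *A* (24-bit RGB) and phase-contrast
image *B* (8-bit gray), both rescaled to [0, 1] — the pipeline is:

1. **Triangle IHS transform** of *A* into intensity, hue and saturation:
   `I = (R+G+B)/3`, `S = 1 − 3·min(R,G,B)/(R+G+B)`, and the arccos hue
   formula with `H = α` when `B ≤ G`, else `2π − α`. Hue and saturation
   carry the colour (protein localization) and are passed through
   untouched.
2. **Sharp-frequency-localization Contourlet transform (SFL-CT)** of
   `I_A` and *B*: a multiscale pyramid built from a pair of 2-D frequency
   responses `L(ω)`, `H(ω)` with `|L|² + |H|² = 1` (raised-cosine
   transition between the passband corner `ω_p = 4π/21` and the stopband
   corner `ω_s = 10π/21`; the low-pass branch is decimated by diag(2, 2),
   alias-free because `ω_s ≤ π/2`), followed by a critically sampled
   directional filter bank that splits each high-pass band into wedge
   subbands (4, 8, 16, 16 directions from the coarsest to the finest of
   the four levels). The transform reconstructs to machine precision.
3. **Three fusion rules**, one per subband role:
   - approximation subband — **maximum region energy (MRE)**: per
     position, keep the coefficient whose 3×3 window has the larger
     mean-removed energy `E = Σ_Ω (c − μ)²`;
   - finest-level detail subbands — **maximum absolute value (MAV)**:
     keep the larger-magnitude coefficient;
   - all other detail subbands — **neighborhood consistency measurement
     (NCM)**: with neighborhood energies `ρ_X = Σ_N d_X²`, the consistency
     `Ψ = 2 Σ_N d_A d_B / (ρ_A + ρ_B)` (`Ψ ≤ 1`) selects the
     higher-energy coefficient where `Ψ < T` and blends
     `Ψ·max(d_A, d_B) + (1−Ψ)·min(d_A, d_B)` where `Ψ ≥ T`
     (default `T = 0.75`). The neighborhood shape follows the subband
     orientation: a cross-arm (Nhd I) for near-horizontal/vertical
     subbands, a rotated diamond (Nhd II) for oblique ones.
4. **Inverse SFL-CT** of the fused coefficients gives the fused intensity
   `I_F`; **inverse IHS** with `(I_F, H_A, S_A)` gives the fused RGB.

Two baselines are included for comparison: `fuse_t_ihs()` (plain
component substitution `I ← B`) and `fuse_ihs_mre_mav()` (MRE + MAV on
every detail subband).

Evaluation follows the region-wise **visual information fidelity (VIF)**
protocol: Otsu's method splits the GFP intensity plane into fluorescent
and non-fluorescent areas, and the fused intensity is scored against each
source inside each region (`VIF^A-fl`, `VIF^B-fl`, `VIF^B-nfl`; 1 =
identical).

## Worked example

No external data are needed; the package generates registered synthetic
pairs that emulate the statistics of real GFP / phase-contrast
micrographs:

```r
library(sflctfuse)

pair  <- make_pair(scene_spec(seed = 11))      # 256x256 registered pair
fused <- fuse_images(pair$gfp, pair$phase)     # hybrid MRE/MAV/NCM fusion
region_vif_report(pair$gfp, pair$phase, fused)
#> <vif_report: A-fl 0.0828 | B-fl 0.3135 | B-nfl 0.5289 | otsu 0.1680>

baseline <- fuse_t_ihs(pair$gfp, pair$phase)   # plain substitution
region_vif_report(pair$gfp, pair$phase, baseline)
#> <vif_report: A-fl 0.0062 | B-fl 0.3550 | B-nfl 0.2484 | otsu 0.1680>
```

The hybrid method preserves the phase-contrast structure in the
non-fluorescent background far better than plain substitution
(`B-nfl` 0.53 vs 0.25): substitution pushes the bright phase intensity
through the noisy saturation of the dark GFP background, overflowing the
RGB gamut and flattening texture where channels clip, while the hybrid
keeps the background at the darker GFP approximation level with the phase
detail coefficients layered on top. It also transfers more GFP
information into the fused image (`A-fl` 0.08 vs 0.006). `otsu` is the
threshold that separated the fluorescent area.

The transform itself is exposed directly:

```r
co <- sflct_decompose(rgb_to_ihs(pair$gfp)$i)
co
#> <sflct_coefficients: 256x256 image, 4 levels, dirs (fine->coarse) 16,16,8,4, approx 16x16>
max(abs(sflct_reconstruct(co) - rgb_to_ihs(pair$gfp)$i))   # ~1e-15
sflct_redundancy(co)$redundancy                            # 1.332031
```

A small command line sits on top (`inst/cli/sflctfuse` after install):

```sh
sflctfuse synth --out-gfp gfp.png --out-phase phase.png --seed 4
sflctfuse fuse  --gfp gfp.png --phase phase.png --out fused.png --report report.json
sflctfuse eval  --gfp gfp.png --phase phase.png --fused fused.png --report report.json
```

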