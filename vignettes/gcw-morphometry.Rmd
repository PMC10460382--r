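---
title: "Quantifying starch in gas cell walls from polarized multiphoton stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying starch in gas cell walls from polarized multiphoton stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcwmorph)
```

## The measurement problem

A proving bread dough is a foam: gas cells separated by thinning lamellae
(gas cell walls, GCWs) of hydrated gluten with embedded starch granules.
How much of a wall's cross-section is starch, how the granules are sized,
and whether a wall is still intact or already a post-rupture "string" are
central quantities for understanding wall stability — and they can be
imaged without labels. Starch granules generate second harmonic (SHG) from
their radially arranged crystalline amylopectin; the gluten network shows
endogenous two-photon fluorescence (EF); gas is dark in every mode.

Two optical facts shape the whole analysis:

* A linearly polarized excitation lights up only a **two-lobe segment** of
  each granule, oriented along the polarization, and the centrosymmetric
  hilum at the granule core emits no SHG at all. A complete granule outline
  therefore requires combining backward and forward detection over several
  polarization angles (here 0°, 45°, 90°, 135°).
* SHG **attenuates with depth much faster than EF**, so the depth range
  usable for starch segmentation is a shallow prefix of the stack, while
  the EF signal still delimits the wall much deeper.

`gcwmorph` implements the quantification chain — fusion, depth
delimitation, granule and envelope segmentation, morphometrics — together
with a ground-truthed scene simulator, so that every stage can be validated
even though real acquisitions of this kind are not publicly deposited.

## The synthetic scene generator

`build_scene()` fills a wall slab (box of length × width × depth at a given
z-offset, optionally rotated in-plane) with ellipsoidal granules:

* **Diameters** follow a three-component lognormal mixture parameterized by
  its modes. The defaults — modes 4, 6 and 22 µm with log-sds 0.18, 0.12,
  0.25 and number weights 0.50/0.38/0.12 for C/B/A — reproduce the trimodal
  wheat-starch size distribution with its characteristic property that
  C-types dominate by number while A-types dominate by volume. A-type
  granules are rendered lenticular (polar semi-axis 0.4 of equatorial),
  B/C near-spherical.
* **Packing.** Granules are packed by collective rearrangement: a
  volume-budgeted subset of the population is dropped at random into the
  slab, then overlapping pairs are iteratively pushed apart (with an
  oblate-aware scaled distance) until residual overlaps are below 1 % of
  granule voxels, topping up with small granules or trimming until the
  areal starch fraction matches the target within ±0.02. Rejection
  sampling cannot reach the dense packings real walls show (the mean
  per-slice areal fraction of any granule arrangement equals its
  volumetric packing fraction, and sequential insertion jams near 0.55);
  pressed-together rearrangement is both the physically apt picture for
  dough and the reason targets up to 0.65 are attainable. A short second
  relaxation phase then opens a thin gap (~5 % of the pair contact
  distance, best effort) between touching granules — the gluten films
  that in real walls pass between granule surfaces — so that granules
  remain individually resolvable where space allows, while saturated
  packings stay dense. Granule z-centres are assigned by tracking
  per-slice volume capacity, keeping the areal fraction near-stationary
  in depth, and overlap resolution moves granules mostly laterally so
  this balance survives. Granules are fully embedded in depth — a
  granule thicker than the wall is excluded, as observed for thin walls
  — but may protrude laterally into the gas, as real edge granules do.
* **Ground truth.** The achieved areal fraction is recorded exactly, as
  granule pixels over wall-body pixels (gluten slab ∪ granules), averaged
  over the *representative interior band*: the first 6-µm window of slices
  whose granule content reaches the interior plateau. The first slices of
  a wall are structurally unrepresentative (a granule fully embedded in
  depth cannot intersect the wall's top slice with its equator), which is
  exactly why the measurement protocol discards leading slices; defining
  the recorded truth over the same kind of window keeps generator truth
  and pipeline estimate comparable without sharing any code path.

`render_shg_channel()` renders, per granule, concentric shells with the
angular law $|\cos(\theta_{radial}-\theta_{pol})|^p$ (default $p = 2$; only
the two-lobe phenomenology is constrained, not the exponent), an exactly
dark hilum core (default 15 % of the radius), complementary linear radial
ramps for backward (periphery-heavy) vs forward (interior-heavy) detection,
and depth attenuation $e^{-z/\lambda_{SHG}}$. `render_ef_channel()` gives
gluten a high mean level modulated by a band-pass "fibrillar" texture
elongated along the wall axis, granule interiors a low but non-zero level
(gluten/granule EF ratio ≥ 3), gas exactly zero, and slower attenuation
$e^{-z/\lambda_{EF}}$.

`apply_axial_elongation_and_noise()` emulates the tubular z-stretching of
granules seen in SHG stacks of dough (an aberration caused by the
inhomogeneous harmonophore distribution and index mismatch): the field is
resampled along z about its intensity centroid by the elongation factor,
then blurred with an anisotropic PSF (axial sigma = factor × lateral
sigma), and finally degraded with signal-dependent noise
$x + s\sqrt{x}\,\mathcal N(0,1)$. The stretch, not the blur, is what makes
an elongation factor of 2 actually double the half-max z-extent of a
rendered sphere; the blur alone would leave the half-max isosurface almost
unchanged, which is why the artifact is modelled as resampling plus PSF.
EF is blurred and noised but not stretched — depth fidelity in the EF mode
is what makes string/intact classification possible in practice.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `pixel_size_xy`, `z_step` | 0.17 µm, 0.5 µm | voxel geometry of a high-resolution GCW acquisition |
| mixture modes | 4, 6, 22 µm | C/B/A diameter modes of wheat starch |
| `hilum_radius_frac` | 0.15 | radius fraction of the SHG-dark core |
| `lobe_exponent` | 2 | sharpness of the two-lobe angular response |
| `atten_length_shg_um` | 2.5 µm | 1/e depth of SHG; with the axial stretch this yields ≈ 8–10 µm of analyzable depth, the order observed in real walls |
| `atten_length_ef_um` | 20 µm | 1/e depth of EF; EF remains usable several times deeper than SHG |
| `z_elongation_factor` | 1.4 | axial stretch of granule SHG ("somewhat tubular") |
| `psf_sigma_um` | 0.25 µm | lateral PSF sigma |
| `noise_scale` | 0.02 | shot-noise scale relative to full range |

No quantitative attenuation lengths or lobe sharpness are available for
this kind of acquisition; the defaults were chosen once so that the
qualitative orderings that are documented — SHG analyzable depth strictly
shorter than EF, two-lobe anisotropy recoverable per angle, granules
"somewhat tubular" in z — hold on every default scene, and are not tuned
further.

## The analysis pipeline

`quantify_stack()` chains the stages; each is exported on its own.

**Fusion.** `combine_polarizations()` sums (default; a voxelwise maximum is
available for saturation-prone data) all SHG channels and rescales to the
input dynamic range. With four angles and $p = 2$,
$\sum_k \cos^2(\theta - \theta_k)$ is constant in $\theta$, so the fused
image turns angle-dependent lobes into rotationally complete outlines —
the property the acceptance suite checks as outline-coverage monotonicity
and ≥ 95 % combined coverage for granules that any single angle images
incompletely (< 80 %).

**Analyzable depth.** `determine_analyzable_depth()` keeps the contiguous
run of slices whose robust (99th-percentile) maximum stays above
`contrast_floor` (default 0.1) of the brightest slice's robust maximum.
Using the brightest slice as reference — rather than the first non-empty
one — makes the criterion robust to dim leading slices produced by the
axial stretch. On a pure exponential decay with 1/e length λ the rule
recovers the analytic cutoff λ·ln(1/floor) within one z-step. The result
is a slice-level truncation (a contiguous prefix, not a per-voxel mask),
matching how such stacks are analyzed in practice.

**Granule segmentation.** Within the analyzable depth each slice is
attenuation-normalized by its robust maximum, smoothed (σ = 1 px),
thresholded (pooled Otsu by default), hole-filled — the dark hilum sits
*inside* the bright shell, so filling recovers solid granules — and closed
(disc radius 2 px). Touching granules are split by a watershed on the
in-plane distance transform (EBImage's deterministic implementation; the
tolerance and neighbourhood radius are exposed). 2D regions are linked
across slices into 3D granules when their overlap reaches half the smaller
area, via union-find with first-appearance relabelling — deterministic and
26-connected in effect. Fragments below 8 voxels are discarded.

**Envelope.** `segment_envelope()` thresholds the EF image per slice,
keeps the largest connected component (one wall per field of view), closes
and hole-fills it. The default threshold is 0.12 × the robust maximum of
the positive EF voxels: deliberately *below* the Otsu split of the
within-wall intensities, because Otsu lands between the dim starch
interiors and the bright gluten and would cut edge granules out of the
envelope; a low threshold keeps granules inside while gas (essentially
zero signal) stays out, and the PSF halo makes the envelope extend just
beyond the outermost granules, as it should. The envelope's slice extent
× z-step is the wall depth D used to classify the wall: a **string** has
D ≤ 0.6 × stack depth and D ≤ 1.5 × width; an **intact** wall has
D ≥ 0.85 × stack depth; anything else is flagged indeterminate and
assigned to the nearer class.

**Starch fraction.** Starch pixels over envelope pixels, on five slices
evenly spaced across a 6 µm depth span (sample SD across slices reported).
The band starts below the envelope top: with `discard_first = "auto"` (the
pipeline default) the leading envelope slices whose segmented starch area
sits below 60 % of the median over the usable depth are treated as the
granule border effect and skipped — the automated counterpart of starting
the selected stack "from different slices for each wall" — while an
integer fixes the discard explicitly. The band is capped by the SHG
analyzable depth. `sweep_envelope_threshold()` repeats the computation at
threshold × (1 ± 0.4) by default and reports the spread of the three mean
fractions, propagating the envelope-threshold uncertainty into the result.

**Size distribution.** On the representative slice (the one carrying the
most granule labels within the analyzable depth; ties go to the shallower
slice — a deterministic stand-in for the expert's choice), each granule's
Max-Feret diameter is measured on its slice mask (exact: convex hull or
all-pairs; singletons return 0 µm with a sub-resolution flag), classified
as A/B/C with the B interval closed (`5 ≤ d ≤ 15`), and converted to a
spherical-equivalent volume πd³/6. Number and volume percentages are
reported per class and per near-logarithmic diameter bin; 2D analysis is
deliberate — the z-elongation artifact rules out axial volumetrics, so all
granule quantities are in-plane.

## What the synthetic benchmark does and does not show

Passing the recovery suite demonstrates that the chain of operations is
internally correct: fractions fed into the generator come back within
±0.07 in ≥ 90 % of seeded scenes (the tolerance mirrors the across-slice
variability real walls show, up to ±13.6 %), wall classes are recovered,
trimodal populations keep their modes and the number/volume crossover. It
does not certify performance on real acquisitions: the simulator renders
clean two-lobe responses, a box-shaped wall, exactly-zero gas, and a
single wall per field of view; real data add refractive-index artifacts
beyond the modelled elongation, saturated or clipped detectors, touching
walls, and an extragranular aqueous phase whose autofluorescence is not
separated from gluten here (an open problem for the field). The default
scene sizes used in the tests and the acceptance script (160–256 px
canvases, 40 slices) were chosen as the smallest fields that hold a full
wall at the native 0.17 µm sampling.

## Numerical choices and degenerate inputs

* Axis order is `[y, x, z]` (TIFF pages are z within channel); slice `k`
  covers the half-open depth interval `[(k−1)·z_step, k·z_step)`.
* Intensities are kept on the 16-bit grid `0..65535`; simulated stacks are
  quantized jointly across channels at 90 % of full scale, which makes
  write → read round trips voxel-exact and seeded runs byte-identical.
* Empty inputs are flagged, not errors, where the quantity is genuinely
  absent (empty analyzable depth, nothing above an envelope threshold,
  no granules on a slice); contradictions (metadata vs page count,
  negative geometry, percentages not summing to 100) are errors with
  typed conditions.
* Watershed markers, linking and relabelling are deterministic; ties in
  label interpolation go to the lower id, and a label present on only one
  bounding key slice is copied through the gap and flagged.
* The acceptance tolerance of the generator (±0.02 on the achieved
  fraction) and of the recovery suite (±0.07, ≥ 90 % of runs) are fixed
  study conditions, not knobs.

## Known limitations

* One wall per field of view (the largest EF component); multi-wall scenes
  are out of scope.
* No gluten/extragranular-phase unmixing; the envelope is everything the
  EF threshold keeps.
* Granule volumetrics are 2D-based (spherical assumption from the
  Max-Feret diameter); axial measurements are intentionally avoided.
* The simulator is phenomenological: no nonlinear-optics propagation, no
  refractive-index heterogeneity, no THG channel (interface imaging is a
  separate problem and is not quantified here).
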