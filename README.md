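# gcwmorph

Label-free multiphoton microscopy can image the two structural phases of a
bread-dough gas cell wall (GCW) without staining: second-harmonic generation
(SHG) is produced only by the radially ordered crystalline amylopectin of
starch granules, while the gluten network is seen through its endogenous
two-photon fluorescence (EF). Because a single linear polarization excites
only a two-lobe segment of each granule's SHG, a complete granule outline
requires fusing backward and forward detection across four polarization
angles. `gcwmorph` implements that quantification chain for R users working
on dough and crumb structure:

* **Reconstruction** — voxelwise summed (or maximum) fusion of the eight
  polarized SHG channels into one complete-outline starch image, and
  delimitation of the analyzable depth from the decay of per-slice contrast.
* **Segmentation** — automated granule segmentation (threshold, hilum hole
  filling, watershed splitting of touching granules, 3D linking across
  slices), slice-interpolation of sparsely traced labels, and EF-threshold
  delimitation of the wall envelope.
* **Morphometrics** — per-granule Max-Feret diameters `d` on a
  representative slice, wheat-starch typing (A > 15 µm, B 5–15 µm,
  C < 5 µm), spherical-equivalent volumes `V = πd³/6`, number- and
  volume-weighted size distributions, areal starch fraction
  (starch px / envelope px averaged over five slices spanning 6 µm),
  wall dimensions L × W × D, and string vs intact wall classification.
* **Synthetic scenes** — a ground-truthed simulator of nine-channel
  polarized SHG + EF stacks (trimodal granule population, two-lobe
  polarization response with dark hilum, fibrillar gluten texture,
  faster SHG than EF attenuation, axial elongation artifact, shot noise),
  so every stage is testable against known truth.

Inputs and outputs are plain formats: 16-bit multi-page TIFF stacks with a
small YAML sidecar, CSV granule tables, JSON summaries.

## Worked example

```r
library(gcwmorph)

params <- simulation_params(target_starch_fraction = 0.55, seed = 7)
sim <- simulate_stack(params,
                      wall_geometry("string", length_um = 20,
                                    width_um = 11, depth_um = 10),
                      canvas_px = c(160, 160), n_slices = 40)
sim$achieved_fraction       # ground truth recorded by the generator
#> [1] 0.562544

q <- quantify_stack(sim$stack, sweep = 0.4)
q
#> <gcw_quantification>
#>   SHG analyzable depth: 9.5 um (slices 8..26); EF: 11.0 um
#>   12 granule label(s); starch fraction 52.1% +/- 6.5%
#>   wall L x W x D = 24.0 x 15.8 x 11.0 um -> string
glance(q)$sweep_spread      # starch-fraction spread under a +/-40% threshold change
#> [1] 0.005721772
tidy(q)[, c("max_feret_um", "size_class")]
#> # A tibble: 9 x 2   (one row per granule on the representative slice)
#>   max_feret_um size_class
#> 1         5.55 B
#> 2         3.01 C
#> # ... 7 more rows (B- and C-type granules)
```

The printed summary gives the depth usable for starch segmentation (SHG dies
faster than EF), the areal starch fraction with its across-slice SD — here
52.1 ± 6.5 % against a simulated ground truth of 56.3 % — the wall
dimensions, and the string/intact call. `autoplot(q)` overlays envelope and
granule outlines on the fused SHG slice; `autoplot(q$sizes)` draws the
number/volume size distribution.

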