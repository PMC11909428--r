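---
title: "Cross-device validation of OCT retinal layer segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-device validation of OCT retinal layer segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retilab)
```

## The problem

Automatic segmentation of retinal layers in spectral-domain OCT (SD-OCT)
volumes underpins drusen quantification in age-related macular degeneration
(AMD): the volume of the RPE-drusen complex (RPEDC, the region between the
retinal pigment epithelium and Bruch's membrane) is a standard biomarker of
drusen load, and the neurosensory retina (NSR, ILM to RPE) volume is a
companion measure. Deep segmentation networks are usually trained on one
device's images, yet clinics mix devices whose exports differ in voxel grid,
field of view, intensity transfer and noise. The question a cross-device
validation answers is: does a network trained on device A still produce
clinically usable layer positions, region masks and volumes on device B,
without any device-specific tuning?

Real studies answer this with thousands of expert-annotated B-scans that are
not publicly shareable. `retilab` instead packages the *validation pipeline
itself* — phantom generation with exact ground truth, compact trainable
segmentation networks, the percentile boundary-extraction rules, and the full
metric battery — so the experiment can be exercised end-to-end, at desk
scale, with every number traceable to a seed.

## Synthetic phantoms

A phantom is a parametric macular anatomy sampled onto a device grid:

* **Bruch's membrane (BM)** is a near-planar, slightly tilted surface.
* **RPE** runs one band thickness (`rpe_band_px`, default 3 px) above BM,
  elevated locally by a drusen field: each druse is a radially symmetric
  Gaussian cap with seeded random centre, apex height and radius. Drusen are
  the severity driver; geographic atrophy and neovascular morphologies are
  deliberately out of scope.
* **ILM** drapes over the RPE at the NSR thickness (default 18 px), carved
  by a Gaussian foveal pit (default depth 8 px, radius 16 columns) and a
  gentle seeded waviness (0.3 px). Because the ILM follows the elevated RPE,
  the ordering `ILM <= RPE <= BM` holds everywhere by construction.

An AMD severity score of 0-11 maps monotonically to the drusen field
(`params_for_severity()`): scores 0-1 carry no drusen; from score 2 the
count (`2*(score-1)`) and apex height range (`0.8 + 0.45*score` px,
±40%) grow linearly. Severity groups follow the standard reporting
convention: Group 1 = scores 0-1, Group 2 = 2-5, Group 3 = 6-8 (medium to
large drusen), and 9-11 are reported separately as "advanced". Expected
ground-truth RPEDC volume is therefore nondecreasing across groups, which the
tests check by simulation.

Ground-truth label channels are rasterized with a voxel-centre test: the ILM
and RPE bands take all voxels within `band_halfwidth_px` (default 1.5, i.e.
~3-voxel bands — multi-pixel targets without merging the bands in thin
regions) of the surface; the RPEDC channel fills all voxel centres between
RPE and BM inclusive. The three channels overlap (the RPE band lies inside
the RPEDC region), which is why the networks use independent per-channel
binary outputs rather than mutually exclusive classes.

## Device profiles

Two presets emulate the qualitative appearance gap between a frame-averaged,
high-contrast scanner and an unaveraged one:

| field | spectralis_like | cirrus_like |
|---|---|---|
| grid (full) | 496 x 768 x 121 @ 3.87 x 11.7 x 58.7 um | 512 x 512 x 128 @ 3.91 x 11.7 x 47.2 um |
| field of view | 1.9 x 9 x 7 mm | 2 x 6 x 6 mm |
| reflectivity (vitreous/NSR/RPE/RPEDC/choroid) | 10/110/225/170/60 | 30/115/185/150/85 |
| speckle contrast | 0.50 | 0.55 |
| frame averages | 12 | 1 |
| transfer gamma | 1.0 | 0.8 |

Rendering assigns each voxel its compartment reflectivity, multiplies by
gamma-distributed multiplicative speckle whose variance is divided by the
frame-averaging count (the average of `n` unit-mean Gamma draws is drawn
directly from the equivalent Gamma distribution), applies the monotone gamma
transfer, and quantizes to 0-255. The parameters were fixed once to
reproduce the qualitative divergence reported between real devices — the
averaged profile shows more extreme low/high intensities, the single-frame
profile more mid-range intensities and visibly heavier noise — without any
claim of physical fidelity. On a shared grid the two renderings of one
anatomy correlate voxelwise at roughly r = 0.7-0.8 in the default
configuration; real device pairs are reported far lower (r ~ 0.3), so the
phantom's domain gap is conservative in that respect, though its noise gap
is substantial.

The default working grids are quarter-scale versions of the printed device
grids (e.g. 124 x 192 x 30 voxels), with spacings inflated fourfold so the
physical field of view is preserved. This is the package's own choice of
problem size for routine runs; the full printed grids remain available via
`device_preset(..., scale = 1)`.

## Geometry

All physical bookkeeping uses a voxel-centre convention: voxel `i` along an
axis with spacing `s` spans `[(i-1)s, i*s)` with centre `(i-0.5)s`, and
indices are R-native 1-based. Fields of view are aligned by their physical
centres (phantom pairs are constructed co-centred; registration of real
data is out of scope). Volumes resample by trilinear interpolation at target
voxel centres with nearest-edge padding; resampling onto the source grid is
exactly the identity. Surfaces resample by bilinear interpolation of
physical depth over the lateral plane, with weights of undefined neighbours
dropped and renormalized. Label masks are never interpolated — they are
re-rasterized from resampled surfaces — so no fractional label voxels ever
arise.

Which device is resampled onto which is configurable; the experiment
default resamples second-device test volumes onto the training profile's
grid, and restricts *all* evaluation (distance errors, Dice, volumes) to the
common field of view of the two devices, so same-device and cross-device
arms measure the same physical region.

## Segmentation networks

No deep-learning framework ships with this package's environment, so
`retilab` includes a compact CNN engine (Rcpp/Armadillo: im2col
convolutions, max-pooling/nearest upsampling, sigmoid + binary
cross-entropy or soft-Dice loss, Adam). Two architectures are provided:

* `encoder_decoder` — a contracting/expansive path with skip connections,
  four resolution levels (widths 8/16/32/64 by default, ~100k weights).
* `dilated` — constant-resolution multi-scale context: a two-conv stem
  followed by parallel dilated branches at rates 1/2/4/8, fused and
  projected (~10k weights).

Both map one grayscale B-scan (divided by 255; no per-volume
standardization, mirroring the no-device-tuning premise) to three per-pixel
score channels thresholded independently at 0.5 with a strict-greater rule.

Two training-side design choices matter and are worth stating explicitly:

* **Fixed-gain parameterization.** Stored parameters are scaled by a
  constant per-layer gain (128) at use; Adam's per-step motion on the stored
  parameters (~the learning rate) therefore translates into effective weight
  updates of `lr * 128`. This keeps the conventional small learning rates of
  large-scale training (1e-5) effective for a compact network trained for
  only a few hundred steps, in the spirit of maximal-update
  parameterizations, without touching the training configuration contract.
* **Seeded intensity augmentation** (on by default): per B-scan
  multiplicative speckle of random contrast (0-0.7), Gaussian blur of random
  width (emulating interpolation smoothing), gamma jitter (0.65-1.4),
  brightness/scale jitter, and left-right flips (applied to image and labels
  together). Without it the compact networks key on absolute intensity
  values and fail on the second device; with it they learn the structural
  cues (dark-to-bright ILM edge, bright band over darker choroid) that
  transfer. Disable with `train_config(augment = FALSE)`.

Training is fully seeded (initialization, shuffling, augmentation) from one
integer, uses its own random stream, and is bit-reproducible run to run on
one machine in single-threaded mode.

## Boundary extraction

Network outputs are multi-pixel bands; surfaces are recovered per A-scan by
pooling the labelled voxel rows of each column and taking a percentile with
linear interpolation between closest ranks (R's type-7 convention), keeping
sub-pixel values to avoid a 0.5 px quantization bias in MAE. The standard
extraction takes the ILM and RPE at the 50th percentile of their band
channels and BM at the 95th percentile of the RPEDC channel — near the lower
RPEDC edge just above the choroid, robust to stray last-voxel noise. For a
solid RPEDC column the p95 rule sits at most `0.05 * thickness + 1` px above
the true BM, a property the tests assert on every column. Columns whose
label set is split by gaps are pooled (no connected-component filtering);
empty columns are undefined and flow into the metrics' exclusion rule. The
p95 BM is used for visualization and thickness maps; quantitative RPEDC
volume and Dice default to counting the region channel directly (a
surface-based alternative is available via `rpedc_mode = "surface"`).

## Metrics

* **MAE / MSE with exclusion**: over columns where both prediction and
  ground truth are defined; interrupted or missing columns are excluded and
  counted. Aggregation is over all mutually defined columns of a volume, and
  group tables then average per-volume values ± sample SD. `mae <= sqrt(mse)`
  is asserted at construction. (Published tables of this kind occasionally
  violate that inequality, which would imply a different error pooling;
  `retilab` implements the standard definitions.)
* **Intergrader RMSE**: same exclusion rule; the second annotator is
  simulated by adding a smooth laterally correlated field per layer (defaults
  ILM 0.3, RPE 1.3, BM 1.0 px, constant across severity), then re-clamping
  the ordering. The defaults encode the robust finding that RPE annotation
  varies far more than ILM.
* **3D Dice** on the RPEDC region over the whole volume — never per B-scan,
  which would be dominated by B-scans with tiny RPEDC areas. Two empty masks
  define Dice 1 (with a warning).
* **Volumes** in mm^3: voxel count x voxel volume for masks; column-wise
  `max(lower - upper, 0) x voxel volume` for surface pairs (undefined columns
  contribute zero).
* **Bland–Altman**: sample SD (n-1), limits of agreement mean ± 1.96 SD.
* **Paired t test**: classical statistic, two-sided p from the t
  distribution; zero-variance differences raise an error instead of a
  spurious p = 0.
* **Intensity correlation**: voxelwise Pearson r between co-gridded volumes
  plus 256-bin occurrence-probability histograms.

## The default experiment

`run_experiment()` trains each architecture on the first device profile only
(default: 5 quarter-scale training volumes = 150 B-scans, 5 epochs,
learning rate 1e-5, Adam, batch size 1), then evaluates the four settings —
each architecture on held-out same-device volumes and on second-device
volumes resampled onto the training grid — over a stratified test cohort
(default 6 cases, two per severity group). It emits per-case tables, the
group summaries (layer errors, Dice, intergrader RMSE, volumetric errors),
Bland–Altman analyses, en face RPEDC thickness maps (0-50 um, deep blue to
deep red, undefined gray, lateral aspect honouring dx:dy), an event log and
a provenance manifest (config hash, per-case seeds, versions). These problem
sizes are the package's defaults for a run that completes in a few minutes
on one CPU; all of them are configurable upward.

Numerical/degenerate-input conventions used by the runner: a model that
predicts no usable columns for a layer produces an `NA` metric row rather
than aborting; cross-vs-same t tests with fewer than two usable pairs or
zero-variance differences yield `NA`; severity mixes must sum to 1; any
stage failure aborts with the stage name, retaining partial outputs.

## What passing tests do and do not show

The phantom reproduces the *structure* of the validation problem — two
grids, two intensity regimes, drusen-driven severity, annotator noise,
multi-pixel labels — but not retinal texture, vascular shadowing, motion
artifacts, or pathology beyond smooth drusen. Networks that generalize
across the two synthetic profiles are not thereby shown to generalize across
real Spectralis and Cirrus exports; conversely, the *pipeline* (extraction
rules, exclusion-rule metrics, volume and agreement analyses, grid
bookkeeping) is exercised exactly as it would be on real data, and its
correctness properties (percentile conventions, volume closed forms,
resampling invariance within 2%, LOA identities) are independent of image
realism. Cross-device degradations measured on phantoms at desk scale — a
few tenths of a pixel here — are smaller than the 1.5-2 px reported on real
cohorts; the phantom's compartments are cleaner than tissue.

## Known limitations

* Drusen-only pathology; no atrophy, fluid or neovascular morphology.
* Annotator simulation has constant sigma across severity, so the simulated
  intergrader table does not reproduce the severity trend real annotators
  show.
* Centre-aligned registration only; no lateral registration search.
* The CNN engine is single-threaded and CPU-bound by design; full printed
  grids train slowly and are intended for targeted runs, not routine tests.
* Dice/volume defaults count the region channel; surface-based RPEDC is
  available but sensitive to p95-BM bias on thin columns.
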