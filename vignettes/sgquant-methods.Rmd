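---
title: "Methods: quantifying secretory-granule docking and exocytosis in dividing cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying secretory-granule docking and exocytosis in dividing cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgquant)
```

## The biological question and the measurements

Neuroendocrine cells such as PC12 store hormones in dense-core secretory
granules (SGs) that dock in the F-actin-rich cortex under the plasma
membrane and release their content by regulated exocytosis. During cell
division both the docked pool and the cell's responsiveness to secretagogue
stimulation change. `sgquant` implements the three quantitative readouts
used to characterize this:

1. **Cortical localization** (EM scale). For a single cell with a digitized
   membrane outline and granule centroids, the fraction of granules whose
   minimal distance to the membrane is at most 500 nm — the operational
   definition of "morphologically docked". Interphase and metaphase
   populations of per-cell percentages are compared with a classical
   pooled-variance two-sample *t*-test.

2. **Surface-exposure densitometry** (widefield fluorescence). After
   stimulation, surface-exposed secretogranin II (SgII) is immunostained
   without permeabilization; a cell that underwent exocytosis shows
   punctate SgII on its surface. Cells are segmented from a uniform WGA
   membrane stain; the detected cell borders on the *outside* of cell
   clusters are extended by 3 pixels to each side; total SgII intensity in
   this ribbon divided by its pixel area gives a per-cell mean; the mean
   over unstimulated control cells is subtracted; cells with a strictly
   positive corrected mean are *responders*. Per stage class the pipeline
   reports the responder percentage and the metaphase-to-interphase ratio
   of mean corrected intensities.

3. **Track kinetics** (time-lapse). SG puncta are detected per frame
   (Laplacian-of-Gaussian with subpixel centroid refinement), linked by
   greedy mutual-nearest-neighbor association, and summarized per track:
   path length, net displacement, straightness, mean velocity (path length
   over duration, in μm/s), and the fraction of detections within a fixed
   radius of a microtubule skeleton.

No raw images accompany the study, so the package ships seeded generators
that produce synthetic scenes with exact ground truth; every pipeline stage
is validated by recovering generator parameters.

## Segmentation model

The membrane stain forms a bright, roughly closed ridge around every cell.
`segment_cells()` enhances ridges with a morphological white top-hat (disc
diameter 9 px by default, chosen just above the default 3 px ring width),
thresholds them (Otsu by default), fills the enclosed regions, and floods
the filled foreground from markers with `EBImage::propagate` — a
marker-controlled, watershed-style Voronoi region growing on the smoothed
membrane image. Markers are the user-supplied per-cell seed points when
given (the semi-automatic mode; annotations carry one reference point per
chosen cell) or, in automatic mode, the connected interior basins enclosed
by the ridge. Regions under `min_area` (500 px² by default) are merged
into background. Undetected borders are tolerated: a cell whose ring has a
gap merges with its neighbor or the background and the event is recorded
as a warning, never an error, mirroring the supervised workflow the
protocol describes.

Border pixels use the inner-boundary convention (a pixel of the label with
at least one 8-neighbor of a different value), so boundary pixels remain
part of the area they contribute to. A boundary pixel adjacent to another
nonzero label is *cluster-internal* and excluded from quantification; one
adjacent only to background is *cluster-outer* and usable.

## Surface densitometry choices

* **"Extended by 3 pixels to each side"** is read as a symmetric Chebyshev
  (8-connected) dilation of the 1-px outer border, producing a 7-px-wide
  ribbon. This is the only reading in which "each side" has a geometric
  meaning for a curve, and it matches a brute-force distance computation in
  the tests.
* **Background** is the unweighted mean over control cells of their
  per-cell mean ribbon intensity — a per-cell average, not an area-weighted
  pool.
* **The responder boundary.** The protocol assigns corrected value 0 to
  both the responder and the non-responder class. For continuous
  intensities the event has measure zero; `sgquant` resolves the boundary
  conservatively as responder ⇔ corrected mean > 0.
* Cells whose ribbon would be truncated by the image edge, and cells with
  no outer border, are flagged unquantifiable and excluded, with the
  exclusions tallied in warnings.

## The synthetic generators: what they emulate, and what not

**Fluorescence scenes.** Cells are smoothed random-radius star polygons
(8–12 radial control points, periodic-spline interpolated), not circles,
so segmentation is non-trivial. The WGA channel renders a closed ring of
configurable width and intensity plus a dim interior; in the paired layout
two cells share a membrane segment, rendered once along the pixel-ownership
interface. Hoechst renders an interphase nucleus blob or a metaphase-plate
bar — used only to plumb stage annotations, never for automated staging.
SgII is a uniform background plus, on responder cells only, Poisson-like
puncta confined to a band of ±3 px around the true outline, with the
per-cell added band mean equal to `responder_surface_mean` times the
class factor (default 0.61 for metaphase). Read noise is additive
Gaussian on every channel.

The stimulated/control preset pair fixes the responder probabilities at
0.81 (interphase) and 0.67 (metaphase) and sets `noise_sd = 0`. The
noiseless default is deliberate: with the strict `> 0` responder rule, a
true non-responder's corrected mean is symmetric around zero under any
symmetric pixel noise, so each non-responder becomes a fair coin flip and
the responder percentage would be structurally biased upward by half the
non-responder rate regardless of the noise magnitude. The presets define
parameter-recovery validation conditions, and identifiability requires the
noiseless limit; `noise_sd` remains a first-class parameter and the
segmentation and densitometry stages are exercised with noise elsewhere in
the test suite. Consequences for interpretation: passing recovery tests
shows the pipeline's geometry and arithmetic are correct, not that the
responder rule is robust to detector noise — on real images the rule
inherits the protocol's sensitivity to background fluctuation.

**EM granule scenes.** One star-polygon outline per cell (default radius
5 μm) with granules placed by rejection sampling: each granule is
independently cortical with the preset probability (0.70 interphase, 0.13
metaphase), where cortical means within 500 nm of the outline under the
same polygon-distance definition the analysis uses, so ground truth and
recomputed classification agree exactly. Fixture presets draw per-cell
counts from a multinomial conditioned on the published totals (227 and
376) so the packaged three-cell fixtures carry those totals exactly.

**Track sets.** Directed tracks move at a constant per-track speed drawn
from a Normal truncated at zero (presets 0.23 ± 0.09 μm/s for anaphase and
0.34 ± 0.09 μm/s for cytokinesis), along straight-to-gently-curved paths
or along one of a few straight filaments of a synthetic skeleton;
non-directed tracks are Gaussian random walks. Reported positions carry
isotropic Gaussian localization noise (default 20 nm).

The generators do **not** simulate photobleaching, focus drift, a 3-D PSF,
Poisson shot noise, cell motility, or EM texture; they emulate the
statistical structure the analyses assume, not microscope physics.
Recovery on these scenes therefore validates the analysis chain, not
robustness to every real-world artifact.

## Numerical and statistical choices

* Distances from granules to the membrane are point-to-segment minima over
  the polygon edge set; the shell is closed (distance exactly 500 nm is
  cortical). Scale invariance and agreement with a dense 10-nm-grid
  distance-transform oracle are tested properties.
* The pooled two-sample *t* is implemented in closed form because the
  summary-statistic entry path (group means/SDs/ns, the form in which the
  comparison is published) cannot be fed to `stats::t.test`; the raw-data
  path is verified against `stats::t.test(var.equal = TRUE)` to 1e-10.
  Zero pooled variance with equal means yields p = 1; with unequal means
  the p-value is reported at the machine floor with a flag. A Welch option
  exists but is not the default, since the named test is Student's.
  The published P = 0.0008 for the interphase/metaphase contrast is not
  reproducible from the published summary statistics alone (the per-cell
  fractions behind it are unpublished), so the package treats the test
  *procedure*, not that p-value, as the contract.
* "Directed movement" is operationalized as straightness (net displacement
  over path length) ≥ 0.8 sustained over ≥ 4 detections, the span the
  published tracks cover; the threshold is a parameter. Mean velocity is
  path length over duration; localization noise inflates path length by
  roughly `2σ²/(step·pixel)` per step (≈1.5 % at the defaults) and no
  noise correction is applied — a documented limitation absorbed by the
  validation tolerances (≤ 5 % at default noise).
* Watershed ties at region interfaces follow `EBImage::propagate`'s
  deterministic flooding; all generators draw from one explicit seed with
  global RNG state saved and restored, so identical parameters and seed
  give bit-identical outputs.
* The colocalization radius defaults to 2 px at 100 nm/px — 200 nm, the
  lower bound of the optical resolution the imaging system is stated to
  achieve (200–250 nm). The default fluorescence calibration of 100 nm/px
  samples that resolution near Nyquist; the camera's true pixel size is
  not published, so this default is declared, not inferred.

## Validation problem sizes

The shipped validation uses 20 EM cells per class (≈75 and ≈125 granules
per cell), a 200-cell stimulated fluorescence scene (100 per stage class)
with a 50-cell control arm, and 50-track time-lapse sets of 20 frames on a
512² field — sizes at which binomial/sampling error bands around the preset
parameters are a few percentage points, comparable to the published
standard deviations, while a full run stays in the tens of seconds.

## Known limitations

* Segmentation quality is only as good as ridge closure; ring gaps larger
  than the top-hat scale merge cells, and the package reports rather than
  repairs them.
* The surface ribbon is defined in pixels, so its physical width scales
  with calibration; analyses mixing calibrations must normalize first.
* Linking has no gap closing and no motion model; crossing tracks can
  fragment. Fragments ≥ 4 detections still contribute unbiased velocities.
* The relative-intensity statistic conditions on responders only; with few
  metaphase responders its sampling error grows quickly.
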