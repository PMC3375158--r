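# sgquant

Quantitative image analysis of secretory-granule (SG) docking and regulated
exocytosis in dividing neuroendocrine (PC12) cells.

During mitosis, PC12 cells release their cortically docked SG pool and
dampen — but do not lose — their ability to respond to secretagogue
stimulation. `sgquant` implements the three measurements used to quantify
this, as a tested, reusable R pipeline, together with seeded
synthetic-microscopy generators (with exact ground truth) that stand in for
the study's undeposited raw images. It is written for cell biologists and
image analysts who want the quantification protocol itself — segmentation
through population statistics — as auditable, reproducible code.

## The measurements

**Cortical-shell localization (EM scale).** For a cell with membrane
outline $\partial\Omega$ and granule centroids $g_i$ (nm), a granule is
*docked* when $d(g_i, \partial\Omega) \le 500$ nm; the per-cell statistic is
the docked fraction, and groups of cells (interphase vs metaphase) are
compared on per-cell percentages with the classical pooled two-sample
*t*-test,

$$t = \frac{\bar x_1 - \bar x_2}{s_p\sqrt{1/n_1 + 1/n_2}},\qquad
s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}.$$

**Surface-SgII densitometry (widefield fluorescence).** Cells are segmented
from the uniform WGA membrane stain (ridge enhancement + marker-controlled
watershed-style flooding); borders inside cell clusters are discarded; the
remaining outer borders are extended by 3 px to each side; the mean SgII
intensity per mask pixel is computed per cell; the mean over unstimulated
control cells is subtracted; cells with corrected mean $> 0$ are
*responders*. Reported per stage class: responder percentage and the
metaphase/interphase ratio of mean corrected intensities.

**Track kinetics (time-lapse).** Laplacian-of-Gaussian punctum detection
with subpixel centroids, greedy mutual-nearest-neighbor linking, per-track
path length, straightness (net/path), mean velocity (path/duration, μm/s),
directed-motion classification (straightness ≥ 0.8 over ≥ 4 frames), and
the fraction of detections within 200 nm of a microtubule skeleton (via a
distance transform).

## Worked example

```r
library(sgquant)

## EM-scale docking: 3 interphase and 3 metaphase cells at the published
## cortical placement probabilities (0.70 / 0.13)
res_i <- cortical_fractions(
  generate_em_scene(sg_preset("em_interphase", n_cells = 3, seed = 1)))
res_m <- cortical_fractions(
  generate_em_scene(sg_preset("em_metaphase", n_cells = 3, seed = 2)))
res_i
#>   cell_id stage_class n_total n_cortical  fraction
#> 1       1  interphase      75         52 0.6933333
#> 2       2  interphase      75         56 0.7466667
#> 3       3  interphase      75         44 0.5866667
compare_groups(res_i, res_m)
#> Two-sample pooled t-test on per-cell cortical percentages
#>   group A: mean 67.56 sd 8.15 n 3
#>   group B: mean 11.73 sd 0.46 n 3
#>   t = 11.8491, df = 4, p = 0.00029
```

Each row is one cell: `n_cortical` of `n_total` granules lie within the
500-nm shell, and the group contrast (interphase mean 67.6 % vs metaphase
11.7 %) is significant at n = 3 + 3 cells.

```r
## Surface-exocytosis pipeline on a synthetic stimulated scene
## (20 interphase + 20 metaphase cells) with a matched unstimulated control
stim <- generate_fluorescence_scene(sg_preset("fluor_stimulated",
  n_cells = 40, stage_classes = rep(c("interphase", "metaphase"), each = 20),
  seed = 7))
ctrl <- generate_fluorescence_scene(sg_preset("fluor_control",
  n_cells = 20, seed = 8))
quantify_surface(stim$scene, ctrl$scene)$summary
#> population summary (surface SgII densitometry)
#>  stage_class n_cells responder_fraction mean_corrected_responders
#>   interphase      20                 90                  18.06869
#>    metaphase      20                 55                  10.85857
#> relative intensity (metaphase/interphase responders): 60.1%
```

The pipeline segments all 40 stimulated cells from the WGA channel (seeded
at the annotation points), measures the 7-px surface ribbons on the SgII
channel, subtracts the control background, and recovers the generator's
responder probabilities (0.81 / 0.67, here 90 % and 55 % at n = 20 per
class) and its metaphase intensity factor of 0.61 (measured 60.1 %).

Larger runs, granule/track CSV and TIFF I/O, and a YAML-configured
end-to-end driver are available through `run_pipeline()` and the thin CLI
at `inst/cli/sgquant.R` (`simulate` and `run` subcommands).

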