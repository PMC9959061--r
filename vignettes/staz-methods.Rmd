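---
title: "Methods: steatosis scoring and GP membrane-order mapping in stazr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steatosis scoring and GP membrane-order mapping in stazr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stazr)
```

## The measurement model

The assay images each larva's liver in two fluorescence channels over up
to three optical slices. The green channel reports neutral-lipid staining;
the blue channel is a normalization signal that is insensitive to lipids —
either weak hepatic autofluorescence (wild-type larvae) or a strong
liver-restricted blue fluorophore (transgenic larvae). All quantification
is restricted to a user-supplied liver region of interest (ROI), because
the surrounding yolk and gut carry strong unrelated lipid signal.

Three parameters are extracted per slice:

* **Raw ratio** `F_green / F_blue`: total green over total blue intensity
  within the ROI. Because both sums run over the same mask, this equals
  the ratio of mean intensities; we compute sums and document that
  explicitly to remove any ambiguity between the two conventions.
* **LD_dens**: number of detected lipid droplets divided by ROI area, in
  droplets per liver *pixel*.
* **LD_area**: fraction of ROI pixels covered by detected droplets
  (dimensionless, in [0, 1]).

The raw ratio is anchored to the vehicle controls of the same batch,
`Ratio_x = (raw_x − m) / m` with `m` the mean raw ratio of the batch's
DMSO larvae, so 0 means "at control level" and negative values (below
control) are legitimate and never clamped. The composite slice score is
the published linear combination

```
score = 400 · Ratio_x + 10000 · LD_dens + 100 · LD_area
```

whose coefficients were set by the assay's authors to give the three
parameters homogeneous weight; they are exposed as
`score_coefficients()` but there is no reason to re-derive them. A
larva's score is the arithmetic mean over its slice scores; fewer than
three slices is accepted with a warning.

Two consequences worth keeping in mind:

* Scores are **relative to the batch's control group** — within every
  batch the control corrected ratios average exactly zero by
  construction, so only treated-vs-control contrasts are meaningful.
* `LD_dens` is per pixel, so the score is only comparable across
  acquisitions at one magnification and one segmentation configuration.
  When a physical pixel size is supplied, densities per µm² are available
  as a separate output, but the score always uses pixels so that the
  published coefficients keep their meaning.

### Control-mean scope

The source protocol normalizes to "the group of larvae exposed to DMSO"
without stating whether that group is per experiment or global; its ΔGP
procedure, however, is explicitly per experiment (one batch, one
staining). For consistency the score correction defaults to per-batch
anchoring (`scope = "per_batch"`), with `"global"` available when a run
has no batch structure. The control mean is the mean of the control
larvae's per-larva mean raw ratios, so every control larva contributes
equally regardless of its slice count.

### Slice masks

Whether the original hand-drawn liver outline was reused across a
larva's three optical slices is not specified by the protocol. Both are
supported: each slice carries its own mask, and sharing one mask across
slices is simply the degenerate case of supplying the same file three
times. Correction and droplet quantification always use the slice's own
mask.

## Droplet segmentation

The original analysis used unavailable Fiji macros, so the recipe here is
a transparent, fully parameterized stand-in (`segmentation_config()`):

1. **Median smoothing**, radius 1 px by default — removes single-pixel
   shot noise without eroding droplet cores. Radius 1 uses a vectorised
   median-of-9 selection network; larger radii delegate to EBImage.
2. **Threshold**: Otsu's method computed on the in-ROI intensity
   histogram only (256 bins over the observed range), or a fixed value.
3. **Background guard** (`min_contrast_sd`, default 3): the Otsu
   threshold is floored at `median + 3 · MAD` of the in-ROI intensities.
   Otsu's criterion always splits a histogram — on a droplet-free slice
   the split lands inside the noise and would label roughly half the ROI
   as foreground. The guard keeps pixels within ~3 robust standard
   deviations of the background out of the foreground; on slices with
   real droplets the Otsu threshold lies far above it and the guard is
   inert. Constant in-ROI intensity has no threshold at all and returns
   zero droplets with a warning.
4. **8-connected components** clipped to the ROI; components smaller
   than `min_area_px` (default 4 px) are discarded, since blobs below
   ~4 px are at the resolution limit of this acquisition class and their
   sizes are unreliable.
5. Optional **watershed split** of touching blobs on the distance
   transform (`split_touching`), off by default because the simulator's
   acceptance ground truth uses non-overlapping droplets.

Because the smoothing is an order statistic, the threshold is computed
from the data's own range, and the guard uses median/MAD, the entire
segmentation is equivariant under positive intensity scaling: rescaling
the image rescales the threshold and leaves the segmented pixel set
unchanged (bit-exact for power-of-two factors; up to one unit in the last
place otherwise).

Scores produced under different segmentation configurations are not
comparable; the configuration is therefore a single explicit object that
is serialized into run configs.

## GP membrane-order mapping

Membrane order is mapped per pixel from an ordered-phase and a
disordered-phase emission image as
`GP = (I_ord − I_dis) / (I_ord + I_dis)`, which lies in [−1, 1] with
higher values indicating more ordered (rigid) membranes. Pixels are
flagged undefined where the total intensity falls below an intensity
floor or outside the liver ROI; the default floor is 2% of the 99th
percentile of the in-ROI total intensity, a background guard standing in
for the unpublished dim-pixel cutoff of the original macro, and is fully
configurable (0 disables it).

A larva's GP is the unweighted mean over defined pixels — the simplest
faithful reading of a per-larva GP value. Whether the original analysis
weighted pixels by intensity or restricted them to membrane-like
structures is not stated; we deliberately do not guess, and note that an
intensity-weighted variant would change absolute GP values but not the
control-anchored differences much. To absorb batch and staining
variation, results are reported as `ΔGP = mean_gp − mean(control
mean_gp)` within the same batch, so control ΔGP averages zero per batch
by construction.

## Group statistics

Groups are summarised as mean ± SEM (sample SD / √n larvae) with larva
and batch counts; the larva is the statistical unit, batches are
reported but not modelled as random effects. Three tests are provided,
matching the assay's reporting conventions:

* `kruskal_dunn()`: tie-corrected Kruskal–Wallis H, then Dunn's z on the
  pooled ranks for each treated-vs-control comparison, Bonferroni-adjusted
  over the comparisons made (all-pairs mode available). The Dunn z is
  implemented directly (pooled-rank difference over its tie-corrected
  standard error) and verified against hand rank computations.
* `anova_dunnett()`: one-way ANOVA F, then Dunnett's many-to-one
  comparisons with single-step multivariate-t adjusted p-values (via
  multcomp).
* `two_way_anova_bonferroni()`: two-factor ANOVA with interaction;
  requested cell contrasts are pooled-variance t-tests on the residual
  mean square, Bonferroni-adjusted. A stepwise Newman–Keuls post-test
  appears once in the source material's legends; it is intentionally
  replaced by Bonferroni contrasts, which carry coherent familywise error
  control.

Adjusted p-values are never below raw ones, and stars follow the
0.05/0.01/0.001 convention. Which test to run is always an explicit
argument — the source material alternates between them per figure without
stating a rule, so nothing is auto-selected.

Degenerate inputs take defined paths: an all-identical sample collapses
to statistic 0 with p = 1; groups with between-group signal but zero
within-group variance raise a degenerate-variance error (no valid error
term exists); empty design cells are reported by name.

### Calibration

Under null simulations the familywise error of the vs-control procedures
sits at the nominal 5% where the adjustment is exact: Dunnett's
multivariate-t by construction, and Dunn's z in the single-comparison
family (measured level 0.050 at n = 15/group). With several correlated
vs-control comparisons the Bonferroni step is conservative by
construction (measured familywise error ≈ 0.040–0.045 for 2–4
comparisons) — a property of the published procedure itself, inherited
deliberately. The test suite calibrates each procedure in a design where
its nominal level is exact and checks the conservative direction
separately.

## The synthetic-image generator

`simulate_larva()` renders what the pipeline needs to see, not larval
anatomy: an elliptical liver emitting the blue normalization signal
(45/35 counts liver/background in wild-type mode, 130/8 in transgenic
mode), a diffuse green background (20 counts), and bright green droplets
(160 counts above background) placed uniformly inside the liver as
non-overlapping disks, then Gaussian PSF blur (σ 0.8 px), Poisson shot
noise and Gaussian read noise (σ 4 counts). Droplet counts per slice are
Poisson with mean `droplet_rate × liver area`.

Defaults — 96×96 px images, liver semi-axes 30×20 px (~1900-px liver,
emulating a downsampled confocal field at fixed zoom), droplet rate
1.5×10⁻³ per pixel (~3 droplets/slice in controls, as sparse as healthy
vehicle larvae), radii 2.2 ± 0.3 px — were fixed once from two
considerations: the droplet signal-to-noise ratio lands near 11
(comfortably detectable but not trivial), and the liver's empirical
packing capacity (≥21 non-overlapping droplets at these radii and the
3-px separation margin) keeps the probability of an infeasible Poisson
draw negligible even at doubled treated rates. Packing is by rejection
sampling with at most 1000 retries per droplet, and genuinely infeasible
configurations raise a packing error rather than silently overlapping,
so the droplet-count ground truth is always unambiguous.

Each larva draws from its own sub-seed derived from the cohort seed, so
a larva's images do not depend on cohort composition; the same seed
reproduces images bit for bit. Batch effects are modelled only as a
shared multiplicative intensity factor per batch — exactly what per-batch
ratio anchoring should cancel, and nothing more.

GP test data are generated by inverting the GP formula: given a true GP
field `G` and total intensity `T`, `I_ord = T(1+G)/2` and
`I_dis = T(1−G)/2`, with optional multiplicative noise per channel. The
noiseless inversion is exact to machine precision, which pins the sign
and scaling conventions of the GP computation.

What the generator does **not** emulate: larval anatomy and the
yolk/gut autofluorescence that makes real ROI drawing necessary, optical
sectioning physics and z-correlation of droplets across slices,
intensity falloff within the liver, and droplet shape irregularity.
Passing tests therefore demonstrate that the pipeline recovers known
truth under the stated noise model — they do not validate the biological
sensitivity of the assay on real images, and score magnitudes on real
data depend on the segmentation configuration used.

## Problem sizes and runtimes

The simulation-backed checks use sizes chosen to exercise the claims at
useful statistical resolution: segmentation precision/recall over 100
seeded larvae (3 slices each); end-to-end effect recovery over 100
replicate cohorts of 20 + 20 larvae (two batches) with a doubled treated
droplet rate, checking both score direction and Dunn's flagging; null
calibration of each test over 2000 replicates against the 95% binomial
band around the nominal level; and rate-monotonicity of the mean score
across 1×/2×/4× droplet rates averaged over 100 seeds. The full suite
runs in a few minutes on one core.

## Known limitations

* Absolute scores are configuration-bound; only within-configuration,
  within-batch-normalized comparisons are meaningful.
* The segmentation stands in for unavailable original macros; droplet
  counts on real images will differ from the original pipeline's in
  absolute terms.
* Batches are normalization units, not random effects; strong batch-by-
  treatment interactions would require a mixed model outside this scope.
* GP aggregation is an unweighted pixel mean; no spectral unmixing or
  histogram decomposition is attempted.
* 3D droplet reconstruction across slices (and droplet tracking) is out
  of scope; slices are treated as independent samples of the same liver.
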