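---
title: "Methods: scoring and optimizing seed-spreading uniformity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and optimizing seed-spreading uniformity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedspread)
```

## The problem

Customs laboratories screen imported soybean lots for quarantine ragweed
seeds (*Ambrosia trifida*, *A. artemisiifolia*). An automated inspection
device spreads a seed sample in a single layer on a moving belt, images it
at 3840 × 2160, and counts each class. Ragweed seeds are much smaller than
soybeans (3.2 × 2.8 mm vs. 7.65 × 6.52 mm), so whenever the dispenser
clumps seeds the weeds end up occluded and undercounted. The engineering
question is therefore statistical: *how uniform is a spread, and which
dispenser settings make it most uniform?* This package implements that
analysis — a grid-binned Moran's I uniformity score, a Taguchi L18
factor-screening analysis around it, and counting verification metrics —
together with a scene simulator that stands in for the physical device.

## Uniformity score: grid-binned Moran's I

A frame's binary seed mask is divided into 48 equal tiles (6 rows × 8
columns; 480 × 360 px at full resolution) and each tile's seed-pixel
fraction $x_i$ becomes one observation. Moran's I on these 48 values,

$$I = \frac{N \sum_i \sum_j w_{ij}(x_i-\bar x)(x_j-\bar x)}
           {S_0 \sum_i (x_i-\bar x)^2},$$

measures whether high-coverage tiles neighbor other high-coverage tiles
($I > 0$, clumping), alternate with empty ones ($I < 0$, regular
dispersion), or show no spatial structure ($I \approx 0$, the uniform
spread the device aims for). Design choices where the method leaves room:

* **Weights.** Binary queen contiguity (8 neighbors; rook available) with
  no row standardization — the statistic already normalizes by
  $S_0 = \sum_{ij} w_{ij}$. Queen binary weights are the most common
  default for lattice data, and with a fixed weight matrix the score is
  comparable across frames.
* **Tile order.** Tiles are traversed row-major from the top-left; the
  weight builder uses the same indexing, and a transposed mask yields a
  transposed grid (tested).
* **Degenerate input.** If every tile has the same fraction the statistic
  is 0/0. We raise an explicit error instead of returning 0, because the
  analysis interprets magnitudes — a silent 0 would masquerade as a
  perfectly uniform spread.
* **Inference.** A two-sided permutation test (random relabeling of tile
  values, add-one correction, $p = (1 + \#\{|I_\pi| \ge |I|\})/(1+B)$) is
  available as an extension; the underlying device study used the score
  descriptively only, so the test is off by default. Under permutation
  $E[I] = -1/(N-1) = -0.02128$ at $N = 48$, which the test suite verifies
  by Monte Carlo.
* **Exactness.** The matrix implementation is tested to $10^{-12}$ against
  a literal double-loop evaluation on random grids, and the alternating
  checkerboard under rook weights returns $-1$ exactly.

## From image to tile fractions

Segmentation follows the device's processing chain: optional unsharp-mask
sharpening (`clip(x + amount · (x − blur(x, σ)))`, Gaussian blur truncated
at 3σ via EBImage), then HSV thresholding. All three HSV channels are
scaled to $[0,1]$ and the hue interval may wrap through 0, since seed hues
sit near the red/yellow boundary. There are no universal thresholds: the
shipped defaults (`default_hsv_thresholds()`) are tuned to the synthetic
palette — warm-yellow soybeans, mid- and dark-brown ragweed on a near-white
belt — and segment synthetic scenes at IoU ≥ 0.99 against the ground-truth
mask. For real imagery thresholds are a required user input. On synthetic
scenes the sharpening step is a near no-op (flat colors plus white noise),
so the fast path scores the ground-truth mask directly; the segmentation
route is exercised in tests.

Tiling refuses non-divisible dimensions rather than dropping partial
tiles, and the identity
`sum(proportion) × tile area = foreground pixel count` holds exactly
(integers), which the suite asserts.

## The scene simulator

The generator emulates what the device's camera sees — a single layer of
seeds on a light belt — with three placement regimes spanning the
dispenser's behavior from clumped to singulated:

* **Thomas cluster**: Poisson parents, Gaussian offspring scatter
  (`cluster_sd_mm`); emulates adhesion/clumping. With exact target counts,
  each seed picks a uniform parent and a Gaussian offset.
* **Poisson / binomial**: independent uniform centers; complete spatial
  randomness.
* **Hard-core**: sequential inhibition with a minimum center distance;
  emulates singulation. The default radius of 12 mm follows the dispenser's
  ~14 mm socket pitch (about 1.5 soybean lengths). Infeasible packings
  fail loudly after a bounded number of rejections — never a silent
  shortfall.

Seeds are rendered as filled rotated ellipses at the class's mean caliper
dimensions with per-pixel Gaussian color jitter; orientations are uniform
on $[0, \pi)$. Ellipses are the simplest shape that preserves the size
contrast which makes small weed seeds hard to detect. The mask is the
*union* of footprints, so overlapping seeds lose mask area — intended,
since that is exactly the occlusion mechanism. Centers are inset from the
frame edge by each seed's semi-major axis by default (no clipped seeds);
`edge_clip = TRUE` lifts this. The default field is a 384 × 216 mm belt at
10 px/mm, giving the device's 3840 × 2160 frame; the physical field of
view is a convention here, not a measured value. One scene seed drives
three derived sub-streams (placement, color jitter, detection), so every
artifact is bit-reproducible from `(parameters, seed)`.

What the simulator does **not** model: optics (blur, specularity, shadow),
belt motion, 3D seed shape and pose, illumination drift, and real
detector behavior. Passing tests on synthetic scenes therefore validate
the *statistical machinery* — not segmentation robustness or detection
accuracy on real imagery.

The detector stand-in is count-level: per-class Bernoulli recall,
optional confusion-matrix relabeling, Poisson false positives (assigned
uniformly across classes unless a distribution is given). Its recovery at
the configured recall is checked against the binomial standard error.

## Taguchi analysis

The device exposes six factors — seed-socket arrangement (2 levels),
spreading-roller speed, conveyor-motor speed, seed-box inclination,
drop-chute inclination, conveyor-belt type (3 levels each) — screened with
the standard L18 orthogonal array (shipped as `taguchi_l18()`; 9 runs per
2-level setting, 6 per 3-level setting, pairwise orthogonal columns).
Each run's replicate observations are per-image Moran's I values pooled
over the three replicate sample groups (soybeans only, +1 %
*A. artemisiifolia*, +1 % *A. trifida*); the run is summarized by its mean
and by the smaller-the-better S/N ratio
$-10\log_{10}(\tfrac1m\sum Y_i^2)$ (ideal response: zero; all-zero
responses give $+\infty$ dB, not an error).

* **Response table.** Level means / S/N per factor; influence measured by
  delta (max − min); dense ranks on descending delta, ties sharing the
  smaller rank — the Minitab-style convention.
* **Sums of squares.** The per-factor between-level form
  $SS_f = \sum_v n_v(\bar y_v - \bar Y)^2$ with $n_v$ = runs per level
  (6 or 9 in the L18). This reconstruction, applied to the shipped device
  response table, reproduces the device study's published ANOVA (e.g.
  roller-speed mean SS 0.2277, motor-speed 0.3302; S/N SS 641.8 and
  696.6; MS 0.1138) to within table rounding — which is the justification
  for the interpretation.
* **Error term.** The published per-factor table implies a common residual
  mean square (its MS/F ratios are constant across factors), so the ANOVA
  pools the remaining variation: $SS_{err} = SS_{total} - \sum_f SS_f$
  (floored at 0) with $DOF_{err} = 17 - 11 = 6$. $F = MS_f / MS_{err}$;
  p-values are the F upper tail, uncorrected, judged against 0.05.
* **Optimal levels.** Two rules reported side by side: the mean rule picks
  $\arg\min_v |\bar y_v|$ (closest-to-zero average Moran's I), the S/N
  rule $\arg\max_v$ S/N (most stable). The two rules genuinely disagree on
  the speed factors (50/250 vs. 150/150); the package reports both and
  does not adjudicate — choosing between average performance and
  stability is an engineering trade-off, not a statistical one.

## Verification metrics

Per class, accuracy is $100 \cdot \min(\text{detected}, \text{true}) /
\text{true}$ — capping overcounts keeps accuracy ≤ 100 and makes
accuracy + leakage = 100 an identity. Published device-level accuracies
are not reproducible from printed counts by any simple ratio, so they are
treated as device measurements, not arithmetic targets, and the simulator
makes no attempt to match them. Composition percentages use the all-seed
denominator and say so in an output attribute; the protocol checker
(`check_composition()`) instead uses the weed-to-soybean ratio, matching
the spiking protocol (5 ± 0.5 % by count, 1 ± 0.05 % by mass per 500 g
sample, ~2000 soybeans).

## The virtual experiment

`run_virtual_experiment()` replays the L18 protocol with the simulator:
a knob map translates each run's factor levels into process parameters,
each run × group × image scene is scored, and the full analysis (response
table, ranks, ANOVA, optimal levels) is returned with a manifest recording
every scene's seed — deleting outputs and re-running from the manifest
reproduces them bit-identically. The default knob map is a declared toy
mechanism (per-level clumping scores summed and thresholded into
hardcore/poisson/thomas), with the speed factors dominating; tests use
custom maps to inject known effects and verify recovery (a single
clustering-controlling factor is ranked first in ≥ 95 % of repetitions;
with identical knobs everywhere, factor p-values are non-significant at
the expected rate).

## Problem sizes

Defaults match the study protocol (100 images per run and group,
full-resolution frames, 200 soybeans per frame with 1 % weed spikes in the
spiked groups). The examples, tests and the acceptance script use
deliberately smaller configurations — quarter-scale belts at 1–2 px/mm,
1 image per run, 25–200 seeds per scene, 50–500 replicates per stochastic
check — chosen so each statistical property under test retains a ≥ 3
standard-error margin. The regime-ordering check (mean I: thomas >
poisson > hard-core at matched counts) runs at 200 seeds per frame on the
full-size belt rasterized at 2 px/mm with 60–100 scenes per regime.

## Known limitations

* Rendering is flat-shaded; no illumination or perspective model.
* The hard-core sampler is sequential inhibition, which differs from an
  equilibrium Gibbs hard-core process at high packing fractions.
* Segmentation offers no instance splitting of touching seeds; counts come
  from the layout or the simulated detector, never from the mask.
* The Taguchi module covers the smaller-the-better characteristic only,
  and no interaction columns.
* Detection-time accounting and any trained detection model are out of
  scope; the detector model is a calibrated stochastic stand-in.
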