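---
title: "Interpreting multi-scale detection layers with Grad-CAM attention scores"
author: "spikeCAM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting multi-scale detection layers with Grad-CAM attention scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeCAM)
options(spikeCAM.quiet = TRUE)
```

## The problem

Single-stage object detectors such as YOLOv5 predict from several detection
layers at different strides: a *small-scale* head (stride 8, fine grid, small
receptive field), a *medium-scale* head (stride 16) and a *large-scale* head
(stride 32, coarse grid, large receptive field). Feature-map pixel counts
shrink by a factor of 4 from one head to the next while receptive fields grow
by the same factor. In wheat-spike (head) phenotyping imagery the object size
varies enormously between sites, genotypes and acquisition setups, so it is
not obvious which of these heads actually carries the detection — and
therefore not obvious how to slim down or strengthen the network.

spikeCAM quantifies each head's contribution with gradient-weighted class
activation mapping (Grad-CAM) and a per-object *attention score*, then turns
per-layer score statistics into rule-based refinement advice.

## The model

For one detection layer with feature maps $A^k_{ij}$ ($k = 1..K$ channels,
$Z = H \times W$ positions) and a scalar prediction score $y$ for the spike
class, the channel weights are the spatial means of the gradients,

$$\alpha_k = \frac{1}{Z} \sum_i \sum_j \frac{\partial y}{\partial A^k_{ij}},$$

and the class-activation map is the rectified weighted sum,

$$L_{\text{Grad-CAM}} = \mathrm{ReLU}\Big(\sum_k \alpha_k A^k\Big).$$

After upsampling to image resolution, the *attention area*
$R_{\text{Grad-CAM}}$ is the set of pixels with a strictly positive map
value. Each labeled box with pixel area $R_{\text{Label}}$ receives a score

$$S = \frac{|R_{\text{Grad-CAM}} \cap \text{box}|}{R_{\text{Label}}} \in [0, 1],$$

the fraction of the box the layer attends to. We compute the numerator as
the attention area *within* the box: large-stride layers routinely spread
attention far beyond the labeled boxes, and a plain area ratio would exceed 1
exactly in those cases while every published score table is capped at 1. The
intersection reading keeps $S$ a coverage fraction and makes the zero/one
edge cases meaningful ($S = 0$: the layer ignores the object entirely;
$S = 1$: the box is fully covered).

One CAM is computed per (image, layer) from a single backward pass of $y$,
and all boxes in the image are scored against it — per-object backward
passes are out of scope, as are Grad-CAM variants (Grad-CAM++, Score-CAM,
guided backprop).

## Per-layer statistics and the refinement rules

Scores are aggregated per layer into 0.1-wide bins ([0, 0.1), ...,
[0.9, 1.0], the last bin closed so a perfect score is counted), each bin
carrying the percentage of spikes and their mean pixel size. A separate
*zero-score audit* reports the proportion and mean size of spikes with
$S = 0$ — the objects the layer misses outright. Zero-score records are
counted inside the first bin *and* reported separately; both views are
emitted because they answer different questions (score distribution vs.
outright failure). Display rounding (proportions to 1 decimal, sizes to
integers, mean scores to 3 decimals) only affects the formatted report;
machine-readable output keeps full precision.

Layer ranking uses the zero-score proportion as the primary criterion and
mean score as tie-break. The mean score alone cannot reproduce the observed
verdicts: on multi-site wheat data the large-scale layer has the *highest*
mean score (0.309) yet misses 30% of all spikes, which is exactly why it is
judged worst.

The advisor grades each layer from its zero-score proportion:

* **poor** at or above `zero_poor_pct` (default 25%),
* **excellent** at or below `zero_excellent_pct` (default 20%),
* **moderate** in between,

and maps (role, verdict) to actions: a poor large-scale layer is removed; an
excellent small-scale layer is kept and gains a micro-scale companion head
(a poor one is removed); an excellent medium-scale layer gets feature
enhancement. The published grades are never quantified numerically in the
source study, so the thresholds are this package's own calibration: they are
chosen once so that the reported multi-site zero proportions (17.5% small,
4.0% medium, 30.0% large) reproduce the published refinement — remove
large, keep small + add micro-scale, enhance medium — with margin on both
sides (17.5 sits 2.5 points under the excellent bound, 30 sits 5 points
over the poor bound). Both thresholds are configurable and echoed in every
report, and the rationale strings embed all statistics, not only the
deciding one.

```{r}
stats <- list(
  layerStatsFromSummary("small", 17.5, meanScore = 0.083,
                        zeroMeanSpikeSize = 13040),
  layerStatsFromSummary("medium", 4.0, meanScore = 0.25,
                        zeroMeanSpikeSize = 4660),
  layerStatsFromSummary("large", 30.0, meanScore = 0.309,
                        zeroMeanSpikeSize = 3434))
advise(stats)
```

## The toy detector

Grad-CAM needs feature maps *and* their gradients. To keep the toolkit
testable end to end without an external deep-learning framework, spikeCAM
bundles a fully hand-implemented toy multi-scale detector: a stack of
stride-2, kernel-3, zero-padded convolutions with ReLU activations, tapped
at cumulative strides 8 / 16 / 32 so that successive detection-layer pixel
counts differ by a factor of 4 — the same scale structure as the three-head
networks it stands in for. Each tapped layer feeds a 1x1 single-channel
response head; the target score $y$ is the global sum of the configured
heads. This definition of $y$ is a design choice: a real detector's "spike
class score" involves anchor decoding and NMS, which are out of scope, while
a head sum yields dense, well-defined gradients everywhere and keeps the
backward pass exactly differentiable.

Numerical choices:

* **Padding**: zero padding with output size $\lceil n / s \rceil$, which
  keeps the factor-of-4 pixel-count relation exact for power-of-two inputs.
* **Weights**: seeded uniform in $[-0.5, 0.5]$, biases zero. Sign diversity
  matters — it exercises the ReLU in the CAM rectification. Weights are
  bit-reproducible from the seed.
* **Gradients**: hand-written backpropagation through ReLU (subgradient 0 at
  exactly 0) and convolution. Because the network is piecewise linear in any
  single activation entry, central finite differences are exact away from
  ReLU kinks; the test suite checks agreement to a relative error of 1e-4 at
  $\varepsilon = 10^{-4}$ on seeded 2-layer configurations.

Activations and gradients from *real* detectors enter through a portable
binary array file (magic header, dtype, shape, little-endian reals; one
array per file, shape order K x H x W, naming
`<image_id>__<layer_id>__{values|grads}`). The format carries a float32 /
float64 dtype flag: external frameworks typically dump float32, while the
package's own dumps default to float64 so a dump-and-reload round trip
reproduces downstream CAMs bit for bit. How a user defines $y$ for a real
multi-box detector (per-detection, class-summed, confidence-filtered) is
deliberately left to the user and recorded as a free-text `definitionTag`.

## The synthetic scene generator

Real multi-site wheat imagery is emulated by seeded synthetic scenes:
elliptical Gaussian-intensity blobs on a flat (or noise-textured)
background. The log-normal size distribution governs the **bounding-box
area** (width x height, in px^2) — the same semantics as the "average spike
size" columns of multi-site wheat datasets — and the blob's support (pixels
above 10% of its peak) is the ellipse inscribed in that box, so every
ground-truth box is the tight bounding box of visible object pixels.
Placement rejects candidates whose box IoU with any earlier box exceeds
`maxOverlapIoU` (default 0.3), with 200 retries per object before failing
loudly.

Defaults: dispersion 0.25 on the log scale (a moderate ~25% spread, so the
mean area exceeds the median by only ~3%), aspect ratios uniform in
[0.5, 2], peak intensities uniform in [0.5, 0.9], additive Gaussian pixel
noise with sd 0.02. Four presets mirror the four sub-dataset scales used
for multi-site interpretive analysis — median box areas 4783 (ethz-like),
6312 (arvalis-like), 9247 (usask-like) and 15271 px^2 (inrae-like), with
per-image object counts 69 / 43 / 29 / 21 from the corresponding
spikes-per-image ratios, on 1024 x 1024 images.

What the generator does *not* emulate: spike texture and awns, occlusion by
leaves, illumination gradients, genotype- or growth-stage-dependent
morphology, and label noise. Passing tests on synthetic scenes therefore
demonstrate the correctness of the attention machinery and statistics, not
detection performance on real imagery.

`corruptDetections()` turns ground truth into imperfect detections with
known failure modes (per-box drop rate, Gaussian corner jitter with
confidence $1/(1 + \text{mean |offset|})$, uniform-confidence false
positives), giving the evaluation module inputs with analytically known
recall ceilings.

## Detection evaluation

Matching is greedy by descending confidence: each detection claims the
unmatched ground truth of highest IoU at or above the threshold (default
0.5; ties break to the earlier ground-truth row, then the earlier
detection). Precision $TP/(TP+FP)$ and recall $TP/(TP+FN)$ are swept over
confidence cuts, and AP integrates precision over recall using the
all-point interpolated envelope (precision at recall $r$ replaced by the
maximum precision at any recall $\ge r$); the classic 11-point
interpolation is available for comparison. The source study prints neither
its matching threshold nor its interpolation rule, so the defaults follow
the VOC-2010 convention that mainstream detector tooling uses. The greedy
matcher is verified in the test suite against exhaustive assignment
enumeration on all instances with up to 5 detections and 4 ground truths.

## Numerical and degenerate-input conventions

* Coordinates are 0-based, half-open ($x_{\min} \le x < x_{\max}$), y down.
  GWHD-style packed box strings use inclusive max corners and gain +1 on
  read; YOLO labels convert with floor (min corner) / ceil (max corner)
  after snapping to 9 decimals so decimal inputs behave as written.
* Bilinear CAM upsampling aligns pixel centers and replicates edges;
  nearest-neighbour preserves the multiset of distinct values.
  Downsampling is refused.
* The mask threshold default is 0 (strict positivity). Whether the original
  analysis thresholded above 0 is unknown; the knob exists (`threshold`)
  but the default follows the "non-empty Grad-CAM area" definition.
* Raw CAM magnitudes are kept for region extraction; min-max normalisation
  happens only inside heatmap rendering (an all-zero map stays zero; a
  constant positive map renders at the top of the ramp). Attention scoring
  depends on emptiness, not magnitude.
* Empty record sets raise explicit statistics errors rather than returning
  silent zeros; infeasible blob placement names the failing object.
* Bin proportions are computed from exact integer counts; their float sum
  sits within 1e-9 of 100 and the counts reconstruct the total exactly.

## Problem sizes used in the checks

The bundled verification runs are sized for a laptop-class single CPU: the
gradient check uses 2-layer detectors on 8 x 8 inputs (132 gradient entries
across 3 seeds), the Grad-CAM oracle sweeps 100 random layers up to
8 x 8 x 8, the score-law check 1000 random mask/box pairs, and the
end-to-end study three 128 x 128 scenes with 8 objects of median box area
500 px^2 (24 spikes x 3 layers = 72 records per run, run twice to confirm
byte-identical outputs). These sizes are the package's own choice of a
representative small study; all of them scale linearly if users want larger
runs.

## Known limitations

* The toy detector is untrained; its attention maps are those of a random
  network. It validates the attribution and scoring machinery, not
  detection quality. On its random weights most layers look "poor" — as
  they should.
* Attention is not partitioned among overlapping boxes; a pixel may count
  toward several spikes (no assignment rule exists in the underlying
  method).
* The advisor's thresholds are a calibration, not an estimated quantity;
  with other datasets they should be re-examined rather than trusted.
* AP here evaluates box sets, not the multi-resolution training experiments
  of the original study (training, PANet/BiFPN fusion and dataset downloads
  are out of scope).
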