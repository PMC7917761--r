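---
title: "Cascaded shape regression for thermal face alignment: models and methods"
author: "thermalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded shape regression for thermal face alignment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Remote physiological assessment from thermal infrared video — respiration,
stress, autonomic activity — reads skin temperature from facial regions of
interest (nose, cheeks, periorbital area). Locating those regions requires
facial landmarks, but thermal frames lack the texture cues that visible-light
landmark detectors rely on: no skin albedo, no eye sclera contrast, and
appearance that changes with vasomotor state. Generative model fitting (AAM
variants) works on thermal faces but is slow and brittle for unseen subjects.
This package implements the discriminative alternative: cascaded shape
regression (CSR) with gradient-boosted ensembles of regression trees (ERT),
which needs only coarse monotone intensity information and runs at real-time
rates on a single core.

## The model

A face shape is the stacked landmark vector
$S = (x_1, y_1, \dots, x_M, y_M)^\top$ with $M = 68$ points in the standard
annotation scheme. Starting from an initial shape $S^{(0)}$ the cascade
refines the estimate through $T$ stages:

$$S^{(t)} = S^{(t-1)} + \Delta S^{(t)}, \qquad
  \Delta S^{(t)} = r^{(t)}(I, S^{(t-1)}),$$

where each stage regressor $r^{(t)}$ maps the image $I$ and the current
estimate to a shape increment. Each $r^{(t)}$ is an ensemble of $K$ depth-$F$
regression trees combined by gradient boosting with shrinkage $\nu$, trained
to minimize

$$\sum_i \left\lVert \hat S_i - \left(S_i^{(t-1)} +
  r^{(t)}(I_i, S_i^{(t-1)})\right) \right\rVert^2$$

over the training images, where $\hat S_i$ is the annotated ground truth.
Each split node thresholds a *two-pixel intensity difference*: the image is
probed at two positions indexed to the current shape (an anchor landmark
plus an offset carried from the mean-shape frame by a similarity transform),
and the scalar difference of the two intensities decides the branch. This
makes every feature pose-covariant and cheap.

### Initialization and the mean shape

The initial estimate $S^{(0)}$ is the mean shape: every training shape is
mapped into the unit square spanned by its face bounding box (translation
plus anisotropic scale), averaged per landmark, and scaled back out by the
test-time box. The normalization frame is a design choice of this package —
bounding boxes are the only exogenous geometry available at test time, so
they define the reference frame end to end.

### Residual frame

Boosting residuals $\hat S_i - S_i$ are expressed in a per-sample
isotropically normalized frame, divided by $s_i = (w_i + h_i)/2$ of the
sample's bounding box, and leaf updates are scaled back by $s_i$ when
applied. With three camera distances in the protocol the same leaf vector
must serve faces of ~184 and ~97 px width; normalizing makes those
commensurable. The boosting objective is unchanged apart from this fixed
per-sample weighting, and the monotone-decrease property of the training
loss holds in the normalized frame (this is the loss recorded in
`lossTrace`).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `T` | 10 | cascade stages |
| `K` | 500 | boosted trees per stage |
| `F` | 4 | tree depth (16 leaves) |
| `P` | 400 | probe pixels per stage pool |
| `nCandidates` | 400 | candidate (u, v, θ) triples per split node |
| `shrinkage` | 0.1 | boosting learning rate ν |
| `spread` | 0.15 | probe offset half-width, mean-shape units |
| `normalization` | minmax | thermal → [0,1] intensity mapping |
| `lambdaPrior` | 0 | closeness prior on probe pairs, exp(−λ‖u−v‖) |

`T`, `K`, `F`, `P` default to the protocol's stated settings. The remaining
values are this package's choices where the protocol is silent:

* **Shrinkage ν = 0.1.** Gradient boosting requires a learning rate; 0.1 is
  the standard in the ERT lineage this method follows. Larger values fit the
  training set faster but generalize worse across subjects.
* **`spread` = 0.15** of the mean-shape frame keeps probes on or near the
  face at every stage; substantially larger values waste candidates on
  background pixels whose minmax-normalized values are near 0 everywhere.
* **Candidate interpretation.** The protocol states both "a random pair of
  pixels P = 400" and "400 randomly sampled features per split node". These
  are reconciled as: a per-stage pool of P = 400 probe points, and at each
  split node 400 candidate (u, v, θ) triples drawn from that pool, keeping
  the best. A fresh pool is drawn per stage, consistent with the cited
  method family.
* **`lambdaPrior` = 0** reproduces the stated uniform pairing; the
  exponential closeness prior common in this method family is available but
  off.

## Numerical and algorithmic choices

* **Split search.** At each node, candidate thresholds are drawn uniformly
  between the observed min and max of the candidate feature at that node;
  candidates are scored by between-child sum of squares (equivalent to
  squared-error reduction), ties broken by first-seen order under the seeded
  stream. An `exhaustive` mode searches *all* probe pairs × all midpoint
  thresholds and is verified in the tests against an independent recursive
  brute-force oracle.
* **Trees are complete depth-F heaps.** Nodes with fewer than two samples
  (or no admissible split under `minLeaf`) become pass-through nodes: a
  zero-effect split with θ = +∞. Empty leaves hold zero vectors, so they
  never move a prediction.
* **Features are extracted once per stage** at the stage-entry shapes —
  the stage regressor is a function of $(I, S^{(t-1)})$, not of the
  intermediate boosted estimates.
* **Nearest-pixel lookup, border-clamped.** The feature is a coarse
  intensity difference; nearest lookup keeps extraction exact under integer
  translations (the property the tests exercise) and total under extreme
  pose estimates.
* **Determinism.** One master seed is split by a deterministic integer mix
  into named substreams (per stage pool, per tree candidates, per fold).
  Training twice with the same seed yields byte-identical models; model
  serialization preserves doubles exactly, so reloaded models predict
  bitwise-identically.
* **Coordinates** are 0-based with pixel centers at integers throughout;
  the 1-based convention of the on-disk pts dialect is converted at I/O.
  Horizontal flips use x → W − 1 − x, so double flipping is exact up to
  floating-point association (≤ 1e−9 in practice).

## The NPPE metric

For a predicted shape $S_r$ and annotation $S_g$ over $N$ landmarks,

$$\mathrm{NPPE} = \frac{1}{N}\sum_{n=1}^{N}
  \sqrt{(x_{n,r}-x_{n,g})^2 + (y_{n,r}-y_{n,g})^2}
  \; \Big/ \; \tfrac{w + h}{2},$$

the mean landmark error as a fraction of face size; 0.05 is the
conventional acceptability level. Face extent $(w, h)$ is taken from the
ground-truth landmark bounding extent (annotation-tool independent), with a
flag to use the manifest box instead. The metric appears both as a fraction
(CED curves, thresholds like 0.05) and ×100 as a percentage (per-distance
tables); both are the same number on two scales. Cross-validation is
subject-wise: one fold per subject, all of that subject's images held out,
flipped copies following their subject so no identity leaks across the
split. By default mirrored duplicates are excluded from test sets (a flag
restores the alternative reading); they would only double-count each image.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *structure* of the acquisition protocol so the
full pipeline can run and be measured without any external data:

* 7 subjects × 87 images (609 total; 1218 after flips), three camera
  distances with face widths ≈184/126/97 px (scatter 20/13/10 px), three
  recording intervals per distance — Small and Large cycling nine head
  directions at 20°/45°, Random drawing free poses within ±45° plus
  expression jitter on mouth and brows. With 87 images per subject the
  per-distance allocation is 9 Small + 9 Large + 11 Random; the true
  per-section breakdown behind 87 is not part of the emulated protocol's
  stated totals, and this allocation is the package's own convention
  reproducing them.
* Per-subject facial temperature parameters use the seven reference
  subject statistics (min 29.2–31.4 °C, max 33.7–34.3 °C, mean
  31.9–33.0 °C over ~24 °C ambient); each rendered face's temperature field
  is calibrated so its face-region min/mean/max equal the subject's
  parameters exactly before noise. Warm anchors sit at the inner eye
  canthi and forehead, cool anchors at the nose tip — the gradient
  structure reported throughout the thermal-imaging literature.
* Sensor noise is Gaussian with σ = 0.05 °C (the camera class's stated
  thermal resolution), truncated at ±3σ as the camera noise model, so
  rendered extremes stay within the declared envelope even across tens of
  thousands of face pixels.
* Out-of-plane pose is approximated by anisotropic compression
  (cos yaw / cos pitch about the centroid) plus in-plane roll — plausible
  2-D landmark/appearance covariation without a 3-D head model, and exactly
  invertible so stored landmarks are exact ground truth by construction.

What it does **not** emulate: self-occlusion at large yaw (compressed faces
remain fully visible), glasses and hair, breathing-driven nostril
temperature dynamics, radiometric artifacts, background clutter, or
between-image autocorrelation within a recording interval. Synthetic faces
are also substantially more homogeneous than real ones. Passing the
held-out-subject experiment here therefore demonstrates that the estimator,
features, training loop and evaluation protocol are implemented correctly
and can recover an unseen subject's geometry under pose, scale and
temperature variation — it does not certify accuracy on real thermal faces.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run a scaled-down replica of the
study: 7 subjects × 30 images, training on six subjects with flip
augmentation (360 images) at T = 10, F = 4, K = 200, P = 400, evaluating on
the held-out seventh subject's 30 originals. These sizes were chosen so a
complete training run takes a few minutes on one core while leaving the
cascade deep enough to show the per-stage error decay; the full-size
protocol (87 images/subject, K = 500) runs through exactly the same code
path via `protocolSpec()` and `csrConfig()` defaults. Boosting
monotonicity is checked at T = 10, K = 100 on a 100-image study, and
protocol counts (609/1218/68/7 folds) on the full-size default study.

## Known limitations

* Pure R prediction keeps per-frame latency in the tens of milliseconds;
  the throughput reported by `benchmarkFPS()` is hardware-dependent and
  deliberately not a tested quantity.
* The closeness prior (`lambdaPrior`) uses per-anchor categorical sampling
  and is noticeably slower than the default uniform pairing.
* `meanShape()` averages in the bbox frame; no generalized Procrustes
  refinement is applied (out of scope for this estimator, whose
  initialization is bbox-driven by design).
* Bounding boxes are inputs everywhere; there is no face detector.
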