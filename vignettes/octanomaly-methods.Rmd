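---
title: "Anomaly detection in OCTA en face images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anomaly detection in OCTA en face images: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Optical coherence tomography angiography (OCTA) renders retinal blood
flow as en face projections: bright curvilinear vasculature on a dark
background. Ocular and systemic disease perturbs this pattern —
capillary non-perfusion erases signal, neovascularisation adds dense
tangles, vessel tortuosity bends the vessel course — but annotated
lesion datasets are scarce and disease-specific. `octanomaly` therefore
treats the task as *unsupervised anomaly detection*: both of its
detectors learn only what healthy vasculature looks like and score
deviations from it, so they are not tied to any particular disease or
biomarker.

## Route 1: VQ-VAE with an autoregressive latent prior

The VQ-VAE encoder compresses an image into an `h x w` grid of
`d`-dimensional feature vectors; each vector is replaced by the nearest
of `K` learned codebook prototypes (Euclidean distance, ties to the
lowest index), and the decoder reconstructs the image from the
quantized grid. Training minimises

* an L1 reconstruction term (L1 is the standard choice for this
  architecture family and is robust to the long-tailed intensity
  distribution of angiography),
* the *alignment* term `||sg[E(x)] - e||^2`, whose gradient updates only
  the codebook (each selected prototype moves toward the features it
  quantizes),
* the *commitment* term `||sg[e] - E(x)||^2` (weight 0.25 by default),
  whose gradient updates only the encoder and keeps it from oscillating
  between codes.

Reconstruction gradients pass through the quantizer by the
straight-through estimator. Alignment and commitment are numerically
equal — they differ only in which side receives the gradient — and the
per-position squared distance is kept as the **Alignment Loss Map
(ALM)**: after training on healthy scans, codebook prototypes tile the
healthy feature distribution, so anomalous tissue produces features far
from every prototype and lights up in the ALM.

Two training details matter for making the discrete bottleneck learn
reliably at small scale, and both are purely about optimisation, not
the model:

* **Autoencoder warm-up.** For the first `warmup_epochs` (desk default
  5 of 20) the encoder output feeds the decoder directly, unquantized.
  Bootstrapping the quantizer against a randomly initialised encoder is
  unstable — assignments churn, the decoder learns to ignore its input,
  and the codebook can collapse onto a single prototype. A short
  warm-up gives the encoder informative features first.
* **k-means codebook initialisation.** At the end of the warm-up the
  codebook is initialised by k-means over encoder features of training
  images, so every prototype starts inside the feature distribution and
  none is born dead. Codebook vectors then follow the alignment-loss
  gradient (no exponential moving averages), with a learning-rate
  multiplier (default 10) so the codebook can track the still-moving
  encoder. Prototypes that stop being selected are left where they are.

The **AR prior** models healthy latent grids as a product of causal
conditionals in raster order (row-major). It is a masked-convolution
network: the first layer uses a type-A mask (center excluded), deeper
layers type-B masks, which makes the causality structural — position
`i` *cannot* receive information from positions after it, a property
the tests verify bit-exactly and that also guarantees the factorisation
is normalized (the test suite checks that all 81 grid probabilities of
a 2x2, K=3 toy sum to 1). Two further choices:

* **Positional input channels.** Two normalised coordinate channels
  accompany the one-hot symbols. Masked convolutions alone are
  translation-invariant, so without position they cannot distinguish an
  ectopic signal void from the physiological one at the fovea; the
  full-scale models of this family are position-aware through their
  attention layers. Coordinates carry no information about future
  symbols, so causality is untouched.
* **Early stopping.** With a small healthy cohort the prior overfits:
  held-out healthy grids grow more surprising with further training,
  eroding the healthy/diseased contrast. The trainer monitors mean NLL
  on healthy validation latents and restores the best-validation
  weights (patience 5).

The full-scale architecture in this family adds self-attention between
convolution blocks; at the desk scale of a 16x16 grid the masked
convolutions already cover the useful context, so attention is not
implemented and the model is documented as what it is, a
masked-convolution causal network.

**Scan-wise score.** The per-position negative log-likelihood (NLL, in
nats) of a test grid is summed over cells strictly above a threshold
`t_ar`, calibrated as the 95th percentile of pooled per-cell NLL values
of healthy *validation* scans. Pooling per-cell (rather than per-scan)
is the finer-grained choice and is exposed as such. Healthy scans then
contribute only their top 5% tail; anomalous latents are improbable
under the prior and accumulate surprise quickly.

**Pixel-wise score.** The ALM is upscaled to image resolution by
nearest-neighbour interpolation (values are preserved exactly, so
thresholds keep their meaning), thresholded strictly at `t_al`, and
refined by opening, dilation and small-component removal.

## Route 2: Bayesian U-Net epistemic uncertainty

A U-Net (conv 3x3 + batch normalisation + ReLU + dropout per block,
2x2 max pooling down, transpose convolutions up, skip connections)
is trained to segment vessels on healthy scans only, against the
phantom generator's exact vessel masks standing in for weak labels,
with loss `CE + beta * (1 - Dice)` and `beta = 0.6`. At test time
dropout stays active and `n` stochastic passes are drawn (default
`n = 20`, dropout probability 0.1 — neither is prescribed by the
method, so both are explicit configuration with their values reported
alongside results). The epistemic uncertainty at a pixel is the
per-class *population* variance (divide by `n`, matching the estimator's
definition) of the sampled class probabilities, averaged over the two
classes; predictions are used as post-softmax probabilities rather than
hard labels because the variance of probabilities yields smoother, less
quantized maps (a switch to hard labels would only coarsen the same
signal). For two classes the map is bounded by 1/4, is zero exactly
when all samples agree, and — the mechanism this route relies on — is
systematically higher on vasculature the model has never seen in a
healthy configuration.

Scan-wise scores sum uncertainty above `t_un`; pixel-wise segmentations
threshold at `t_un` and refine as above.

## Threshold calibration

All three thresholds are determined on the healthy validation split,
never on test data. `t_ar` is the 95th percentile of pooled validation
NLL cells. For `t_al` and `t_un`, the full-resolution reference values
(0.05 for the ALM, 0 for uncertainty maps) are tied to the score scales
of fully-converged full-scale models; at desk scale the package instead
calibrates them on the validation split: candidate thresholds are
percentiles (90–99.5) of pooled healthy validation score cells, and
when the validation split contains diseased scans the candidate with
the best mean validation Dice is selected — thresholds are tuned on
validation data, never on the test split, mirroring standard practice
for operating-point selection. Without diseased validation scans the
99th percentile is used. Both thresholds can also be fixed to any
value in the run configuration. The strict (`>`) comparison in `binarize()` means a
threshold of exactly 0 flags *any* strictly positive uncertainty.

## The synthetic phantom study

The generator emulates the geometry that the detectors exploit:
curvilinear bright vessels (bounded-curvature random walks with
Gaussian cross-sections, stochastic branching) over a dense fine
capillary mesh (band-pass-filtered noise at capillary scale, contrast
0.35) — en face full projections show a perfused reticular field, not
a dark void, and that matters: a non-perfusion anomaly must be a hole
in an otherwise filled texture to be out-of-distribution at all. A
darker central disk imitates the foveal avascular zone (FAZ), and
additive noise completes the background. Anomalies are injected into
circular regions with exact masks:

* **dropout** — intensities pulled toward the dark signal floor (the
  5th percentile of non-vessel intensity) by a severity factor;
  severities are drawn from Uniform(0.6, 0.95),
  substantial but incomplete perfusion loss (clinical non-perfusion
  retains faint residual signal, and a faint remnant is also what makes
  the region ambiguous to a vessel segmenter);
* **tuft** — a dense tangle of short bright strokes, emulating a
  neovascular membrane;
* **tortuosity** — a smooth sinusoidal displacement field confined to
  the region (severity scales amplitude, tapered to zero at the region
  boundary), producing a locally non-smooth vessel course.

Region radii are drawn from 10–22 px at 128 px resolution (roughly 1/12
to 1/6 of the field of view). Healthy phantoms are split 80/10/10 into
train/validation/test; diseased phantoms 50/50 into validation/test, so
training is healthy-only by construction and the validator enforces it.

What the phantoms do *not* emulate: OCTA speckle statistics, capillary
meshwork texture, motion and shadowing artifacts, field-of-view
vignetting, or the continuum of real lesion appearance. Passing the
desk-scale study therefore demonstrates that the machinery — discrete
representation learning, causal likelihood scoring, uncertainty-based
segmentation, calibration and evaluation — works end to end and detects
the geometry of perfusion anomalies; it does not certify clinical
performance on real OCTA, which requires full-scale training on real
healthy scans.

## Scale presets and problem sizes

The `desk` preset is sized so a complete study (200 healthy + 40
diseased phantoms at 128 px, both routes, training included) runs in
roughly a quarter hour on one CPU core: VQ-VAE with channels (8, 16,
32), one residual block per stage, K = 32 codes of dimension 64 on a
16x16 latent grid (the same 8x spatial compression as 480 to 60), 20
epochs at batch size 1 (with a small training set, optimiser steps
matter more than gradient smoothing; the full-scale preset keeps batch
4); the AR prior with 2 hidden masked-conv blocks, 32 channels, up to 80
epochs with early stopping; the U-Net at depth 4 with 8 base channels,
8 epochs. The
`paper` preset carries the full-scale settings (480-px inputs, 5
conv blocks of 4 residual blocks, K = 128, d = 256, 60x60 latents, 200
VQ-VAE epochs, AR with 4 blocks and 300 epochs, U-Net depth 5 with 64
channels) and is intended for GPU-class budgets.

## Numerical choices and degenerate inputs

* Quantization ties break to the lowest codebook index; the ALM is
  exactly zero iff a feature equals its prototype.
* `standardize()` min-max rescales to [0, 1]; constant images map to 0.
  Center crops use equal margins with odd remainders toward the
  top-left; resizing is bilinear. Already-standardized images pass
  through unchanged (idempotence).
* Hessian eigenvalues are ordered by absolute value with |.|-ties
  broken by signed value; trace/determinant identities are asserted to
  1e-9. The vesselness response uses the bright-ridge convention
  (respond only where the dominant eigenvalue is negative) with
  scale-normalised derivatives (gamma = 2), ratio term beta = 0.5 and
  structureness scale c set to half the per-scale maximum; scales
  {1, 2, 4} px by default. The ridge filter follows the Frangi
  construction from the two eigenvalues; any eigenvalue-based ridge
  response satisfying the same contracts (zero on constants, stronger
  on ridges than off, rotation-equivariant) would serve.
* Vesselness enhancement is exposed on the segmentation path but off
  by default: at desk scale the ridge filter suppresses the
  capillary-mesh texture the segmenter relies on, and held-out vessel
  Dice is measurably higher on raw standardized images. The
  classification paths always consume raw standardized images
  (enhancement flattens the global intensity statistics that scan-wise
  scoring uses).
* Connected components use 8-connectivity; component removal keeps
  areas `>= s`. Morphology radii (opening 1, dilation 2) and `s = 64`
  px^2 are expressed at 480-px scale and rescaled (area
  quadratically) to the working resolution.
* Both-empty-mask Dice is 1, so anomaly-free evaluation images cannot
  poison test-set averages; the same convention guards the
  empty-denominator confusion-matrix ratios.
* The Youden operating point is selected on the same score set being
  evaluated (the convention for small test sets); Youden ties break
  toward higher specificity.
* Population (1/n) variance is used in the uncertainty map, matching
  the estimator's definition rather than the n-1 sample variance.
* Mini-batches accumulate gradients image by image (there is no batch
  dimension in the tensor layout); batch normalisation therefore
  normalises over the spatial dimensions of a single image during
  training and uses running moments at inference.

## Known limitations

* The desk-scale models are deliberately small; their absolute scores
  are not comparable to full-scale results on real data, which is why
  thresholds are recalibrated rather than transplanted.
* The AR prior's latent resolution (16x16 at desk scale, 60x60 at full
  scale) bounds how small an anomaly can be resolved; lesions far
  smaller than one latent cell (8 px at desk scale) are diluted.
* Capillary dropout removes structure, and a region that merely lacks
  vessels also occurs in healthy anatomy (the foveal avascular zone),
  so dropout is intrinsically the hardest of the three anomaly classes.
  On the phantom study this shows quantitatively: the Alignment Loss
  Map and the uncertainty map localise neovascular tufts well (the
  added tangle is texture the healthy models have never quantized or
  segmented) but barely react to dropout — a clean signal void is
  *confidently* background to the U-Net and quantizes cheaply for the
  codebook — and only the causal prior, which sees spatial context,
  retains a scan-level signal for it. Real non-perfusion retains
  ambiguous residual texture that these detectors feed on, which the
  phantoms deliberately do not fabricate; phantom results for the
  dropout class are therefore conservative lower bounds on the
  mechanism.
* Desk-scale separation has intrinsic variance: scan scores sum the
  NLL tail over a 16x16 grid, and phantom-to-phantom geometry
  differences move healthy scores by more than a small anomaly does.
  Scan-wise AUROC on the phantom study sits well above chance but far
  below the full-scale result on real data, and the per-class
  behaviour above explains the gap.
* The conv-net core is single-threaded CPU code built for desk-scale
  problems; full-scale presets are functional but not practical
  without far larger compute.
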