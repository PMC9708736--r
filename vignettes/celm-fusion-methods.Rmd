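---
title: "Pixel-selection fusion of multimodal medical images with a convolutional extreme learning machine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-selection fusion of multimodal medical images with a convolutional extreme learning machine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celmfuse)
```

## The problem

Co-registered images of the same anatomy from different modalities carry
complementary information: CT-like images resolve bone and sharp outline,
MRI-like images resolve soft tissue, SPECT adds functional pseudo-color.
`celmfuse` combines such a pair into a single image by deciding, pixel by
pixel, which source is the more informative one and copying that pixel.
The result is always *selective*: every output pixel equals the
corresponding pixel of one of the two inputs, so no blending artifacts,
contrast loss or spectral distortion can be introduced.

## The classifier

The decision engine is a convolutional extreme learning machine (CELM):
a siamese convolutional feature extractor whose convolution weights are
**random and fixed**, capped by a linear output layer that is the only
fitted component.

Each branch maps a 32×32 patch through

```
conv 3×3 (64) → ReLU → maxpool 2×2/2
conv 3×3 (128) → ReLU → maxpool 2×2/2
conv 3×3 (256) → ReLU → global average pooling
```

All convolutions are valid (no padding) cross-correlations, so a k×k map
becomes (k−r+1)×(k−r+1); the spatial trace is 32 → 30 → 15 → 13 → 6 → 4,
and global average pooling yields 256 non-negative channel means per
branch. The two branches share one kernel bank (weight sharing is what
makes the network siamese: both sources are measured with the same
features), and their outputs are concatenated into a 512-vector.

Kernel entries are drawn i.i.d. from N(0, 1/fan_in) with
fan_in = in_channels·r²; this variance-preserving scale keeps post-ReLU
activations comparable across layers, which matters because no
normalization layers exist in the network. Biases are zero. The bank is
a pure function of `(config, seed)`.

The output weights β solve the ridge system

  β = (I/C + HᵀH)⁻¹ HᵀT,

where H stacks the 512-feature rows of all training pairs and T holds
the 0/1 labels ("1: source A is the informative member"). We solve the
linear system by Cholesky factorization rather than forming the inverse,
and verify the normal-equation residual to 1e−8. The score of a patch
pair is the inner product of its features with β, clamped to [0, 1];
0.5 is the decision threshold, with ties ("score exactly 0.5") going to
A.

Design points that the architecture description leaves open, resolved
here as package decisions:

* the two branch vectors are combined by **concatenation** — it
  preserves both branches' information and keeps the ridge fit
  unchanged;
* a **single linear output node** with targets {0, 1}; no activation
  precedes β;
* the ELM "hidden layer map" is identified with the random-kernel GAP
  features themselves — all convolution weights are random, only β is
  fitted;
* the regularization constant defaults to C = 1 and is configurable.

## Dense scoring of whole images

Training uses patches; fusion scores whole images. `score_map()`
evaluates the patch pair centered on every grid pixel (default stride 4)
after reflect-padding both sources by half a patch, then spreads grid
scores by nearest neighbor. `exact = TRUE` scores every pixel.

Because the default stride equals the network's cumulative pooling
factor (two pools of stride 2), all patch windows on the grid see
pooling boundaries at the same alignment. The implementation exploits
this: one conv/pool pyramid over the whole padded image serves every
patch of one alignment class, with per-patch GAP features read off as
box sums over the last convolution map. This is an exact
re-factorization — the arithmetic per output is the same as per-patch
evaluation (tested to 1e−10 against an independent per-patch path), and
grid points of a strided map are bit-identical to the exact map. A
256×256 pair fuses in about a second at stride 4 on one core.

## The two-stage fusion scheme

**Stage 1.** Thresholding the score map gives the binary label map;
the initial fused image F copies A where the label is 1, B elsewhere.
A consistency matrix records that ownership. Isolated misclassified
pixels are then corrected by a 3×3 majority-style filter over the
*original* ownership (a single pass, no in-place cascade, so the result
is order-independent): if the eight neighbors sum to ≥ 5 the pixel is
taken from A, ≤ 3 from B, and exactly 4 leaves it unchanged. Borders
replicate-pad the ownership matrix.

**Stage 2.** The refinement asks, neighborhood by neighborhood, which
source the initial fusion actually drew its information from. For each
pixel we compare the 5×5 windowed RMS of the residual F−B against that
of F−A; the binary map MF is 1 where F is strictly farther from B
(evidence that the local content came from A). A seemingly symmetric
alternative — comparing the *cross* residuals (F−B)−A and (F−A)−B — is
algebraically vacuous: both expressions are the same image F−A−B, so
that contest ties everywhere and carries no information; the
residual-magnitude contest is the operative rule. Ties (r1 = r2) give
MF = 0.

MF is smoothed by one binary opening followed by one closing with a
flat 5×5 square structuring element ("square identity matrix" read as
the all-ones square: a literal diagonal matrix would not smooth region
outlines). Opening removes speckle smaller than the element; closing
seals comparably small holes. Border pixels use the clipped-element
convention (the same convention as MATLAB's `imerode`/`imdilate` and
EBImage).

The final image FF modifies F only under unanimity: where MFF and all
eight of its 3×3 neighbors are 1 the pixel is taken from A, where all
are 0 from B, otherwise F stands. Together with stage 1 this preserves
the selection-closure invariant — every FF pixel is a verbatim A or B
pixel — and the identity fixed point: fusing an image with itself
returns it exactly.

## Color path

Color (SPECT-like) inputs are handled in YUV. We use the full-range
BT.601 analog transform (Y = 0.299R + 0.587G + 0.114B,
U = 0.492(B−Y), V = 0.877(R−Y)); the standard is not pinned by the
method description, and BT.601 is the canonical definition of "YUV".
Only luminance is fused; chrominance passes through from the single
color source, or — when both sources are color — is selected per pixel
according to which source supplied the final luminance pixel, which
keeps selection closure. The float round trip RGB→YUV→RGB is exact to
1e−6 after final clipping.

## Synthetic training data and phantoms

The corpus the classifier needs — patch pairs where exactly one member
is information-rich — is generated, not downloaded. Each pair cuts the
same window from a 1/f^1.5 spectral-synthesis texture and from a
Gaussian-blurred copy (σ ~ Uniform[2, 4]); the sharp member sits in
slot A with probability ½ (label 1), classes balanced to within one.
Blurring strictly reduces patch variance, so ground truth is
unambiguous. An 80/20 split by pair gives a held-out accuracy estimate;
with 500 pairs and the default architecture, held-out accuracy is
essentially perfect.

The evaluation phantom emulates complementary modalities: image A
carries a bright, finely textured skeletal ring plus thin line spokes,
image B smooth textured soft-tissue blobs confined to the inner disk;
the ground-truth masks of where each modality is informative are
disjoint by construction and cover every pixel where the images differ
appreciably.

What the generator does *not* emulate: imaging physics (beam hardening,
partial-volume effects, Rician noise), anatomy, intensity
non-uniformity, or mis-registration. Passing the recovery checks
therefore demonstrates that the pipeline's decision machinery works
when "informative" coincides with "locally sharper and more
structured" — the same premise the patch-labeling protocol encodes —
not that the method is clinically validated.

## Quality metrics

Four standard measures, computed on luminance for color images:

* **Q_SF** — spatial frequency of the fused image on the 0–255 scale:
  the root of summed squared horizontal and vertical neighbor
  differences. Higher = sharper; natural-image content lands in the
  tens.
* **Q_Piella** — the weighted quality index Q_W (not the edge variant):
  universal quality index Q0 per sliding 8×8 window between F and each
  source, mixed by relative source variance and averaged with
  saliency-proportional weights. Windows with a vanishing Q0
  denominator contribute 1 when the window pair is identical and are
  skipped (and counted in a message) otherwise. 1 is perfect.
* **Q_MI** — entropy-normalized mutual information on 256-bin joint
  histograms, `2·(I(A;F)/(H(A)+H(F)) + I(B;F)/(H(B)+H(F)))`, bits,
  0·log 0 = 0; bounded [0, 2]; an identical non-constant triple scores
  exactly 2. A zero-entropy pair makes its normalized term 1 when
  identical, else 0. The plug-in estimator has a small positive bias on
  independent images (~0.1 on a 256×256 shuffle), which is a property
  of the estimator, not an implementation defect.
* **Q_CV** — perceptual distortion, lower is better: residuals A−F and
  B−F (0–255 scale) are filtered by the Mannos–Sakrison contrast
  sensitivity function H(ρ) = 2.6(0.0192 + 0.114ρ)exp(−(0.114ρ)^1.1)
  with the digital Nyquist frequency mapped to 30 cycles/degree
  (configurable viewing constant), then mean squared per 16×16 region
  and combined with gradient-energy saliency weights.

The perfect-fusion fixed points (Q_Piella = 1, Q_MI = 2, Q_CV = 0 for
f = a = b; Q_SF = 0 for a constant image) hold exactly and are part of
the test suite.

## Numerical conventions

* images are float in [0, 1] internally; 8-bit I/O quantizes by
  `round(v·255)`, so a write/read round trip moves a pixel by at most
  1/255;
* all windowed operations replicate-pad at borders;
* score ≥ threshold counts as label 1; r1 > r2 (strict) sets MF = 1;
* odd pooling inputs drop the trailing row/column (floor semantics);
* degenerate inputs fail loudly: non-finite training data, single-class
  corpora, all-windows-degenerate metric inputs and zero-saliency
  Q_CV inputs are errors, not silent NaNs.

## Problem sizes in the checks

The test suite and the acceptance script run at desk scale, chosen so
the full suite completes in well under a minute: oracle comparisons on
≤ 16×16 rasters (100 seeded cases per operation), ridge instances up to
200×512, training at 500 pairs under the default architecture,
phantoms at 64–128 pixels, and whole-image identity checks at 256×256.

## Known limitations

* The selective (copy-one-source) paradigm cannot average away noise;
  a noisy input pixel survives verbatim.
* Decision quality rests entirely on the synthetic sharp-vs-blurred
  premise; modalities whose informativeness is not expressed as local
  structure (e.g. uniform but diagnostic intensity shifts) will not be
  prioritized correctly without a corpus that encodes that notion.
* Inputs must be co-registered and the same size; no registration is
  attempted.
* Single 2-D 8/16-bit images only: no DICOM/NIfTI ingestion, no 3-D
  volumes, no more-than-two-source fusion.
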