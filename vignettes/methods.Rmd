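---
title: "Methods: whole-cell segmentation and classification of single-cell cytology images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-cell segmentation and classification of single-cell cytology images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(deepcyto)
```

## The problem

Papanicolaou (Pap) smear screening examines stained cervical cells under the
microscope for precancerous changes. Two computational tasks dominate
automated analysis of single-cell crops: *whole-cell segmentation* — a binary
labelling of pixels as cell (cytoplasm plus nucleus) versus background — and
*cell-type classification*, which assigns each cell to a diagnostic category.
The morphology that drives the labels is classical cytology: abnormal cells
show an elevated nucleus-to-cytoplasm (N/C) area ratio, together with changes
in shape, size and texture.

`deepcyto` implements both stages and the machinery connecting them: a U-Net
segmenter with optional dilated encoder convolutions and group normalization,
region-of-interest (ROI) extraction by mask–image multiplication, a residual
DCGAN image augmentor scored by the Fréchet distance, three classifier
families (single backbone, 7-member majority voting, 8-backbone feature
concatenation), pixel- and label-level metric suites, and six named pipelines
that wire the stages together. Because no deep-learning framework is
available to R in this stack, the package carries its own compact CNN engine:
convolution (stride, dilation, asymmetric padding), max pooling,
nearest-neighbour upsampling, transposed convolution, group/batch
normalization, spatial dropout and Adam, with forward and backward passes
validated against finite differences in the test suite.

## The segmentation model

The segmenter is a standard encoder–decoder U-Net: each encoder block applies
two 3×3 convolutions, each followed by a normalization layer and ReLU, then
2×2 max pooling; the decoder mirrors the encoder, doubling spatial resolution
and concatenating the matching encoder feature map before each conv block.
A 1×1 convolution with a sigmoid produces the per-pixel cell probability.

Two printed parameter totals pin the exact schedule. A batch-norm U-Net with
total 31,466,753 parameters of which 12,032 are non-trainable implies that
the summed normalized channel count is 12,032/2 = 6,016 (batch norm keeps two
running statistics per channel), and `reconcile_architecture()` searches a
grid of depths, base filters, upsampling types and normalization placements
for a schedule matching all three totals exactly. Exactly one candidate
matches: **depth 5, base 32 filters (bottleneck 1024), biased convolutions,
per-conv normalization, parameter-free nearest-neighbour upsampling in the
decoder** (no learned up-convolution), and a 1×1 output head. The widely
used 4-level, base-64 schedule with learned upsampling does *not* match
(its normalized channel sum is 5,888). Swapping batch for group
normalization moves the 12,032 running statistics out of the model and
changes nothing else — total 31,454,721, all trainable — which is precisely
the improved variant's accounting. The improved variant additionally sets a
dilation rate of 2 on every encoder convolution ('same' padding); dilation
enlarges the receptive field and adds no parameters, an invariance the test
suite asserts.

Unstated details are fixed as follows and exposed in `seg_model_config()`:
ReLU activations (sigmoid output); group count 32, clamped to the channel
count where smaller; spatial dropout 0.5 in the deepest encoder block and the
final decoder block; encoder-only dilation. Training follows
`train_config()`: Adam at learning rate 0.003, batch size 18, Jaccard
distance loss `1 − (I + s)/(U + s)` (smoothing `s = 100`, batch-pooled), up
to 100 epochs with early stopping on validation loss (patience 5,
best-weight restoration).

## Augmentation

The augmentor is a DCGAN variant with residual blocks in the generator. A
latent vector (default length 128) is projected to a 6×6 spatial seed and
mapped through four up-sampling stages with filters decreasing 512→64 to a
96×96×3 image; each stage is a 2× nearest-neighbour upsample plus 3×3
convolution (group norm, ReLU) followed by a residual block of two 3×3
convolutions with an identity skip. We chose upsample-plus-convolution
rather than stride-2 transposed convolution for the generator's upsampling:
it plays the same architectural role with the same parameter count order,
avoids checkerboard artifacts, and reuses the same audited kernels; the
segmenter still offers transposed convolution as a config option. The
output is mapped to [0,1] through a rescaled tanh. The discriminator is
exactly five stride-2 3×3 convolutions with filters increasing 32→512,
leaky ReLU, and a single sigmoid unit. Losses are non-saturating binary
cross-entropy with one-sided label smoothing (real targets 0.9), Adam
(2e-4, β₁ = 0.5) — conventional DCGAN settings, since none are printed for
this family. One generator is trained per class, so generated images carry
their class label by construction.

Generated image quality is scored by the Fréchet distance between Gaussian
fits of feature embeddings, `||μr − μf||² + Tr(Σr + Σf − 2(ΣrΣf)^{1/2})`,
with the matrix square root computed on the symmetrized product
`Σr^{1/2} Σf Σr^{1/2}` (eigendecomposition, small diagonal jitter, negative
eigenvalues clamped). The embedding is pluggable; the default is a fixed,
seeded random projection of 8×8 block-averaged pixels. A learned
inception-style embedding would weight perceptual structure differently, but
the Fréchet formula and all its metric properties (symmetry, non-negativity,
zero on identical sets, the univariate closed form `(μr−μf)² + (σr−σf)²`)
are embedding-agnostic, which is what the tests assert.

## Splits and augmentation placement

Real data are split 64/16/20 into train/validation/test; generated data are
split 80/20 into train/validation and never receive a test partition. Test
and validation sizes are rounded half-up and training takes the remainder,
which reproduces the 84-item and 810-item test sets implied by cohorts of
419 and 4,049 samples. Splits are stratified by class (largest-remainder
apportionment, proportions preserved within one sample per class) — class
structure in the per-class augmentation counts makes class-aware handling
the natural default, and it is exposed as a flag. Augmentation placed
*before* segmentation mixes generated train/val into both the segmentation
and the downstream classification training sets (the `RES_DCGAN_Nor` and
`RES_DCGAN_ROI` pipelines); placed *after* segmentation it reaches only the
classification sets (`Nor_RES_DCGAN`, `ROI_RES_DCGAN`). The invariant asserted at every mixing step and
at the orchestration level: generated images never enter a test split, and
GAN training only ever sees real train+validation images.

Where a segmenter must be trained on generated images (before-placement),
those images have no ground-truth masks; they receive automatic pseudo-masks
from `threshold_mask_from_image()` (modal-luminance thresholding, largest
connected component, hole filling), flagged `pseudo_mask` in their metadata.
This is an explicit stand-in for information the original procedure leaves
unspecified.

## Classification

All classifiers consume 224×224 (configurable) RGB inputs — original images
for the "Normal" pipelines, mask×image ROI products for the ROI pipelines.
The single-backbone path is a backbone plus global average pooling and a
softmax layer; only that final layer changes with the class count. The
voting ensemble trains seven independently seeded single-backbone
classifiers (ResNet50V2, VGG19, VGG16, Xception, DenseNet121,
EfficientNetB2, MobileNetV2) and combines test predictions by majority vote;
ties (possible with 7 voters on ≥3 classes) resolve to the smallest class
index, a deterministic rule the enumeration tests pin down. The
concatenation ensemble extracts features from eight frozen backbones (the
seven above plus InceptionV3), flattens them literally (no pooling),
concatenates, and trains a dense 256 → batch-norm → dropout 0.5 → dense 64 →
softmax head with Adam and categorical cross-entropy (batch 32, early
stopping); normalization sits after the 256-unit layer only.

Offline, backbone names map to registered tiny stand-in CNNs (3×3 stride-2
conv stacks of per-family depth/width) with frozen, seeded random weights.
Pretrained ImageNet weights are an optional enhancement, never a test
dependency: the package's claims about ensemble mechanics — frozen-weight
contracts, feature concatenation arithmetic, vote aggregation — are
independent of where the features come from. Frozen features are
standardized (train-set mean/sd, stored with the model) before the head;
with random-projection features this is what makes the logistic head's
optimization well-conditioned.

## Synthetic phantoms

Every stage is testable without external data via the phantom generator:
one rotated elliptical cytoplasm per frame with an interior elliptical
nucleus, painted background/cytoplasm/nucleus from a Pap-stain-like palette,
Gaussian-blurred and noised. The class label drives the N/C area ratio:
the nucleus area is an exact fraction of the cell area (drawn from the
class interval, shrunk 15% per side so pixelation cannot cross the interval
edge), so a threshold on the *measured* pixel-count ratio separates classes
perfectly — the property that guarantees segmenters and classifiers have
learnable signal. Defaults: 96 px frames, cytoplasm semi-axis 0.24–0.40 of
the frame, normal N/C ∈ (0.05, 0.15), abnormal N/C ∈ (0.50, 0.70)
(cytology-realistic: normal superficial/intermediate cells have small
nuclei; high-grade lesions approach N/C > 0.5), noise sd 0.03, blur σ 0.8.
What the phantoms deliberately do not model: stain variability, overlapping
cells, debris, texture — so passing the desk-scale tests demonstrates that
the machinery is correct and the architectures can learn a real
morphological signal, not that real-data accuracies transfer.

## Pipelines

Six pipelines wire the stages: `Normal` (segment, classify originals),
`Nor_RES_DCGAN` (augment classification inputs), `ROI` (classify mask
products), `ROI_RES_DCGAN` (augment ROI classification), `RES_DCGAN_Nor`
(augment segmentation training with pseudo-masked generated images, then
classify), `RES_DCGAN_ROI` (same segmentation stage, classify ROI).
What "the segmentation output used directly" feeds the Normal classifier is
genuinely ambiguous; we default to the original resized images — ROI is
explicitly defined as the mask product, so the Normal/ROI contrast is only
meaningful if Normal is the unmasked input — and expose
`normal_input ∈ {original, predicted_mask, overlay}`. Pipelines sharing a
segmentation stage and seed reuse the cached trained segmenter, so their
segmentation rows are identical by construction and the comparison table
reports one representative score per shared stage. Every run report carries
provenance (seeds, configs, split sizes, a dataset checksum) sufficient to
reproduce it.

## Numerical choices and problem sizes

All arithmetic is double precision. Convolutions use im2col plus BLAS
matrix multiplication; 'same' padding follows the ceil convention with the
extra pixel at the bottom/right. Normalization uses ε = 1e-5 and biased
variance; batch-norm running statistics use momentum 0.9. Weight
initialization is He-normal throughout. The Jaccard loss gradient is exact
(no surrogate). Degenerate metric ratios (zero denominators) report 1 when
the corresponding error count is zero, else 0, so perfect-empty cases never
produce NaN.

The test suite and the acceptance script run entirely on CPU at desk scale,
sizes chosen so each stage demonstrably learns while a full run stays
comfortable on one core: segmentation learnability uses 200 phantoms at
64 px with a base-8 improved U-Net for at most 10 epochs (held-out Dice
≥ 0.90 is typically reached within 2 epochs); the small-batch-stability
comparison retrains the same model at batch size 2; the concatenation
ensemble uses 400 phantoms at 32 px; the adversarial run uses 200 phantoms
at 32 px for 300 steps. Parameter accounting, reconciliation, metrics,
splits and Fréchet checks are exact and effectively instant.

## Known limitations

Single-cell crops only (one cell per frame is baked into the phantom model
and the pipelines); no patient-level grouping in splits; no multi-class
semantic masks (nucleus vs cytoplasm); the default Fréchet embedding is
random-projection rather than a learned perceptual embedding; stand-in
backbones share only the interface, not the capacity, of their namesakes;
and desk-scale results on separable phantoms say nothing quantitative about
real stained-cell datasets.
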