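---
title: "Synthetic learning for neonatal brain MRI segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic learning for neonatal brain MRI segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neosynth)
```

## The problem

Segmenting neonatal brain MRI is hard for two compounding reasons: the
brain changes shape dramatically between 26 and 45 weeks postconception
(cortical folding develops over this window), and tissue contrast changes
with myelination, so the same tissue can be dark or bright depending on
age and sequence. A supervised network trained on real T2-weighted images
learns the intensity statistics of its training domain and fails on any
other contrast.

*Synthetic learning* sidesteps the domain entirely: the training set is
generated from label maps alone. Each training volume is rendered by
giving every tissue a randomly drawn Gaussian intensity distribution, so
over many samples the network sees every possible contrast and can only
learn the correspondence between label geometry and *relative* intensity
structure. `neosynth` implements this generative model, two enrichments
that matter specifically for neonates (k-space motion artifacts and
white-matter intensity subdivision), the surface-derived ground-truth
construction, a 3D UNet training harness, and the evaluation protocols —
all testable end to end on self-generated phantoms.

## The generative model

A training sample is produced from a label map by a fixed chain of
transforms, each with documented parameter distributions:

1. **Optional WM subdivision** (probability 0.5 in the `SynthInh` /
   `SynthMotInh` recipes). A 1D Gaussian mixture with `N` components
   (`N` drawn from 2–6) is fitted by EM to the reference-image
   intensities inside the WM mask; each WM voxel is reassigned to its
   maximum-responsibility component. Each sub-region then renders as a
   distinct tissue, emulating myelination-related WM inhomogeneity.
   The subdivision is a fixed relabelling per subject (cached), and the
   *target* labels always regroup the sub-labels to a single WM class.
2. **Spatial augmentation.** A random affine (per-axis scaling
   U[0.9, 1.1], rotations U[−20°, 20°], translations U[−10, 10] mm)
   followed by a free-form elastic deformation (12³ control points, each
   displacement component U[−8, 8] mm, densified with clamped cubic
   B-splines). Label maps are warped with nearest-neighbour
   interpolation; images (for the real-data baseline) with trilinear.
3. **Random contrast.** Each label's intensity is drawn i.i.d. from
   `Normal(mean_l, sd_l)` with `mean_l ~ U[0, 1]` and
   `sd_l ~ U[0.02, 0.1]`, one contrast sample per volume.
4. **Bias field.** Multiplication by `exp(P(x))`, `P` an order-3
   polynomial over coordinates normalized to `[−1, 1]³` with
   coefficients U[−0.5, 0.5]. The exponential form keeps the field
   positive; the prose description of the transform fixes only the order
   and magnitude, so the standard exponential-polynomial semantics of
   the reference implementations is used.
5. **Noise.** Additive Gaussian noise, zero mean, sd U[5e−3, 0.1].
6. **Motion** (probability 0.5 in `SynthMot` / `SynthMotInh`). See
   below.
7. **Normalization.** Min–max rescaling to exactly [0, 1]. Constant
   images map to zeros with a warning — a degenerate case that cannot
   occur with the sampled noise floors but keeps the pipeline total.

The `DataT2` baseline replaces steps 1, 3 and 6 with the subject's real
(here: reference-rendered) image, and appends a gamma perturbation
`x^exp(g)`, `g ~ U[−0.3, 0.3]` in log space — the range is a design
choice ("slight variations" is all the description fixes).

### Motion simulation

MRI is acquired line by line in k-space; if the head moves between
lines, the assembled spectrum mixes inconsistent object states, which
appears as ghosting and intra-tissue inhomogeneity. The simulator
models a single sudden movement: the trajectory is identity until a
uniformly drawn event segment, ramps smoothly (smoothstep) over a few
segments, and plateaus at a rigid transform whose translation norm and
rotation norm equal the sampled maxima (both U[3, 8], mm and degrees).
For each k-space segment (by default one per phase-encode line,
sequentially ordered; centric ordering is available) the object is
rigidly transformed — rotations by trilinear resampling in image space,
translations exactly as linear phase ramps — and the segment's lines are
taken from that state's spectrum. The magnitude of the inverse FFT is
returned, with the background forced to zero beforehand so that air
does not mix into the object.

Two properties pin the implementation down numerically: a constant
integer-voxel translation reproduces the array-shifted image to within
FFT round-off, and any pure-translation trajectory conserves total
image energy exactly (phase ramps are unitary), both of which are
asserted in the test suite. The single-event trajectory shape is an
assumption — the amplitude ranges are specified, the time-course model
is not — and is recorded as a configurable default (`event`, `ramp`).

## Ground truth from cortical surfaces

Volumetric neonatal segmentations tend to over-segment cortical GM. The
alternative ground truth starts from the inner (white) and outer (pial)
cortical boundaries, here represented as signed-distance volumes
(negative inside). The GM partial-volume fraction of a voxel is
estimated by counting `supersample³` sub-voxel centres falling between
the surfaces (trilinearly interpolated signed distances), then
binarized at 0.5 (closed threshold, deterministic at exact ties).
Fusion into an existing label map preserves every structure except
GM/WM/CSF: voxels that lose GM are reassigned to the nearer of WM or
CSF by exact Euclidean distance transform (ties to WM), voxels that
gain GM may only overwrite WM or CSF. The reassignment rule is our
reading of "propagating the adjacent labels"; no algorithm is specified
for it, and nearest-mask assignment is the simplest rule consistent
with only WM/GM/CSF differing between the two ground truths.

On a spherical-shell phantom the sub-voxel counting reproduces the
analytic shell volume to within 2% at `supersample = 4`, which is the
package default.

## Phantoms

No real data ships with the package; every stage is exercised on
seeded, neonatal-like phantoms: nested head / CSF / cortical GM shell /
WM spheres with deep structures (paired ventricles, deep GM,
hippocampus+amygdala, cerebellum, brainstem) placed as disjoint
ellipsoids in the WM interior. A `folding` parameter in [0, 1] — the
stand-in for gestational age, mapped linearly to 26–45 weeks — controls
a sinusoidal radial perturbation of the cortical shell (amplitude up to
2.5 mm and angular frequency 3–10, jointly scaled), chosen because it
is smooth, analytic, trivially seedable, and monotonically increases
the GM/WM interface area. The default grid is 64³ at 1 mm (48³ or 32³
for the training experiments); voxel geometry is carried everywhere so
mm-denominated parameters stay meaningful.

Paired ground-truth variants emulate annotation bias: the `tight`
variant thresholds the surface partial volume directly; the `large`
variant first displaces the outer boundary outward and the inner inward
by `bias_mm`. `calibrate_gt_bias()` finds, per phantom, the
displacement reproducing a 25% GM volume excess (ratio 1.25), the
magnitude reported for volumetric-vs-surface neonatal ground truths.
For these phantom radii that calibrated displacement is ≈ 0.35–0.4 mm —
sub-voxel, which is exactly why partial-volume counting rather than
voxel indicator functions is used throughout.

What the phantoms do *not* emulate: real cortical folding topology
(the perturbation is a single-valued radial function), partial-volume
mixtures in the rendered images beyond label granularity, anatomically
realistic deep-structure shapes, and any real scanner artifact
statistics. Tests passing on phantoms therefore validate the
*machinery* (transforms, losses, metrics, training mechanics) and the
*relative* behaviour of the recipes, not clinical accuracy.

## The network

The segmentation backbone is a 3D UNet: five resolution levels, three
3×3×3 convolutions per level, each followed by batch normalization,
ReLU and 10% dropout (the final 1×1×1 classifier only by a softmax),
24 feature maps in the first block, doubling after each 2×2×2
max-pooling and halving after each upsampling, with residual skip
connections inside the blocks.

The prose leaves several conventions open; they are explicit
configuration fields, and `unet_parameter_sweep()` enumerates them
against the published size of 21.6 million trainable parameters. The
frozen default — channel-preserving 2³ transposed-convolution
upsampling, concatenation with the encoder skip, three convolutions,
residual shortcuts with 1×1×1 projections on the (channel-changing)
decoder blocks and identity shortcuts over the constant-width tail of
the encoder blocks, batch-norm parameters counted — instantiates
21,586,858 ≈ 21.59 M parameters, the sweep's closest match to the
printed figure (nearest alternatives: 21.69 M with projections
everywhere, 21.44 M with none). The class count (9, 10 or 19) moves the
total by < 0.001 M either way; the package default is 10 classes (nine
tissue classes with all extra-cerebral tissue collapsed to `head`, plus
air background).

Training follows the published settings as defaults: 128³ patches,
eight structure-balanced patches per generated volume (a structure is
drawn uniformly among those present, then a centre voxel uniformly
within it), batch size 4, Adam at 1e−4, average soft dice loss
`1 − 2Σpy / (Σp² + Σy²)` per class, mean over classes, with an empty
class (in both prediction and target) contributing zero to avoid 0/0.
Batch statistics for the normalization layers are computed per volume
during training. At inference the default (`bn_eval = "running"`) uses
the training-time running averages, so full-volume prediction is
deterministic and fully convolutional (verified by the patch-vs-volume
consistency test). For contrast-agnostic models a second mode
(`bn_eval = "input"`) normalizes with the statistics of the volume
being predicted: a network trained on random contrasts has running
averages that correspond to no contrast in particular, and normalizing
an arbitrary unseen contrast with them shifts every layer's activation
distribution; input statistics remove that mismatch (and measurably
improve the toy models' cross-contrast dice). Both modes are
deterministic; the toy experiments use `"input"`. Training determinism
is promised single-threaded under a fixed seed.

### Desk-scale experiment settings

The three experiment replications run at toy scale, chosen so the full
suite trains in minutes on one CPU: 32³ phantoms at 1 mm with 2 mm
cortex, a 3-level UNet with 1 convolution per level, 8 base features
and no dropout, input-statistics normalization at inference, 24³
patches, batch 2, a few hundred Adam iterations at 3e−3 (optionally
decaying exponentially to 3e−4 — at small iteration budgets the
gradient noise of random-contrast training otherwise dominates the
endpoint), and 3 training with 3–4 test phantoms on disjoint seed
ranges (asserted before every run). In the ground-truth-bias
experiment the tight- and large-trained member of each model pair is
trained with the *same* seed, so the two runs see identical
augmentation and contrast streams and differ only in their target
labels — a matched-pairs design that isolates the ground-truth effect
from training stochasticity. These sizes are the package's choice of a
reproducible, laptop-friendly configuration; the published full-scale
settings remain the documented defaults of `unet_config()` and
`train_config()`.

## Evaluation

Per structure: binary dice `2|X∩Y|/(|X|+|Y|)` (both-empty = 1,
one-empty = 0 — the standard convention, never triggered on phantoms),
symmetric average surface distance (pooled mean over both boundaries'
6-connectivity surface voxels of the exact Euclidean distance to the
other boundary; the directionality of the published variant is
unstated, so the symmetric pooled form is used and documented), and
structure volume. CSF and ventricles are merged before evaluation.
Dice is kept in [0, 1] internally; the 0–100 scale of published tables
is a presentation choice applied only at report time. Age-binned
summaries use bins [26, 32), [32, 36), [36, 40), [40, 45] (closed-left,
last closed). Outliers are subjects whose structure-averaged dice
deviates from the cohort mean by more than 3 SD — the flagging rule is
ours; only the practice of inspecting such cases is described in the
source material for the protocol. Cross-contrast consistency uses the
Pearson correlation and regression slope of per-subject structure
volumes predicted from two contrasts, and between-model consistency is
the dice between two models' predictions with no ground truth involved.

## Numerical choices and degenerate inputs

* Min–max normalization of a constant image returns zeros with a
  warning rather than failing.
* Gaussian render values are not clipped; normalization rescales them.
* EM: k-means initialization from intensity quantiles, convergence at
  relative log-likelihood change < 1e−6 or 200 iterations,
  responsibility ties to the lower-mean component — all for
  determinism. Fewer distinct intensities than clusters reduces the
  cluster count with a warning.
* Elastic densification uses *clamped* cubic B-splines so the basis
  keeps partition of unity at the volume borders and the field is
  bounded by the control values — the property the displacement-bound
  test relies on.
* Out-of-field voxels fill with the background label / zero intensity;
  rotation centres are the volume centre in world coordinates.
* The distance transform uses a large finite sentinel internally
  (exact-arithmetic parabola intersections are undefined at infinity)
  and reports `Inf` only for all-empty masks.
* "12 control points" is read as per axis; one contrast sample is
  drawn per generated volume, not per patch. Both are assumptions,
  recorded here.

## Known limitations

* Phantom anatomy is radially star-shaped; predictions that exploit
  this symmetry would not transfer to real cortices.
* The motion simulator is single-coil, 3D-encoded, single-event; no
  partial Fourier, parallel imaging, or multislice through-plane
  motion.
* The toy networks are far below the published capacity and training
  length; their absolute dice values are not comparable to full-scale
  results, only the relative patterns across recipes are meaningful.
  One consequence, measured by the acceptance suite: the
  contrast-robustness pattern (synthesis training generalizes across
  contrasts, real-image training does not) reproduces at toy scale,
  but the ground-truth-bias consistency pattern does not fully — the
  between-model consistency of an undertrained synthesis pair is
  dominated by training noise rather than by the annotation bias, so
  it falls below the real-image pair instead of above it. That
  ordering only emerges once the synthesis models approach
  convergence, which is outside a desk-scale compute budget.
* Batch normalization uses per-volume statistics (batch size 1
  semantics) during training.
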