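---
title: "Grading stem-borer infestation from hyperspectral cubes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading stem-borer infestation from hyperspectral cubes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemborer)
```

## The problem

Striped stem-borer (*Chilo suppressalis*) larvae bore into the rice stalk
and feed inside the stem wall, so the stalk's optical properties change well
before canopy symptoms are visible. `stemborer` implements the standard
visible/near-infrared hyperspectral-imaging workflow for grading that damage
into six ordinal degrees of infestation (DI0 = healthy; DI1--DI5 = infested
for 2, 4, ..., 10 days): each sample is one hyperspectral cube (two spatial
axes x 512 bands over 380--1030 nm) of a stalk, and the model predicts its
DI class.

The workflow combines two complementary information channels:

* **spectral** — the mean reflectance spectrum of the stalk region of
  interest (ROI), which tracks pigment loss in the visible range and
  structural/water changes in the near infrared; and
* **textural** — gray-level co-occurrence (GLCM) statistics of the first two
  principal-component score images of the cube, which track the spatial
  pattern of surface damage.

Because stalk-level hyperspectral datasets of this kind are not publicly
deposited, the package ships a synthetic scene generator that emulates the
documented six-class structure, so every stage of the pipeline is exercised
and tested end to end on data with known ground truth.

## Pipeline stages

### Reflectance calibration

Raw counts are converted to relative reflectance with the flat-field
formula `R = (raw - dark) / (white - dark)`, where `dark` is the
closed-shutter reference and `white` a ~99.9 % reflectance panel, both
single line-scan frames broadcast along the scan axis. Two numerical
conventions apply: cells with `white == dark` (dead pixels) are set to 0 and
counted in a warning rather than becoming `NaN`, and reflectance is clipped
to [0, 1.5] so occasional specular pixels cannot destabilize the min--max
gray-level quantization used later.

### Band trimming and smoothing

The band edges of the detector carry most of its noise; the first 82 and
last 22 of the 512 bands are dropped by default, leaving 408 bands spanning
roughly 480--1000 nm. Spectra are then smoothed by Savitzky--Golay local
polynomial regression (default window 9 bands, order 3, configurable). The
implementation uses `signal::sgolayfilt`, whose first and last half-windows
are completed from the polynomial fitted to the nearest full window — no
reflection padding — so polynomials up to the configured order are
reproduced exactly everywhere, which the tests assert.

### Kennard--Stone partitioning

Samples are split 2:1 into calibration and prediction sets with the
deterministic Kennard--Stone maximin procedure on the smoothed, trimmed
spectra (the representation available at split time): the first two picks
are the farthest pair, each later pick maximizes its minimum distance to
the already-picked set, ties break to the lowest sample index. 365 samples
give 243 calibration and 122 prediction samples (`floor(2N/3)`).

### SPA wavelength selection

The successive projections algorithm reduces the 408 collinear bands to a
small panel of characteristic wavelengths. Phase 1 builds one candidate
chain per starting band: at each step every remaining band is projected
onto the orthogonal complement of the span of the bands already chosen
(maintained by Gram--Schmidt deflation, which is equivalent to the explicit
projector and is verified against one in the tests), and the band with the
largest projected norm joins the chain. Phase 2 fits an ordinary
least-squares model on every chain prefix of every candidate size and
scores it by RMSE on the validation set; the global minimizer wins, with
ties going to the smaller subset and then the earlier chain.

Two open choices were resolved as follows. The regression response is the
numeric DI index 0--5, matching the ordinal severity structure; and the
validation set reuses the Kennard--Stone prediction set, since no separate
internal validation split is defined at this stage. Mean-centering before
the projections is available (`center =`) but off by default. The pipeline
default evaluates subset size 17 — the canonical panel size for this task —
while `spa_sizes = 1:30` gives the free minimum-RMSE sweep.

### GLCM texture features

For each cube, PCA is fitted to the cube's own ROI pixel spectra (the
per-image workflow; a global model can be supplied instead) and the pixel
scores on the first two loadings form the PC1/PC2 score images. Loading
signs are fixed so the largest-magnitude element is positive, making score
images reproducible. Each score image is cropped to the ROI bounding box,
min--max quantized into 64 gray levels, and pair-counted into GLCMs at
distance 1 for the four canonical directions {0°, 45°, 90°, 135°}, with
symmetric counting and off-ROI pairs excluded. Eight descriptors — mean,
variance, homogeneity, contrast, dissimilarity, entropy (natural log by
default), second moment, correlation — are computed per direction and
averaged, giving 8 values per PC image and the 16-feature texture vector.
For a constant image the pair distribution is degenerate and perfectly
predictable, so correlation is defined as 1 there. These GLCM defaults
(D = 1, four averaged angles, 64 levels, symmetric) are standard Haralick
practice; none are fixed by the problem, and all are configurable.

A note on invariances: with symmetric counting, transposing the image swaps
the 0° and 90° offsets while each diagonal offset maps to its own reverse,
so 45° and 135° descriptors are individually invariant. The angle-averaged
texture vector is therefore transposition-invariant as a whole.

### Normalization and fusion

Every feature block is min--max normalized against the calibration rows
only, and prediction-set values may legitimately leave [0, 1].
Feature-level fusion concatenates the normalized characteristic-wavelength
block (17 features by default) with the normalized texture block (16
features) into the fused 33-feature table; these heterogeneous blocks are
scaled per feature. The full-spectra block is the one exception: its 408
bands share a single physical unit, and per-band scaling blows
low-information bands — whose calibration range is essentially noise — up
to full amplitude, visibly degrading the 408-input network. That block
therefore subtracts each band's calibration minimum but divides by the one
largest band range (`minmax_normalize(..., shared_scale = TRUE)`). A single
global (min, max) for the whole block was also evaluated and rejected:
class information of ~0.02 reflectance against a ~0.6 global range reaches
the classifier badly scaled.

### BPNN classifier

The classifier is a from-scratch one-hidden-layer feed-forward network:
logistic activations on hidden and output layers, one-hot targets over the
six classes, squared-error loss. The operating point is 5 hidden nodes,
learning rate 0.6, target epoch error 1e-5, and at most 1000 epochs;
prediction takes the arg-max output node.

Two training choices deserve explanation because both alternatives were
implemented and measured:

* **Per-pattern updates.** Weights are updated after each sample, visiting
  samples in their fixed input order (deterministic). Batch-averaged
  gradient descent at this learning rate and epoch budget stalls — the
  epoch error plateaus around 0.2 and the network degenerates to a
  near-constant class — while sequential back-propagation reaches errors an
  order of magnitude lower on the same data. This matches the classic
  formulation of back-propagation, in which the error is propagated per
  presented pattern.
* **Fan-in-scaled initialization.** Weights start uniform in
  [-0.5, 0.5] / sqrt(fan-in), biases uniform in [-0.5, 0.5], from the
  configured seed. Without the scaling, the hidden-layer net input grows
  with the square root of the feature count and the logistic units
  saturate; the 408-input full-spectra model is visibly crippled (epoch
  error stuck high, prediction accuracy collapsing) while 17-input models
  are unaffected.

* **Deterministic multi-start.** Roughly one initial draw in five converges
  to a visibly poor stationary point (final epoch error an order of
  magnitude above the others, and prediction accuracy degraded to match).
  `bpnn_train()` therefore trains up to `restarts` times (default 3) from
  seeds derived from the configured one, accepts immediately once the final
  epoch error is at or below `restart_tol` (default 1e-3), and otherwise
  keeps the net with the lowest final *training* error — model selection
  never sees the prediction set.

The epoch-loss gradient implementation is verified against central finite
differences to below 1e-6 relative error.

### Evaluation

Confusion matrices are 6 x 6 with actual classes in rows; overall accuracy
is the trace over the total and per-class accuracy the diagonal over the
row sum, with empty classes reported as absent (`NA`), not 0. Percentages
print with two decimals, rounded half-up. `compare_feature_sets()` trains
one network per feature set — full spectra (408), characteristic
wavelengths (17), texture (16), fusion (33) — on the identical split and
seeds. The transcribed reference confusion tables for these four feature
sets ship as plain-text fixtures, and the test suite recomputes their
accuracy columns; the recomputed values are treated as authoritative where
a printed entry is internally inconsistent (the fusion table's prediction
total is 116/122 = 95.08 % but was printed as 95.10 %, and several of its
per-class calibration percentages do not match their own rows).

## The synthetic scene generator

`generate_scene()` builds one labeled cube per sample: raw counts, white
and dark reference frames in arbitrary detector units (so calibration is
genuinely exercised, not bypassed), an elongated meandering stalk ROI of
about 20 % of the 64 x 64 pixels, and the DI label. Under the default
configuration the dataset reproduces the documented sample allocation:
45/69/69/69/69/44 across DI0--DI5, 365 cubes in all.

The spectral model is a fixed analytic vegetation-like base curve (green
reflectance peak near 550 nm, sigmoid red edge near 720 nm rising to a NIR
plateau, mild 970 nm water dip) plus class offsets localized by
raised-cosine windows over 570--700 nm and 750--1000 nm. The offsets encode
the documented severity pattern, including the early-infestation
*compensation effect*: in the visible window reflectance rises with
severity for DI3--DI5 but dips below healthy for DI1/DI2, and the NIR
window mirrors this with opposite sign. Only this ordering/sign structure
is treated as meaningful; no attempt is made to match absolute reflectance
of any real instrument. The configuration validator enforces the sign
pattern.

The texture model multiplies each ROI pixel's spectrum by a lesion field:
thresholded smoothed Gaussian noise, with spots brighter in the red window
and darker in the NIR, plus a smooth overall brightness field. Severity
(`texture_scale`, per class) controls three things at once: lesion-spot
density, lesion amplitude, and spot granularity (the field's correlation
length shrinks with severity, i.e. damage fragments into finer spotting).
The granularity and density channels matter because per-image min--max
quantization deliberately discards absolute amplitude: amplitude-only
texture turned out to be nearly invisible to GLCM descriptors, which
contradicted the well-documented usefulness of texture for this grading
task. With morphology scaling, PC1 contrast rises monotonically with
`texture_scale` (a tested property). The healthy class keeps a small
nonzero texture scale (0.15): healthy stalks show natural surface
mottling, and a perfectly texture-free class would have near-zero
within-class variability — an artifact that, among other things, makes the
deterministic Kennard--Stone split allocate almost none of those samples to
calibration, something never observed with real samples.

Per-scene stochasticity comes from the pixel noise (`noise_sd`, default
0.01 reflectance units), the random lesion/brightness fields, a small
random lateral shift of the stalk axis, and a per-scene relative jitter of
the effective texture scale (`texture_jitter_sd`) representing biological
variability of lesion severity within a class. All randomness derives from
the configured seed; one seed reproduces every cube, split, model and
report bit for bit.

What the generator does **not** emulate: radiative transfer or plant
growth, instrument artifacts beyond white/dark references (no smile/keystone,
no wavelength miscalibration), specular highlights, pot/soil background
clutter, or realistic absolute reflectance levels. Passing end-to-end tests
on these scenes therefore demonstrates that the pipeline's machinery — not
any claim about real rice — behaves correctly and recovers known structure
under controlled conditions.

## Problem sizes used by the tests

Unit tests run on deliberately tiny objects (images up to 32 x 32, 48
bands, tens of samples) where brute-force oracles are affordable: explicit
projector SPA, double-loop GLCM, exhaustive Kennard--Stone, central finite
differences for the BPNN gradient. The end-to-end recovery check runs the
full default conditions — 365 samples of 64 x 64 x 512 — over five
generator seeds and requires the fused 33-feature model to reach >= 90 %
prediction accuracy with texture-only strictly below spectral-only on a
majority of seeds; it evaluates the characteristic-wavelength, texture and
fusion models, which are the three that ordering involves. The acceptance
script additionally trains the 408-input full-spectra model in its single
reported run.

## Known limitations

* The severity signal in the synthetic scenes is cleaner than real
  biology; spectral models can reach 100 % prediction accuracy at the
  default noise level, whereas real data plateaued in the low 90s with
  DI0/DI1 confusion. The generator's class overlap is concentrated in the
  texture channel.
* The 408-input full-spectra network remains the least stable model at the
  fixed operating point (5 hidden nodes, 1000 epochs): depending on the
  seed its prediction accuracy ranges from the 70s to 100 %, with the
  characteristic-wavelength model consistently at or near 100 % on the
  same spectra — one more argument for wavelength selection.
* SPA Phase 2 reuses the Kennard--Stone prediction set as its validation
  set, so the selected panel has seen the prediction distribution; with a
  deterministic split and an RMSE-only criterion the leakage is modest, but
  a three-way split would be cleaner.
* The 490-vs-408 band-count discrepancy in the original description of the
  working range (512 - 82 - 22 = 408) is resolved in favor of 408
  everywhere.
* Run-time comparisons between feature sets are logged informationally but
  never asserted; they are hardware-dependent.
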