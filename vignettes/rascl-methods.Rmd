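---
title: "Random slice contrastive learning for OCT B-scan classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random slice contrastive learning for OCT B-scan classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Full-thickness macular holes (FTMH) are foveal defects disrupting every
neurosensory retinal layer between the internal limiting membrane (ILM)
and the retinal pigment epithelium (RPE). They need timely surgical
repair, while the much more common epiretinal membranes (ERM) — fibrotic
surface plaques that can mimic hole-like anatomy — are often managed
conservatively. Distinguishing the two on macular OCT is therefore a
triage problem worth automating, but labeled clinical OCT datasets are
small (hundreds of eyes), which makes training a deep classifier from
scratch impractical and makes out-of-domain (ImageNet) pre-training a
poor source of features.

`rascl` implements an alternative: *random slice contrastive learning*.
A macular OCT acquisition is a stack of parallel B-scans a fixed distance
apart (243 or 121 µm in common protocols). Two B-scans from the same eye
a few slices apart show nearly the same anatomy; two B-scans from
unrelated eyes do not. That structure yields self-derived labels: an
encoder is pre-trained so that *neighboring slices of one eye* (up to
`max_offset = 2` slices away, drawn uniformly) embed close together
(positive pairs), while scans from different eyes embed far apart
(negative pairs). The pre-trained encoder is then frozen, and a small MLP
classifier is fine-tuned on the labeled eyes.

## The objective

Given `2N` projection vectors ordered so rows `2k-1, 2k` are a positive
pair, the normalized-temperature cross-entropy (NT-Xent) loss is

```
l(i, j) = -log[ exp(sim(z_i, z_j)/tau) / sum_{k != i} exp(sim(z_i, z_k)/tau) ]
```

with `sim` cosine similarity, averaged over both directions of all `N`
pairs. Projections are L2-normalized before similarity; the loss is
therefore invariant to positive rescaling of any single projection, to
permutation of pairs, and to swapping the two views within a pair. The
implementation (`nt_xent_loss`) is verified in the test suite against an
independently coded double-loop oracle and against closed forms
(`log(1 + 2/e)` for two orthogonal pairs at `tau = 1`; `log 3` when all
four projections coincide).

Design choices the method description leaves open, and what this package
does:

* **Temperature** `tau` defaults to 0.5 (the region SimCLR-style training
  is commonly run in); it is configuration, not a constant.
* **Boundary handling** for the pair sampler: near the volume edge the
  offset support `{a+d : 1 <= |d| <= D}` is clipped to in-bounds indices
  and renormalized to uniform. With 3-slice training stacks and `D = 2`
  clipping is unavoidable; rejection-resampling of the anchor is
  available as `boundary = "resample"`.
* **Offsets are uniform**, never Gaussian: the method deliberately
  spreads positive pairs over a slice neighborhood rather than
  concentrating them at the anchor.
* **One eye per patient per batch**, eyes drawn without replacement, so
  every cross-pair view in a batch truly is an unrelated eye.
* **Pre-training "accuracy"** (needed by the checkpoint criterion, below)
  is defined as top-1 positive-retrieval accuracy: the fraction of views
  whose nearest neighbor in projection space, among the other `2N - 1`
  views of a fixed validation batch, is their positive partner.

## Architecture and training protocol

The clinical-scale encoder is a standard-width ResNet-50 (2048-d pooled
features); the package also provides `small_cnn`, a four-block strided
conv net with global average pooling, so the full pipeline runs on one
CPU at desk scale. Both feed an MLP of three fully connected 512-unit
layers; the final layer is the projection head during pre-training, and
a fresh 2-way softmax layer on top of it becomes the classifier during
fine-tuning. Because no deep-learning framework is available in this R
stack, the package carries its own compact engine: im2col convolution
and pooling kernels in C++ (RcppArmadillo), dense layers and Adam in
base R, with every backward pass verified against finite differences in
the tests.

The training protocol follows the clinical study design:

1. **Replicate holdouts.** Three replicate test sets of 10 FTMH + 40
   control eyes (~15% of the cohort), pairwise disjoint, patient-grouped.
2. **Stratified 8-fold split** of each training set: diagnosis counts per
   fold within ±1 of proportionality (hard constraint); age, sex
   (ordinal) and pre-operative vision balanced by minimizing the summed
   per-fold `|Δmean|/SD + |ΔSD|/SD` via random-restart greedy pairwise
   swaps of patient groups (default 50 restarts × 500 swaps — the
   optimizer is this package's concretization; only the moment-matching
   goal is prescribed).
3. **Pre-training** (800 epochs at clinical scale, validated every 10)
   on the training eyes, anchors restricted to the three foveal B-scans
   per eye; the lowest-numbered fold is reserved as the pre-training
   validation set. The transferred checkpoint minimizes
   `val_loss / val_accuracy` (ties to the earliest epoch), treating
   zero-accuracy records as infinitely bad.
4. **Frozen-encoder fine-tuning** per fold with binary cross-entropy on
   up to three foveal B-scans per eye; the same `min(loss/accuracy)`
   criterion selects each member's epoch. A `trainable` encoder mode
   implements the transfer-learning baseline.
5. **Ensembling**: the 8 fold models are averaged with equal weights;
   a scan is called FTMH iff the mean FTMH softmax score is ≥ 0.5 (the
   boundary counts as positive).

The optimizer is Adam (lr 1e-3 pre-training, 1e-4 fine-tuning by
default, no schedule) — the protocol source states none, so these are
package defaults surfaced in configuration.

## The synthetic phantom

No clinical scans ship with the package; a layered-retina phantom stands
in for them. Each eye draws smooth ILM/inner-interface/RPE boundary
curves (low-order cosine + tilt with random control points), a Gaussian
foveal pit, per-layer reflectivity levels, a global tissue gain, and a
lesion:

* `ftmh` — all inner-layer signal removed from ILM down to the RPE band
  in a contiguous column band at the fovea;
* `control_erm` — a thin hyperreflective membrane just above the ILM;
* `lamellar` — a partial-thickness defect (inner half removed, RPE and
  outer layers intact), used as the challenge class.

Slices of one eye share geometry with a small cumulative vertical drift
per slice, so adjacent slices correlate strongly — the coherence the
contrastive pairs rely on. Speckle is multiplicative log-normal (mean
one, log-sd 0.5 by default) applied before clipping to `[0, 1]`, since
OCT speckle is multiplicative. Demographics mirror the study
population: ages N(69.6, 6.4²) for FTMH and N(70.5, 8.6²) for controls,
a 46:15 female:male imbalance in FTMH, and a few percent of bilateral
patients.

Two properties are deliberately calibrated, because they are exactly
what the method needs and what the tests verify:

* **Within-eye coherence**: adjacent slices of an eye correlate more
  than central slices of different eyes (one-sided test, p < 0.01, on a
  noiseless 50-eye cohort).
* **Class separability**: a pixel-threshold oracle (a full-depth
  low-intensity foveal column) classifies noiseless FTMH vs control
  phantoms perfectly, so the downstream task is learnable.

Equally deliberate is what the phantom does **not** model: A-scan
physics, shadowing, motion artifacts, vessel structure, disease staging,
or texture beyond speckle. Between-eye variation (thickness, curvature,
reflectivity, gain) is drawn from wide ranges — real eyes differ
markedly in these — and this variation is what makes eyes mutually
distinguishable to the contrastive task. Passing the desk-scale tests
therefore shows the *pipeline* behaves as specified on data with the
right structure; it says nothing about clinical performance.

## Augmentation

Views are generated by, in fixed order, random crop (area fraction
uniform in `[0.5, 1]` at the input aspect ratio) → horizontal flip
(p = 0.5; vertical flips are anatomically invalid) → brightness (additive
delta in `[-0.2, 0.2]`) and contrast (scaling about the image mean,
factor in `[0.8, 1.2]`) → additive Gaussian noise with per-view
`mu ~ U[-0.1, 0.15]`, `sigma² ~ U[0, 0.2]`, clipped to `[0, 1]`. Noise
comes last so it acts at the final resolution where B-scan noise lives.
Brightness/contrast functional forms and ranges are package choices; the
noise and crop parameters are the documented preprocessing constants.
Evaluation is never augmented. Fine-tuning is un-augmented by default
(`augment = FALSE` in `finetune_config`): with a frozen encoder the
training features are deterministic and are computed once and cached,
which is what makes desk-scale ensembles cheap; setting `augment = TRUE`
re-extracts features from freshly augmented views each epoch, which
matters mainly in trainable-encoder (baseline) mode.

## The desk-scale benchmark

`inst/extdata/desk_benchmark.yaml` runs the whole experiment at a size a
single CPU finishes in minutes: 120 eyes (20 FTMH, 100 ERM) of 7 slices
at 64×64, `small_cnn`, 100 pre-training epochs with 16-pair batches, an
8-fold frozen-encoder ensemble (30–60 fine-tuning epochs), a 5 FTMH +
20 control holdout, and a 20-eye lamellar challenge set. Problem sizes
were chosen as the smallest at which every pipeline stage still has its
full structure (three replicates' worth of disjoint eyes, eight
non-degenerate folds, meaningful batch negatives).

One scaling choice deserves emphasis: the benchmark reduces augmentation
strength (noise variance ≤ 0.05, crops 70–100%, brightness/contrast
ranges halved). The clinical-scale noise constants act on 224×224 views
of 496×512 scans; at 64×64 the same absolute noise variance swamps the
anatomy entirely — empirically, even a pixel-correlation oracle then
fails to match positive pairs, and the contrastive loss sits at its
uninformative-similarity plateau `log(2N-1)`. Scaling the perturbation
to the resolution keeps the pretext task solvable-but-hard, which is the
regime the method operates in at clinical scale. Package *defaults*
keep the clinical constants; only the benchmark configuration scales
them.

## Numerical and degenerate-input choices

* Undefined classification ratios (0/0) are reported as 0 and flagged
  `degenerate` rather than NaN.
* ROC ties enter simultaneously; the trapezoidal AUC then equals the
  Mann-Whitney U statistic with ties counted half (asserted to 1e-10
  against a brute-force oracle).
* Replicate aggregation reports mean ± sample SD (n − 1).
* The checkpoint criterion treats `val_accuracy = 0` as +∞; if every
  record is degenerate, selection errors rather than guessing.
* Integer TIFFs are rescaled to `[0, 1]` by the dtype maximum; color
  TIFFs are rejected, not converted, to avoid silent intensity
  distortion. Round-trip error is ≤ `1/(2^bits − 1)` per pixel.
* All randomness flows from one global seed through a documented
  multiplicative string hash (`derive_seed`), so stages can be re-run
  independently and bit-identically; reproducibility is bit-exact in
  single-threaded BLAS mode.
* Grad-CAM saliency uses the final convolutional block, upsampled
  bilinearly, rectified and max-normalized; plain input-gradient maps
  are available as a method option.

A caveat about what the desk benchmark can show. The benchmark compares
the pre-trained frozen encoder against a *random-initialized* frozen
encoder with the same fine-tuning budget. Random convolutional features
followed by a trained 3×512 MLP are a famously strong baseline on simple
high-contrast tasks, and the phantom lesion — even behind speckle and a
pseudohole-bearing control class — is far closer to that regime than
subtle clinical texture at native scan resolution is. At desk scale there
is a structural tension: any phantom easy enough for the contrastive
pretext task to be solvable by a tiny encoder in 100 epochs also tends to
be easy for random features, which compresses the headroom the
pre-training comparison is meant to measure. The benchmark still runs the
comparison honestly and reports whatever margin materializes; a small or
even negative margin at this scale is informative about the scale, not
about the method's clinical-scale behavior.

## Known limitations

* The phantom's realism is structural, not radiometric; results on it do
  not transfer to clinical scans.
* The pure-R/Rcpp engine is single-threaded and desk-scale; the
  ResNet-50 path is provided for architectural fidelity (forward pass
  and parameter count verified) but pre-training it at 224×224 for 800
  epochs is out of scope on a CPU.
* The challenge evaluation treats every lamellar/pseudohole eye as
  FTMH-negative ground truth, matching the clinical definition, but the
  phantom lamellar class is a single morphology.
* With three replicates, between-replicate SDs are descriptive, not
  inferential.
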