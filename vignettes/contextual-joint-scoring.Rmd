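---
title: "Contextual joint scoring on hand radiographs: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextual joint scoring on hand radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(shscontext)
```

## The problem

Radiographic damage in rheumatoid arthritis (RA) is scored joint by joint
under the modified Sharp/van der Heijde system (SHS): per hand, 16 sites
are graded for erosion (0–5) and 15 for joint space narrowing (JSN, 0–4).
The clinically decisive reading is binary — *intact* (grade 0) versus
*non-intact* (grade ≥ 1) — and it is hard: mild cortical defects are easily
confused with benign margin irregularities, even for experienced readers.
Two pieces of clinical knowledge make the task easier: RA damage
progresses **bilaterally and symmetrically**, so the same joint on the
other hand is informative, and joints of the same anatomical **group**
(PIP, MCP, CMC, wrist) tend to progress together.

`shscontext` implements a two-stage automatic pipeline that operationalizes
this: (1) every target joint is **detected** on the hand image by heatmap
keypoint regression; (2) each detected joint is **cropped** at a
scale-normalized resolution and classified as intact/non-intact by one of
four architectures that differ in how much context they see:

* **SISO** — one crop in, one decision out (the baseline);
* **MIMO local** — the same joint of both hands in, two decisions out;
* **MIMO one-hand** — a full same-hand joint group in, one decision per
  member;
* **MIMO both-hands** — the group of both hands in.

A synthetic hand-phantom generator stands in for clinical data, so every
stage is trainable, testable and fully reproducible at desk scale.

## Joint taxonomy

The taxonomy module is the single source of truth consumed by every other
stage. Canonical ordering is radial-to-ulnar within group, groups ordered
PIP(-IP), MCP, CMC(-M), wrist; this fixes the input-slot assignment of the
grouped classifiers. Stable string ids (`"erosion.mcp3.left"`) serialize
into annotation files, and `contralateral()` is a group-preserving
involution. The JSN PIP group contains four joints (no thumb IP): the
thumb interphalangeal joint is scored for erosion only.

```{r}
target_joints("erosion", "right")
contralateral("erosion.mcp3.left")
```

## The phantom generator

`phantom_config()` + `generate_dataset()` produce single-hand,
radiograph-like images (bright anti-aliased bone capsules on a dark noisy
background) with known joint centers. The generator emulates the
statistical and visual structure the pipeline depends on, not radiographic
physics:

* **Correlated labels.** Each joint's latent severity is
  \(z = \sqrt{\rho_{pat}}U + \sqrt{\rho_{grp}}G + \sqrt{\rho_{sym}}S +
  \sqrt{1-\rho_{pat}-\rho_{grp}-\rho_{sym}}\,\epsilon\), with independent
  standard-normal components per patient (\(U\)), per patient × group
  (\(G\), hand-agnostic), per patient × joint name (\(S\), shared by the
  two hands) and per joint instance (\(\epsilon\)). Thresholding \(z\) at
  the \(1-p_g\) normal quantile reproduces the configured group prevalence
  exactly while \(\rho_{sym}\), \(\rho_{grp}\), \(\rho_{pat}\) tune
  bilateral, within-group and patient-level label correlation
  independently. Grades above 0 grow with the exceedance in steps of
  `grade_step` (0.6 latent SD per grade).
* **Default prevalences** are the per-group non-intact rates of a
  40-patient clinical cohort of 226 hand radiographs (erosion: 125/1130
  PIP-IP, 143/1130 MCP, 131/452 CMC-M, 470/904 wrist; JSN: 342/904,
  254/1130, 350/678, 461/678). The correlation shares default to
  \(\rho_{sym}=0.5, \rho_{grp}=0.2, \rho_{pat}=0.15\); no quantitative
  clinical estimates exist for these, so they are free parameters chosen
  once as plausible for a bilaterally symmetric disease.
* **Visible signatures.** A JSN grade \(k\) shrinks the rendered joint gap
  to \(g_0(1 - k/4)\) (for the composite carpal joints the bone
  approximation is rendered as a bridging blob). An erosion grade \(k\)
  carves a marginal bite into the bone end next to the joint, with radius
  and depth growing in \(k\) and scaled by the `contrast` parameter.
* **Benign mimics.** With probability `mimic_rate` (default 0.25), an
  intact erosion site carries a benign margin irregularity visually
  similar to a mild erosion — independently on each hand. Real radiographs
  contain such lookalikes (cortical irregularities, nutrient foramina);
  they are what makes single-view reading of mild disease genuinely
  ambiguous. Because true damage is bilaterally correlated and mimics are
  not, contralateral context is exactly the information that resolves the
  ambiguity.
* **Geometry variation.** Per-image global scale (±6%), rotation (±5°),
  translation (±2.5%) and per-finger length jitter (±5%); optional ulnar
  drift rotates the finger rays ulnarly in severely damaged hands. Left
  hands are exact mirrors of right-hand geometry.

What the phantoms do **not** emulate: soft tissue, osteopenia, projection
physics, anatomical shape variation beyond the jitter above, or multiple
diseases. Passing tests on phantoms therefore demonstrate that the
pipeline's machinery is correct and that contextual classification helps
*when the generating assumptions hold*; they are not evidence about
clinical performance.

## Detection

One detector per assessment. The image (mirrored to right-hand orientation
for left hands) is resized to `input_size` (default 256, divisible by 4)
and a small fully convolutional encoder–decoder (two 2× downsampling
stages, three bottleneck convolutions, two upsampling stages) regresses one
Gaussian scoremap per joint (σ in input pixels, default 2). The loss is
mean squared error with peak weighting \(1 + w\,t\) (`peak_weight`, default
30) — plain MSE collapses onto the all-background solution because peaks
occupy a vanishing fraction of the map. Centers are read off as per-channel
argmaxes (ties broken toward the lowest y, then x) with quadratic 3×3
subpixel refinement; confidence is the clipped peak value.

Evaluation follows the standard two metrics. Images are first rescaled so
the median proximal-phalanx length (MCP→PIP distance of fingers 2–5;
even-count median = mean of the middle two) matches a fixed reference
`L_ref = 100` px — only ratios matter, the constant is arbitrary. A
detection is *correct* when the ground-truth center lies inside a
joint-specific box centered on the detected point (250 × 250 px for
PIP/IP/MCP/CMC-M, 500 × 300 for the radius, 300 × 300 otherwise); this is
the closest automatable surrogate for a human check that the box contains
the joint. Incorrect detections are flagged `discarded` and excluded
downstream. Distance error is the Euclidean detected-to-truth distance at
the normalized resolution. In the held-out phantom check, the mean
distance error is compared against the heatmap σ expressed in the same
normalized units (σ × image/input ratio × normalization scale): an
error within one Gaussian width of the target is the natural "as good as
the supervision" bound.

## Cropping, augmentation, balancing

Classification crops reuse the evaluation box sizes (no separate sizes are
defined for classification) at the normalized scale, zero-padded at image
borders, and left-hand crops are mirrored to right-hand orientation so one
model serves both sides. Before entering a network, a crop is resampled to
`input_side` (64 is the desk-scale default for standalone use; the canned
studies use 32 for speed) and mean-centered — exposure is uninformative on
radiographs, and removing the per-crop offset conditions optimization.
Downscaling is anti-aliased by iterated 2×2 block averaging before the
final bilinear step, so a few-pixel lesion is integrated rather than
skipped.

Augmentation is purely geometric — rotation in [−3°, 3°], per-axis
translation in [−5, 5] px, isotropic scaling in [0.97, 1.03], sampled
continuously and applied about the window center with bilinear
interpolation. Balancing retains every original crop and adds fresh
augmentations of the under-represented class, round-robin over its
originals, until exactly `n_total`/2 crops per class ("about 10,000 with
no class imbalance" made exact for testability; validation sets are
balanced the same way, test sets never). For the MIMO tuple sets —
where an example is a *tuple* of crops with one label per slot — the same
budget is interpreted per crop (`n_total`/slots tuples) and the
oversampling stream favours tuples rich in the minority class,
interleaving label-disagreeing tuples: those are the examples that force
per-slot discrimination when labels are strongly correlated. This
tuple-level scheme is this package's own design; the per-crop contract
above is the primitive it generalizes.

## Classifiers

All four architectures share one internal wiring: a weight-shared
convolutional feature extractor (two conv+pool stages and a dense
projection to `feature_width`) applied to every input slot; the slot
features concatenated into a fully connected trunk (`n_fc_layers` hidden
layers, width `trunk_width`, optional dropout, He-normal or small-uniform
initialization); and one independent sigmoid output per slot. Each slot's
output head (weights shared across slots) reads the trunk's pooled context
*together with that slot's own feature vector*. The own-feature path is
essential: without it, a jointly trained model on strongly correlated
joints collapses onto a slot-symmetric "pair average" that cannot rank the
two joints of a disagreeing pair — we observed exactly this degeneracy
(slot-output correlation > 0.98) before adding the path.

Training minimizes binary cross-entropy, summed over output slots for the
MIMO variants, with Adam. After each epoch the validation loss is
evaluated; training stops when it has failed to improve for `patience`
(10) consecutive epochs or at `max_epochs` (100 — the epoch cap reading of
the stopping rule), and the weights of the best validation epoch are kept.
Binary calls use a fixed threshold of 0.5; PR-AUC is threshold-free.

When several architectures are compared (`compare_architectures()`), the
SISO model is trained first on each fold rotation and the MIMO variants
initialize their feature extractor from its convolutional weights before
fine-tuning end to end. This mirrors transfer-learning practice (all
architectures fine-tuning one pretrained backbone) and puts them on an
equal feature footing, so the comparison isolates the value of the
contextual wiring. At desk scale it is also what makes the comparison
meaningful: a tiny backbone trained from scratch inside a MIMO objective
often fails to discover the lesion features at all, because the summed
loss over strongly correlated slots is dominated early by context shortcuts.

## Evaluation

Folds are patient-disjoint: a seeded permutation of patients cut into k
consecutive blocks; rotation i tests fold i, validates fold i+1 (mod k),
trains on the rest, so every fold is the test fold exactly once. Metrics
(positive class = non-intact): sensitivity, specificity, precision,
F-measure (harmonic mean of sensitivity and precision; zero-denominator
ratios are reported as missing, never as 0) and PR-AUC by the
average-precision estimator — the sum over recall increments of the
precision at that threshold, with tied scores grouped into one step.
Trapezoidal interpolation of PR curves is biased and deliberately not
used; comparisons against trapezoid-based numbers elsewhere may differ
slightly. Test predictions are pooled across folds (not fold-averaged)
before computing metrics, matching reporting that gives one value per
stratum; strata are each joint group, the combined non-wrist groups, the
wrist, and all joints.

## The canned studies

Two study functions fix the package's desk-scale operating points; they
are used verbatim by the test suite and the acceptance script.

`detection_study()`: 20 training and 10 held-out clean hands (destruction
prevalence 0, noise 0.03) at 256 px, detector input 64 px, σ = 3, 150
epochs. Expected behaviour: correct detection rate ≥ 0.95 and mean
normalized distance error below the normalized σ (≈ 34 px here).

`contextual_advantage_study()`: 60 patients at 256 px, group-MCP erosion,
prevalence 0.3, ρ_sym ∈ {0.9, 0}, ρ_grp = ρ_pat = 0, contrast 0.5, benign
mimics at the default rate, crops at ground-truth centers (isolating the
classification question from detector noise), k = 4 patient-disjoint folds
of which 2 rotations are run, balanced budget 600 crops per model, input
32 px, Adam 1.5e-3, dropout 0.2, epoch cap 60. With bilateral labels
(ρ_sym = 0.9) the contralateral-pair model should beat the independent
model in pooled test PR-AUC; with independent labels (ρ_sym = 0) the two
should tie to within noise. "Weak contrast" here means half amplitude:
the ambiguity that context resolves comes from the benign mimics, whose
depth range overlaps mild erosions at any contrast, while 0.5 keeps the
lesion features reliably learnable by the tiny backbone.

Problem sizes throughout (image resolutions, network widths, epoch caps,
rotation counts) are chosen so a complete run takes minutes on a single
CPU; they are the package's desk-scale defaults, not statements about the
sizes appropriate for clinical data.

## Numerical and degenerate-input choices

* Coordinates are 0-based pixel centers, x rightward, y downward;
  resolution changes use center-aligned mapping
  \(x' = (x + 0.5)s - 0.5\).
* Heatmap argmax ties break toward the lowest y, then x; subpixel offsets
  are clamped to ±0.5 px and skipped at borders.
* `scale_normalize()` requires all eight MCP2–5/PIP2–5 centers and errors
  otherwise; callers pass detected estimates when ground truth is absent.
* Augmentation parameters exactly on a policy boundary are accepted
  (ranges are inclusive); the identity transform is pixel-exact.
* Balancing errors when a class has no originals, or more originals than
  half the budget.
* `pr_auc()` rejects single-class label sets; stratified reports show
  missing PR-AUC for single-class strata instead.
* All randomness flows through explicit integer seeds; sub-seeds derive
  from a string hash of the stage name, and RNG state is restored after
  every seeded operation.

## Known limitations

* The phantom is stylized; none of the reported numbers transfer to
  clinical radiographs.
* The detector is a small from-scratch CNN, not a pretrained pose
  estimator; on 20 training phantoms it localizes well, but the clean
  separation of phantom bones does most of the work.
* The MIMO one-hand and both-hands variants are implemented and tested
  structurally; the canned advantage study exercises the contralateral
  pair, which clinical reading practice and our generator's symmetry
  structure most directly motivate.
* Multi-grade (ordinal) scoring is out of scope: grades beyond the binary
  split affect rendering severity only.
* Time-series structure (repeat visits share patient- and joint-level
  latents) is generated but not exploited by any model.
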