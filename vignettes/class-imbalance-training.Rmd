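---
title: "Class-imbalance-aware training for binary lesion classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-imbalance-aware training for binary lesion classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melbalance)
```

## The problem

Dermoscopic melanoma/nevus datasets are strongly imbalanced: melanoma, the
class whose misses are costly, is the minority (roughly 1 in 4 images in the
large public archives, 1 in 5 in the common 100-image benchmark). A network
trained conventionally on such data minimises its loss mostly on the
majority class, and the resulting classifier has high specificity (SPE) but
poor sensitivity (SEN) at the natural 0.5 threshold. melbalance packages the
three training-side devices that counter this — a class-wise loss, a
fixed-class-ratio mini-batch sampler, and a reformed fully connected head —
together with the evaluation tooling (SEN/SPE threshold analysis, ROC/AUC,
reader comparison) and a synthetic lesion-image generator that makes the
whole pipeline testable on a laptop, offline.

## The class-wise loss

For a mini-batch with $P$ positives and $N$ negatives ($M = P + N$), scored
$s_i \in [0,1]$ with labels $y_i \in \{0,1\}$:

$$
\ell_{\mathrm{PMSE}} = \frac{1}{P}\sum_{i:\,y_i=1}(1-s_i)^2,\qquad
\ell_{\mathrm{NMSE}} = \frac{1}{N}\sum_{i:\,y_i=0}s_i^2,
$$

$$
\ell_{\mathrm{CLF}} =
  a\,(\ell_{\mathrm{PMSE}}+\ell_{\mathrm{NMSE}})^2 +
  b\,(\ell_{\mathrm{PMSE}}-\ell_{\mathrm{NMSE}})^2 .
$$

The first term drives the *total* class-wise error down (pushing SEN + SPE
up); the second penalises any *gap* between the two class errors (pushing
|SEN − SPE| down). Squaring both prevents cancellation and keeps the loss
differentiable, so it backpropagates directly through the sigmoid output.
Defaults $a = 0.5$, $b = 1$: the balance term is deliberately weighted
harder than the sum term. On hard 0/1 predictions the loss has a closed
form on confusion counts ($\ell_{\mathrm{PMSE}} = FN/P$,
$\ell_{\mathrm{NMSE}} = FP/N$), which `clf_from_confusion()` implements and
the test suite verifies to be bit-identical to the batch form:

```{r table2}
clf_from_confusion(tp = c(12, 16, 17), fp = c(2, 8, 10),
                   tn = c(78, 72, 70), fn = c(8, 4, 3))
```

Reading down the rows, accuracy and plain MSE *improve* while the class
balance deteriorates; the class-wise loss ranks the three models the other
way round, which is exactly the property wanted on imbalanced data.

Key properties (all property-tested): non-negativity; zero iff both class
errors are zero (when $a > 0$); symmetry under swapping the class errors;
strict monotonicity in $|\ell_{\mathrm{PMSE}}-\ell_{\mathrm{NMSE}}|$ at
fixed sum (when $b > 0$); analytic gradients matching finite differences.

## The fixed-ratio sampler

With naive shuffling, the number of minority images per batch fluctuates
and is frequently zero at strong imbalance, starving the positive term of
the loss. `make_epoch()` pins the batch composition: negatives are a
shuffled partition consumed exactly once per epoch (epoch length =
`floor(N_neg / negatives_per_batch)`, a short final batch is dropped
because it cannot honour the ratio); positives are drawn from an
independently shuffled cycling stream, reshuffled on exhaustion, so each
positive is used either $\lfloor k \rfloor$ or $\lceil k \rceil$ times per
epoch. The per-batch positive count is exactly `round(positive_fraction *
batch_size)` in every batch.

Two open choices, both configurable because the method description pins
neither: the default `positive_fraction` is the *training-set prevalence*
(keeps each batch's composition equal to the dataset's; 0.5 gives fully
balanced batches), and the epoch is anchored to one full pass over the
majority class (keeps total data exposure comparable to naive shuffling).

## Augmentation and preprocessing

Augmentation is *real-time*: the transform is drawn when an image enters a
batch, so the same image is seen differently in different epochs.
Rotation (±5°), horizontal/vertical shift (±5% of size), shear (±0.05),
and zoom (1 ± 0.05) compose into a single affine matrix applied in one
bilinear resampling pass — avoiding cumulative interpolation blur — with
nearest-edge fill. The source description mixes units for these ranges
("0.05%", "0.05°"); they are interpreted as the fractions/degrees above,
matching the conventions of the augmentation APIs the phrasing mirrors, and
every range is configurable. No flips are applied (none are specified).
Preprocessing is deterministic: centre-crop to 4:3, bilinear resize to
256 × 192, intensities scaled into [0, 1] by division by 255.

## Architecture and optimisation

The classifier head is `dense(1024) → ReLU → BatchNorm → Dropout(0.5) →
dense(512) → ReLU → BatchNorm → Dropout(0.5) → dense(1) → sigmoid`. The
ordering of batch normalisation and dropout relative to the activation is
not pinned by the description; the default normalises post-activation
values and a flag (`bn_before_activation`) switches to pre-activation
normalisation. Forward and backward passes are explicit matrix algebra
(there is no deep-learning framework dependency); gradients are verified
against central finite differences to 1e−6 in the tests.

Training uses Adam (`lr = 1e-4`, $\beta_1 = 0.9$, $\beta_2 = 0.999$, no
decay, no amsgrad) under a *triangular2* cyclical learning rate: the lr
oscillates between `base_lr = 1e-7` and a ceiling starting at
`max_lr = 1e-4` that halves after each full cycle (one cycle = 2 ×
`step_size_epochs`, default 4 epochs), stepped per mini-batch. Model
selection is min-validation-loss checkpointing; validation loss is computed
on the whole validation set in one evaluation-mode pass (the alternative —
averaging over validation batches — is not what checkpointing frameworks
do, and the whole-set value is what the checkpoint rule compares).

The backbone is a pluggable contract (any map from rasters to feature
vectors). The packaged `build_tiny_backbone()` is a ~2.5k-parameter seeded
random convolutional extractor that stays *frozen*, mirroring
frozen-backbone transfer learning: random convolutional features followed
by a trained head are a standard cheap baseline, and freezing keeps every
desk-scale run deterministic and CPU-cheap. A full-scale pretrained CNN can
be substituted wherever a backbone is accepted.

## Scenarios

Three scenarios share one architecture and initial weights (same
initialisation seed) and isolate the devices:

| scenario | sampler | loss |
|---|---|---|
| ORI | naive shuffle | MSE (or BCE/focal) |
| BON | fixed ratio | MSE (or BCE/focal) |
| BLF | fixed ratio | class-wise (CLF) |

MSE is the default baseline loss for ORI/BON. The pairing is enforced:
the class-wise loss presupposes both classes per batch, which only the
fixed-ratio sampler guarantees. If a naive batch does happen to lack a
class while the class-wise loss is in use (possible only outside the
enforced pairings), training mode scores the missing class term as 0 with
a warning; strict (evaluation) mode raises an error.

## Evaluation

Predicted positive iff `score >= threshold` — ties go to the positive
class; the convention matters for threshold tables and is fixed
throughout. `roc_curve()` sweeps all distinct scores, AUC is trapezoidal
and equals Mann–Whitney pairwise concordance with half credit for ties
(property-tested against a brute-force pair count). `threshold_sweep()`
reports, for each SEN target, the *largest* threshold reaching it (hence
the best SPE available at that SEN), and symmetrically for SPE targets.
`balanced_threshold()` offers two selection rules — `min_gap`
(argmin |SEN − SPE|, ties to larger SEN + SPE then larger threshold) and
`youden` (argmax SEN + SPE − 1) — because published "balanced" operating
points rarely state their rule. `readers_outperformed()` counts reader
operating points strictly below the model's interpolated ROC polyline,
reporting on-curve readers separately; the packaged
`dermatologist_readers.csv` fixture carries the published group-level
operating points of a 157-reader benchmark study as *input data*, not as a
computed claim.

## The synthetic world

`generate_dataset()` renders skin-tone backgrounds with one elliptical
lesion whose darkness, border irregularity and asymmetry are drawn from
class-conditional normals; the positive class mean is shifted by
`separability` × (0.25, 0.15, 0.25) in those three parameters. At
`separability = 0` the classes are identically distributed; at 1, the
drawn border-irregularity parameter alone separates the classes nearly
perfectly. Defaults — `separability = 0.7`, `noise_level = 0.1` — were
chosen once as "learnable but imperfect" and are not tuned per test. Each
dataset ships its ground-truth parameters (`params.csv`) so tests can
validate the rendering against the stated distributions. Splits are
stratified 80/10/10; a 20-positive/80-negative `generate_benchmark()` set
with an independent seed mirrors the shape of the public reader-study
benchmark. Images are written as binary PPM — a codec-free format — since
the pipeline needs rasters, not compression.

What a green test does **not** establish: the generator produces
controllable statistical structure, not dermoscopic realism — no hair,
rulers, colour charts, multi-modal lesion appearance, or label noise; and
the desk-scale backbone is frozen and random, so absolute performance
numbers say nothing about full-scale systems trained on real archives.

## The scaled-down scenario experiment

The full-scale headline results (AUC ≈ 0.94 on the reader benchmark)
require GPU training of a large pretrained CNN on tens of thousands of
real images and are explicitly out of desk-scale reach. The package's
acceptance experiment is a property-based surrogate: 10% positive
prevalence (train split 150/1350), the frozen tiny backbone, a 128–64
head, 10 epochs, 5 training seeds, and the claim is *ordinal*: the median
|SEN − SPE| at threshold 0.5 is smaller under BLF than BON, and BLF's
median SEN exceeds ORI's.

One calibration was needed: with the full-scale CLR range (1e−7…1e−4) a
17k-parameter head trained for ~440 iterations barely moves — scores stay
near 0.5 and the 0.5-threshold SEN/SPE are arbitrary, so no ordering is
resolvable in either direction. The qualitative claim concerns *converged*
models, so the desk-scale experiment scales the CLR envelope to
1e−5…1e−2 (an ordinary Adam range for a small MLP); the full-scale
defaults remain the package defaults. With that, the ordering reproduces
robustly across dataset seeds.

## Numerical choices and degenerate inputs

* BCE/focal clip scores to `[1e-7, 1 - 1e-7]`; the class-wise loss needs
  no clipping (it is polynomial in the scores).
* Batch-norm epsilon 1e−5; running statistics use momentum 0.9 and are
  part of the checkpoint.
* Single-class batches: error in strict mode, zero-with-warning in
  training mode (see Scenarios).
* Non-finite training or validation loss aborts with a diagnostic rather
  than silently producing a broken checkpoint.
* Sweep/balance tie-breaks are fixed and documented (see Evaluation) so
  threshold tables are reproducible.
* All stochastic steps (weight init, shuffling, dropout, augmentation,
  rendering) run off explicit seeds; identical seeds give identical
  histories in this pure-R implementation.

## Limitations

Binary classification only (no multi-class extension of the loss); no
automatic search over $a$, $b$ (the source work set them by trial and
error); no confidence intervals on AUC; the tiny backbone is a stand-in,
not a claim about convolutional architecture choice.
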