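---
title: "Handling long-tail label imbalance in multi-label microscopy classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handling long-tail label imbalance in multi-label microscopy classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protclass)
```

## The problem

High-throughput fluorescence microscopy resources such as the Human Protein
Atlas image each specimen through four stains — red (microtubules), green
(the protein of interest), blue (nucleus) and yellow (endoplasmic
reticulum) — and annotate each sample with one or more of 28 protein
localization classes. Two properties make classification hard:

* **multi-label structure**: a sample may carry anywhere from one to all 28
  labels, so the task decomposes into 28 coupled binary decisions;
* **long-tail imbalance**: the most frequent localizations (nucleoplasm,
  cytosol) outnumber the rarest (rods and rings) by two to three orders of
  magnitude. A classifier trained naively collapses onto the head classes:
  its macro-averaged F1 — the metric that weights every class equally — is
  dominated by zeros on the tail.

`protclass` implements, as reusable components, the machinery that
counteracts this collapse: an effective-number weighted loss, batch-level
hard example mining, an adaptive concatenate pooling head with buffering
layers and four-channel input adaptation, learning-rate strategies
(finder, discriminative groups, cosine cycles), greedy per-class decision
thresholds, and a data pipeline (perceptual-hash deduplication, minority
oversampling, multi-label stratified splitting). A synthetic RGBY
generator and a compact trainable CNN let the whole workflow run
end-to-end on one CPU.

## Effective numbers and the E-loss

Weighting each class's loss by inverse frequency $1/n_c$ overcorrects:
samples within a large class are partly redundant, so the $n$-th sample
adds less information than the first. Model each sample as one unit of
volume inside a class-specific feature volume $V$. If $Q_{n-1}$ volume is
already covered, a new sample falls inside it with probability
$p = Q_{n-1}/V$, giving

$$Q_n = p\,Q_{n-1} + (1-p)(Q_{n-1}+1) = \alpha\,Q_{n-1} + 1,
  \qquad \alpha = \frac{V-1}{V},\; Q_1 = 1,$$

whose closed form is $Q_n = (1-\alpha^n)/(1-\alpha)$
(`effective_number()`). The class weight becomes $1/Q_{n_c}$
(`eloss_weights()`), and the training loss is

$$EL = \sum_c \frac{1-\alpha}{1-\alpha^{n_c}}\, L(p_c, y_c),$$

with $L$ any per-class base loss — binary cross-entropy by default, the
focal variant (`focal_base_loss()`) when extra down-weighting of easy
examples is wanted. The single parameter $\alpha \in [0,1]$ interpolates
between uniform weighting ($\alpha = 0$, every $Q_n = 1$) and inverse
frequency ($\alpha \to 1$, $Q_n \to n$). Because the per-class volumes are
unobservable, one shared $\alpha$ is used for all classes; the default is
0.99, which discounts classes beyond a few hundred samples (the weight
saturates once $n_c \gg 1/(1-\alpha) = 100$).

Two conventions are worth making explicit:

* **Normalization.** Raw weights shrink as $\alpha$ grows, which would
  silently rescale the loss and invalidate a tuned learning rate. By
  default the weights are rescaled to sum to the number of counted
  classes, so only their *relative* profile changes with $\alpha$; the
  `normalize` flag turns this off for the literal weighted sum.
* **Zero-count classes** receive weight 0 with a warning rather than an
  error: a training split may simply lack an ultra-rare class, and an
  infinite weight would poison the sum.

## Hard example mining

Even with class weights, a batch drawn from a long-tail distribution is
numerically dominated by easy head-class samples. The hard sampler
(`hard_sample_select()`) sorts the batch by per-sample loss and keeps only
the top $K$ of $B$; the batch loss is the mean over that subset, so
backpropagation sees almost exclusively difficult — predominantly
tail-class — samples. Two composition choices are fixed here:

* class weights apply **before** selection, so a rare-class sample with a
  moderate raw loss still outranks an easy majority sample;
* ties break toward the lower index, making selection deterministic.

$K$ defaults to $\lceil B/2 \rceil$: keeping half the batch suppresses the
easy majority while retaining enough gradient signal; it is exposed as a
fraction (`hard_fraction`) because no single value suits every batch size.

## Architecture components

**Four-channel input adaptation** (`adapt_input_layer()`): pretrained
backbones expect RGB. The first three kernels are kept and a fourth
(yellow) kernel is appended — zero-initialized (exactly preserving the
3-channel behaviour until training moves it), the mean of the RGB kernels
(the default: a neutral mixture of learned filters), or a copy of the red
kernel (both stains image filamentous structures).

**Adaptive concatenate pooling** (`acp_pool()`): global average pooling
summarizes diffuse staining, global max pooling preserves punctate
signal; concatenating both in the channel dimension doubles the feature
length ($C \to 2C$, e.g. 1536 → 3072, 2048 → 4096) while staying
independent of the input's spatial size — important because microscopy
crops vary.

**Buffering layers** (`head_spec()`, `build_head()`): collapsing thousands
of pooled features straight to 28 logits discards information in a single
linear map. One or two intermediate fully connected layers of strictly
decreasing width (each with ReLU and dropout) shrink the representation
gradually, e.g. 4096 → 1024 (dropout 0.5) → 28, or 4096 → 4096 (0.25) →
1024 (0.5) → 28 for a deeper backbone.

## Training-time optimization

**Discriminative learning rates** (`discriminative_lrs()`): pretrained
encoder layers need smaller steps than the freshly initialized head, but
microscopy differs enough from natural images that the encoder rate is
reduced only 2–4×: `[lr/3, lr]` for two layer groups, `[lr/4, lr/2, lr]`
for three.

**LR finder** (`lr_find()`): probe the loss at exponentially increasing
rates starting near 1e-5, smooth the trace with a bias-corrected
exponential moving average (factor 0.98), stop once the smoothed loss
exceeds 4× its running minimum, and suggest the largest rate at which the
smoothed loss was still decreasing. The smoothing factor and divergence
multiple are implementation constants chosen to tolerate batch-level
noise while stopping within a few probes of genuine divergence.

**Cosine cycles with restarts** (`lr_schedule()`, `cosine_cycle_lr()`):
within a cycle of $T$ steps the rate follows
$lr_{\min} + (lr_{\max}-lr_{\min})(1+\cos(\pi t/T))/2$ — fast early
progress, a gentle landing near the minimum — and at each cycle boundary
it restarts at $lr_{\max}$, kicking the optimizer out of sharp local
minima. The floor defaults to 0 (pure cosine to zero), cycles have
constant length (a lengthening multiplier is deliberately not implemented:
constant cycles are the simplest reading of repeated restarts and keep
the step budget predictable).

## Testing-time optimization

During training 0.5 is the implicit decision threshold, but a model
trained on a long tail scores common classes near 1 and rare classes near
0 regardless of correctness. `search_single_threshold()` scans one shared
threshold over the grid 0.1–0.9 in steps of 0.05 (17 values) and returns
the macro-F1 argmax (ties to the lower threshold, favouring recall on
rare classes). `greedy_multi_threshold()` then makes one pass over the
classes in index order, rescanning the same grid for each class while
holding the others fixed. Since macro F1 is a mean of per-class F1 terms
and only the active class's term depends on its threshold, each scan is
evaluated per class in closed form; the current value always remains a
candidate, so the score trace is non-decreasing by construction — this is
asserted on every run. Zero-support classes keep the initial threshold
(there is nothing to optimize) and are reported. A repeat-until-converged
option exists (`passes`) but defaults to a single pass. Predictions use a
closed lower bound (`prob >= threshold`), a convention fixed package-wide
and tested. `ensemble_average()` averages prediction matrices from
several models after verifying shape and sample identity.

## Data pipeline

* **Deduplication** (`compute_image_hash()`, `deduplicate()`): an average
  hash — 8×8 block means thresholded at their mean — per channel,
  concatenated to 256 bits for RGBY. Greedy scan in id order removes any
  sample within a Hamming threshold of an already-kept one. The default
  threshold of 16 bits (4 per channel) was validated on the synthetic
  duplicate fixture: perturbed copies land within a few bits while
  independent samples sit more than 40 bits apart.
* **Minority oversampling** (`oversample_minority()`): a sample whose
  rarest label has fewer positives than the median class count is
  replicated `floor(min(target_ratio, median/rarest))` times (default cap
  4). The median reference and the cap are this package's concrete
  reading of replicating minority classes "a few times" without inviting
  overfitting.
* **Stratified splitting** (`stratified_multilabel_split()`): iterative
  stratification — classes processed rarest-first, each sample assigned to
  the fold with the largest remaining demand for that class — under fold
  size caps, followed by a size-preserving pair-swap repair pass. The
  repair exists because greedy assignment alone leaves the most frequent
  classes (placed last, against nearly full folds) a few positives off
  proportionality; swapping samples between the worst class's most over-
  and under-represented folds, accepting only swaps that strictly lower
  the total squared deviation, restores the ±1 contract while keeping
  fold sizes exact.
* **Input policy** (`resize_and_crop()`): originals up to 2048 px are
  resized to 768 and randomly cropped to 512; larger originals to 1024
  and cropped to 768. The size boundary (2048) is the natural split for
  archives mixing 2048 and 3072 px originals. All channels receive the
  identical geometric transform.

## The synthetic generator

`generate_dataset()` emulates the *statistical* structure the pipeline
must handle, not microscopy itself. Marginal class frequencies follow a
power law in class rank (`tail_exponent`, default 1.5 — about 148:1 from
head to tail over 28 classes); labels are drawn independently per class,
resampling empty vectors and truncating at `max_labels_per_sample`
(dropping head classes first) — independence is used because no
quantitative co-occurrence structure is available to emulate, and the
machinery under test does not depend on one. Each class renders a fixed
Gaussian-blob motif (class-specific blob count, scale and brightness)
into the green channel at a jittered position; the other three channels
carry shared structures shifted coherently with the sample plus a faint
copy of the green signal, mimicking how counterstains correlate spatially
with the protein channel. Pixel noise is added and intensities quantized
to 8 bits, making generation byte-reproducible for a fixed seed. Every
sample logs its motif placements, so tests can verify that a motif is
present iff the label bit is set.

What the generator deliberately does **not** model: real cell
morphologies (the 27 cell types), realistic point-spread functions or
noise statistics, and label co-occurrence. Consequently, passing tests
demonstrate that the *machinery* behaves as specified on long-tail
multi-label image data — not that any particular F1 level is attainable
on real microscopy.

`inject_duplicates()` appends near-copies with bounded perturbation and
returns the ground-truth map, creating the condition deduplication must
detect.

## The compact CNN and the directional experiment

`small_cnn()` is a deliberately small four-channel network: a fixed
block-average stem (64 → 16 px), one 3×3 convolution (16 filters by
default) created for 3 channels and extended to 4 via
`adapt_input_layer()`, `acp_pool()`, and a linear (optionally buffered)
head. Forward and backward passes are plain matrix algebra (im2col +
BLAS); the backward pass is verified against finite-difference gradients
to ~1e-9 in the tests. Training is SGD with momentum 0.9 and weight decay
1e-6 under cosine cycles and two discriminative layer groups.

`run_imbalance_experiment()` is the end-to-end check: a 5000-sample,
64×64, 28-class long-tail dataset (fixed seed; head-to-tail ratio ≈
190:1) is split 3/1/1 into training, validation and test folds by
stratified splitting. Under an identical budget (12 epochs, batch 64,
base lr 0.1, four 3-epoch cosine cycles) and identical initialization per
seed, a plain-BCE model thresholded at 0.5 is compared against E-loss
(α = 0.99) + hard sampler (K = B/2) + greedy thresholds tuned on the
validation fold; both are scored on the held-out test fold. The budget
and network width were fixed from convergence diagnostics (a decreasing
training loss and informative per-class probability rankings) before the
comparison was run. The baseline's failure mode is exactly the one that motivates
the machinery: its probabilities for tail classes never reach 0.5, so its
macro F1 collapses to the head classes, while the treated configuration
recovers a multiple of that score. The expectation is directional —
treated beats baseline across seeds — not a calibrated F1 level, which at
this scale would be meaningless.

## Numerical conventions and degenerate inputs

* Probabilities are clamped to `[1e-7, 1 - 1e-7]` before logarithms.
* `F1 = 0` whenever `P + R = 0`; zero-support classes still enter the
  macro mean.
* `effective_number()` returns `n` exactly at `alpha = 1` and 1 at
  `alpha = 0` (the closed form's removable singularities).
* Top-K and argmax ties resolve to the lowest index / lowest threshold.
* Empty datasets, empty grids, non-square crops, zero-channel feature
  maps and mismatched shapes are rejected with explicit errors.

## Limitations

* The compact CNN is a test vehicle; real use plugs a proper pretrained
  encoder into `acp_pool()`/`build_head()` through the backbone contract
  (any C×H×W feature map).
* The greedy threshold search optimizes the validation macro F1 directly;
  with very small validation folds the thresholds can overfit — the
  experiment guards against this by scoring on a disjoint test fold.
* `deduplicate()` is O(n²) in fingerprint comparisons; adequate for 10⁴
  samples, not for millions.
* Average hashing can conflate images that differ only in fine texture;
  the threshold default errs on the permissive side because the removal
  targets "extremely similar" copies.
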