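# protclass

Imbalance-aware multi-label classification tools for four-channel (RGBY)
fluorescence microscopy images, in R.

Automated protein localization on resources like the Human Protein Atlas
means assigning each specimen one or more of 28 subcellular classes from
four stain channels (red = microtubules, green = protein of interest,
blue = nucleus, yellow = endoplasmic reticulum). The class frequencies are
extremely long-tailed — head classes outnumber tail classes by two to
three orders of magnitude — and the evaluation metric, macro-averaged F1,
weights every class equally. A naively trained classifier collapses onto
the head classes and scores near zero on the tail.

`protclass` packages the counter-measures as composable components for
people building such classifiers (and for anyone with a long-tail
multi-label imaging problem):

* **E-loss** — effective-number class weighting. The effective number of
  $n$ samples under feature-space overlap is
  $Q_n = (1-\alpha^n)/(1-\alpha)$ with $\alpha = (V-1)/V$, and the
  training loss is $EL = \sum_c (1/Q_{n_c})\,L(p_c, y_c)$ with pluggable
  per-class base loss $L$ (BCE or focal). $\alpha$ interpolates between
  uniform ($\alpha=0$) and inverse-frequency ($\alpha\to1$) weighting.
* **Hard example mining** — keep only the top-$K$ per-sample losses of
  each batch, so backpropagation focuses on difficult (mostly tail-class)
  samples.
* **Architecture components** — adaptive concatenate pooling
  (`acp_pool`: global average ∥ global max, $C \to 2C$ features from any
  spatial size), buffering-layer classifier heads, and 4-channel
  adaptation of pretrained 3-channel input layers.
* **Training schedules** — exponential LR range finder, discriminative
  layer-group rates (`[lr/3, lr]`, `[lr/4, lr/2, lr]`), cosine-annealed
  cycles with restarts.
* **Test-time optimization** — single-grid and greedy per-class decision
  thresholds maximizing validation macro F1 (grid 0.1–0.9, step 0.05),
  and prediction ensembling.
* **Data pipeline** — perceptual-hash near-duplicate removal, minority
  oversampling, multi-label stratified k-fold splitting, and the
  resize/random-crop input policy, reading and writing the HPA challenge
  layout (`<id>_<stain>.png` + `train.csv`).
* **Synthetic data + compact CNN** — a long-tail RGBY image generator and
  a small trainable 4-channel CNN (pure R + BLAS), so the entire workflow
  runs end-to-end on one CPU without external data.

## Worked example

Generate a long-tail dataset, train the compact CNN with the full
imbalance machinery, and tune thresholds:

```r
library(protclass)

spec <- synthetic_spec(n_samples = 1000, n_classes = 28, image_size = 64,
                       tail_exponent = 1.5, seed = 7)
ds <- generate_dataset(spec)
ds
#> Synthetic RGBY dataset: 1000 samples, 28 classes, 64x64 px
#> class counts: 744 290 137 85 60 52 44 39 23 15 25 13 18 12 10 12 13 8 8 4 4 8 10 1 5 7 8 4

X <- cnn_input_matrix(ds)                 # 4x4 block-average stem -> 16x16x4
Y <- label_matrix(ds)
folds <- stratified_multilabel_split(Y, 4, seed = 7)
tr <- folds$fold > 1; va <- folds$fold == 1

counts <- class_count_table(Y[tr, ])      # head 557, tail 3 positives
w <- eloss_weights(counts, alpha = 0.99)
round(w$weights[c(1, 14, 28)], 3)
#> [1] 0.065 0.743 2.164                   # tail classes weighted ~30x the head

model <- small_cnn(attr(X, "side"), seed = 1)
model <- train_small_cnn(model, X[tr, ], Y[tr, ], epochs = 12,
                         batch_size = 64, base_lr = 0.1, cycle_epochs = 3,
                         class_weights = w, hard_fraction = 0.5, seed = 1)

probs <- predict_probs(model, X[va, ])
macro_f1_score(probs, Y[va, ], 0.5)
#> [1] 0.0306                              # fixed 0.5 threshold: tail collapses
single <- search_single_threshold(probs, Y[va, ])
c(single$threshold, round(single$score, 4))
#> [1] 0.1000 0.0758                       # one shared tuned threshold
greedy <- greedy_multi_threshold(probs, Y[va, ], init_threshold = single$threshold)
round(greedy$score, 4)
#> [1] 0.0765                              # per-class thresholds, never worse
```

Even this deliberately tiny model shows the pattern that motivates the
toolkit: at the conventional 0.5 threshold the tail classes never fire
and macro F1 sits near the head-class-only floor; threshold tuning (and,
at larger training scale, E-loss and hard mining — see
`run_imbalance_experiment()`) recovers a multiple of that score. The
absolute numbers are those of a 750-sample training run and carry no
meaning beyond the comparison.

`run_imbalance_experiment()` runs the full contrast — plain BCE + 0.5
thresholds vs. E-loss + hard sampler + greedy thresholds under an
identical budget — on a 5000-sample long-tail dataset across five
training seeds, scoring both on a held-out stratified test fold.

A thin command-line interface over the same functions is installed at
`inst/cli/protclass.R` (subcommands `simulate`, `dedup`, `split`,
`thresholds`).

## Documentation

The methods vignette (`vignettes/imbalance-methods.Rmd`) explains the
effective-number model, the composition order of weighting and mining,
all tunable parameters with their defaults and rationale, what the
synthetic generator does and does not emulate, and the package's
numerical conventions.
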