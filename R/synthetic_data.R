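#' Specification of a synthetic long-tail RGBY dataset
#'
#' Describes a synthetic multi-label four-channel microscopy-like dataset:
#' `n_classes` protein classes whose marginal frequencies decay as a power
#' law in the class rank (rank-1 most frequent), samples carrying between 1
#' and `max_labels_per_sample` labels, and square images of side
#' `image_size` with intensities in `[0, 255]`.  Generation from a spec is
#' fully determined by `seed`.
#'
#' @param n_samples Number of samples, `>= 0`.
#' @param n_classes Number of classes, `>= 2` (default 28).
#' @param image_size Image side in pixels, `>= 16`.
#' @param tail_exponent Positive decay exponent: the rank-`r` class has
#'   marginal frequency proportional to `r^-tail_exponent`.  The default 1.5
#'   gives a rank-1 : rank-28 ratio of about 148:1.
#' @param max_labels_per_sample Upper bound on labels per sample, `>= 1`.
#' @param mean_labels Target expected number of labels per sample; scales
#'   the per-class marginals (default 1.4, most samples carry one or two
#'   labels).
#' @param duplicate_fraction Fraction of near-duplicates to inject with
#'   [inject_duplicates()], in `[0, 1)` (recorded here, applied separately).
#' @param seed Integer RNG seed.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_samples, n_classes = 28L, image_size = 64L,
                           tail_exponent = 1.5, max_labels_per_sample = 5L,
                           mean_labels = 1.4, duplicate_fraction = 0,
                           seed = 1L) {
  .stop_if(!.is_count(n_samples, 0L), "`n_samples` must be a non-negative integer")
  .stop_if(!.is_count(n_classes, 2L), "`n_classes` must be an integer >= 2")
  .stop_if(!.is_count(image_size, 16L), "`image_size` must be an integer >= 16")
  .stop_if(!is.numeric(tail_exponent) || length(tail_exponent) != 1L ||
             tail_exponent <= 0, "`tail_exponent` must be positive")
  .stop_if(!.is_count(max_labels_per_sample, 1L),
           "`max_labels_per_sample` must be an integer >= 1")
  .stop_if(!is.numeric(mean_labels) || mean_labels <= 0,
           "`mean_labels` must be positive")
  .stop_if(!is.numeric(duplicate_fraction) || duplicate_fraction < 0 ||
             duplicate_fraction >= 1, "`duplicate_fraction` must lie in [0, 1)")
  structure(
    list(n_samples = as.integer(n_samples), n_classes = as.integer(n_classes),
         image_size = as.integer(image_size), tail_exponent = tail_exponent,
         max_labels_per_sample = as.integer(max_labels_per_sample),
         mean_labels = mean_labels, duplicate_fraction = duplicate_fraction,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Configured per-class marginal frequencies of a synthetic spec
#'
#' Power-law marginals `q_c` proportional to `c^-tail_exponent`, scaled so
#' the expected label count per sample is `mean_labels` and capped at 0.9.
#'
#' @param spec A `"synthetic_spec"`.
#' @return Numeric vector of length `n_classes`.
#' @export
class_marginals <- function(spec) {
  .stop_if(!inherits(spec, "synthetic_spec"), "`spec` must be a synthetic_spec")
  p <- seq_len(spec$n_classes)^(-spec$tail_exponent)
  pmin(spec$mean_labels * p / sum(p), 0.9)
}

# Render the blob motif canvas of one class: a class-specific number, size
# and brightness of Gaussian blobs at class-specific (seeded) positions.
# Classes differ jointly in blob count (2-6), blob scale (3 tiers) and peak
# intensity, so global pooled statistics separate them.
.motif_canvas <- function(class_idx, size, n_classes) {
  n_blobs <- 2L + (class_idx - 1L) %% 5L
  sigma <- size * (0.03 + 0.05 * (((class_idx - 1L) %/% 5L) %% 3L))
  amp <- 140 + 100 * (class_idx - 1L) / max(n_classes - 1L, 1L)
  cx <- stats::runif(n_blobs, 0.15 * size, 0.85 * size)
  cy <- stats::runif(n_blobs, 0.15 * size, 0.85 * size)
  .blob_canvas(size, cx, cy, sigma, amp)
}

.blob_canvas <- function(size, cx, cy, sigma, amp) {
  g <- seq_len(size) - 0.5
  canvas <- matrix(0, size, size)
  for (b in seq_along(cx)) {
    canvas <- canvas + amp * exp(-(outer((g - cx[b])^2, (g - cy[b])^2, "+")) /
                                   (2 * sigma^2))
  }
  canvas
}

# Toroidal integer shift of a square matrix.
.shift_canvas <- function(canvas, dx, dy) {
  s <- nrow(canvas)
  ri <- ((seq_len(s) - 1L - dx) %% s) + 1L
  ci <- ((seq_len(s) - 1L - dy) %% s) + 1L
  canvas[ri, ci]
}

.finalize_channel <- function(x) {
  x <- round(.clamp(x, 0, .INTENSITY_MAX))
  storage.mode(x) <- "integer"
  x
}

#' Generate a synthetic long-tail RGBY dataset
#'
#' Draws multi-label samples according to a [synthetic_spec()]: labels are
#' sampled independently per class from the power-law marginals (resampling
#' empty label vectors, truncating to `max_labels_per_sample` by dropping
#' the most frequent classes first), and each class renders a deterministic
#' Gaussian-blob motif into the green (protein) channel at a per-sample
#' jittered position.  The red (microtubules), blue (nucleus) and yellow
#' (reticulum) channels carry class-independent structures shared across
#' samples, shifted coherently with the sample and overlaid with a faint
#' copy of the green signal, so channels are spatially correlated the way
#' counterstains are.  Gaussian pixel noise is added everywhere and
#' intensities are quantized to integers in `[0, 255]`, making generation
#' byte-reproducible for a fixed seed.
#'
#' @param spec A `"synthetic_spec"`.
#' @return An object of class `"rgby_dataset"`: list with
#'   * `samples`: list of samples, each with `id`, `channels` (named list
#'     `red`, `green`, `blue`, `yellow` of integer matrices), `labels`
#'     (binary vector of length `n_classes`) and `placements` (data frame
#'     logging the class motifs drawn and their offsets and gains);
#'   * `label_matrix`: `n_samples x n_classes` binary matrix;
#'   * `class_counts`: per-class positive counts (its column sums);
#'   * `spec`: the generating spec.
#' @export
generate_dataset <- function(spec) {
  .stop_if(!inherits(spec, "synthetic_spec"), "`spec` must be a synthetic_spec")
  n <- spec$n_samples
  C <- spec$n_classes
  s <- spec$image_size
  q <- class_marginals(spec)
  .with_seed(spec$seed, {
    motifs <- lapply(seq_len(C), .motif_canvas, size = s, n_classes = C)
    context <- list(  # shared class-independent structures per stain
      red = .blob_canvas(s, seq(0.2, 0.8, length.out = 7L) * s,
                         seq(0.8, 0.2, length.out = 7L) * s,
                         sigma = 0.03 * s, amp = 120),
      blue = .blob_canvas(s, stats::runif(6L, 0.1 * s, 0.9 * s),
                          stats::runif(6L, 0.1 * s, 0.9 * s),
                          sigma = 0.08 * s, amp = 170),
      yellow = .blob_canvas(s, stats::runif(5L, 0.1 * s, 0.9 * s),
                            stats::runif(5L, 0.1 * s, 0.9 * s),
                            sigma = 0.05 * s, amp = 110)
    )
    Y <- matrix(0L, n, C)
    samples <- vector("list", n)
    max_shift <- max(1L, s %/% 8L)
    for (i in seq_len(n)) {
      labels <- integer(C)
      repeat {
        labels <- as.integer(stats::runif(C) < q)
        if (sum(labels) >= 1L) break
      }
      if (sum(labels) > spec$max_labels_per_sample) {
        # drop surplus labels starting from the most frequent classes
        set <- which(labels == 1L)
        keep <- utils::tail(set, spec$max_labels_per_sample)
        labels[] <- 0L; labels[keep] <- 1L
      }
      Y[i, ] <- labels
      set <- which(labels == 1L)
      gdx <- sample.int(2L * max_shift + 1L, 1L) - max_shift - 1L
      gdy <- sample.int(2L * max_shift + 1L, 1L) - max_shift - 1L
      green <- matrix(0, s, s)
      placements <- data.frame(class = set - 1L, dx = 0L, dy = 0L, gain = 0)
      for (k in seq_along(set)) {
        dx <- sample.int(2L * max_shift + 1L, 1L) - max_shift - 1L
        dy <- sample.int(2L * max_shift + 1L, 1L) - max_shift - 1L
        gain <- stats::runif(1L, 0.8, 1.2)
        green <- green + gain * .shift_canvas(motifs[[set[k]]], dx, dy)
        placements$dx[k] <- dx; placements$dy[k] <- dy
        placements$gain[k] <- gain
      }
      # faint sample-specific debris per channel (autofluorescent specks):
      # distinguishes individual cells, so perceptual hashes of independent
      # samples stay far apart while near-copies still collide
      debris <- function() .blob_canvas(s, stats::runif(4L, 1, s),
                                        stats::runif(4L, 1, s),
                                        sigma = 0.05 * s,
                                        amp = stats::runif(1L, 50, 90))
      chans <- list(red = NULL, green = NULL, blue = NULL, yellow = NULL)
      for (stain in c("red", "blue", "yellow")) {
        base <- stats::runif(1L, 0.7, 1.3) *
          .shift_canvas(context[[stain]], gdx, gdy) + 0.15 * green
        chans[[stain]] <- .finalize_channel(base + debris() +
                                              stats::rnorm(s * s, 0, 6))
      }
      chans$green <- .finalize_channel(
        green + 0.2 * .shift_canvas(context$blue, gdx, gdy) + debris() +
          stats::rnorm(s * s, 0, 6))
      samples[[i]] <- list(id = sprintf("sample_%05d", i), channels = chans,
                           labels = labels, placements = placements)
    }
    structure(
      list(samples = samples, label_matrix = Y,
           class_counts = as.integer(colSums(Y)), spec = spec),
      class = "rgby_dataset"
    )
  })
}

#' @export
print.rgby_dataset <- function(x, ...) {
  cat(sprintf("Synthetic RGBY dataset: %d samples, %d classes, %dx%d px\n",
              length(x$samples), x$spec$n_classes, x$spec$image_size,
              x$spec$image_size))
  cat("class counts:", paste(x$class_counts, collapse = " "), "\n")
  invisible(x)
}

#' Label matrix of a dataset
#'
#' @param dataset An `"rgby_dataset"`.
#' @return `n x n_classes` binary integer matrix with sample ids as row
#'   names.
#' @export
label_matrix <- function(dataset) {
  .stop_if(!inherits(dataset, "rgby_dataset"), "`dataset` must be an rgby_dataset")
  Y <- dataset$label_matrix
  rownames(Y) <- vapply(dataset$samples, `[[`, character(1), "id")
  Y
}

#' Inject near-duplicate samples into a dataset
#'
#' Appends `round(duplicate_fraction * n)` near-copies of randomly chosen
#' existing samples, each copy perturbed by bounded uniform integer noise of
#' at most `perturbation_amplitude` intensity units per pixel, carrying a
#' fresh id and the source's exact label vector.  The returned map links
#' each injected id to its source and is the ground truth against which
#' hash-based deduplication ([deduplicate()]) is validated.
#'
#' @param dataset An `"rgby_dataset"`.
#' @param duplicate_fraction Fraction of the current size to inject, in
#'   `[0, 1)`.
#' @param perturbation_amplitude Maximum absolute pixel perturbation,
#'   `>= 0`; 0 yields exact copies.
#' @param seed Integer RNG seed.
#' @return List with `dataset` (the augmented `"rgby_dataset"`) and
#'   `duplicate_map` (data frame with columns `duplicate_id`, `source_id`).
#' @export
inject_duplicates <- function(dataset, duplicate_fraction,
                              perturbation_amplitude = 0, seed = 1L) {
  .stop_if(!inherits(dataset, "rgby_dataset"), "`dataset` must be an rgby_dataset")
  .stop_if(!is.numeric(duplicate_fraction) || duplicate_fraction < 0 ||
             duplicate_fraction >= 1, "`duplicate_fraction` must lie in [0, 1)")
  .stop_if(!is.numeric(perturbation_amplitude) || perturbation_amplitude < 0,
           "`perturbation_amplitude` must be non-negative")
  n <- length(dataset$samples)
  n_dup <- round(duplicate_fraction * n)
  if (n_dup == 0L) {
    return(list(dataset = dataset,
                duplicate_map = data.frame(duplicate_id = character(),
                                           source_id = character())))
  }
  .with_seed(seed, {
    src <- sample.int(n, n_dup, replace = n_dup > n)
    new_samples <- vector("list", n_dup)
    for (j in seq_len(n_dup)) {
      sample_j <- dataset$samples[[src[j]]]
      chans <- lapply(sample_j$channels, function(ch) {
        if (perturbation_amplitude > 0) {
          noise <- round(stats::runif(length(ch), -perturbation_amplitude,
                                      perturbation_amplitude))
          ch <- .finalize_channel(ch + noise)
        }
        ch
      })
      new_samples[[j]] <- list(id = sprintf("%s_dup%03d", sample_j$id, j),
                               channels = chans, labels = sample_j$labels,
                               placements = sample_j$placements)
    }
    Y_new <- do.call(rbind, lapply(new_samples, `[[`, "labels"))
    out <- dataset
    out$samples <- c(dataset$samples, new_samples)
    out$label_matrix <- rbind(dataset$label_matrix, Y_new)
    out$class_counts <- as.integer(colSums(out$label_matrix))
    list(dataset = out,
         duplicate_map = data.frame(
           duplicate_id = vapply(new_samples, `[[`, character(1), "id"),
           source_id = vapply(dataset$samples[src], `[[`, character(1), "id")))
  })
}
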