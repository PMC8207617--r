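#' Per-class positive sample counts
#'
#' Column sums of a binary label matrix: `counts[c]` is the number of
#' samples whose bit for class `c` is set (the `n_c` entering the
#' effective-number weights).  Because samples are multi-labelled the counts
#' sum to at least the number of samples.
#'
#' @param labels `N x C` binary label matrix (or an `"rgby_dataset"`).
#' @return Integer vector of length `C`.
#' @export
class_count_table <- function(labels) {
  if (inherits(labels, "rgby_dataset")) labels <- labels$label_matrix
  .stop_if(!is.matrix(labels) || any(labels != 0 & labels != 1),
           "`labels` must be a binary matrix")
  as.integer(colSums(labels))
}

#' Perceptual average-hash fingerprint of an image
#'
#' Computes an average hash: the image is block-averaged to an
#' `hash_size x hash_size` grid and each cell contributes one bit, set when
#' the cell mean exceeds the grid mean.  Multi-channel images (a list of
#' matrices) are hashed per channel and the bits concatenated, giving
#' `4 * hash_size^2 = 256` bits for an RGBY sample at the default size.
#' The hash is deterministic and stable under small intensity
#' perturbations, so near-duplicates land within a small Hamming distance.
#'
#' @param image Numeric matrix, or list of equally sized matrices
#'   (channels), or an element of `rgby_dataset$samples`.
#' @param hash_size Side of the averaging grid (default 8).
#' @return Logical vector of hash bits, length `n_channels * hash_size^2`.
#' @export
compute_image_hash <- function(image, hash_size = 8L) {
  if (is.list(image) && !is.null(image$channels)) image <- image$channels
  if (is.matrix(image)) image <- list(image)
  .stop_if(!is.list(image) || length(image) == 0L ||
             !all(vapply(image, is.matrix, logical(1))),
           "`image` must be a matrix or a list of channel matrices")
  .stop_if(any(vapply(image, length, integer(1)) == 0L), "empty image")
  unlist(lapply(image, function(ch) {
    grid <- .block_mean(ch, hash_size)
    as.vector(grid > mean(grid))
  }), use.names = FALSE)
}

#' Hamming distance between two hash fingerprints
#'
#' @param h1,h2 Logical bit vectors of equal length.
#' @return Integer number of differing bits.
#' @export
hamming_distance <- function(h1, h2) {
  .stop_if(length(h1) != length(h2), "fingerprints must have equal length")
  sum(xor(h1, h2))
}

#' Remove near-duplicate samples by perceptual hashing
#'
#' Greedy deduplication in id order: samples are scanned sorted by id, and a
#' sample is removed when its fingerprint lies within `hamming_threshold`
#' bits of any already-kept sample (so the first member of each duplicate
#' group survives).  At threshold 0 only bit-exact fingerprints are
#' collapsed and samples with a unique fingerprint are never removed.
#'
#' The default threshold of 16 bits corresponds to 4 bits per channel of
#' the 256-bit RGBY fingerprint -- permissive enough for "extremely
#' similar" perturbed copies while leaving independent samples (typically
#' >40 bits apart) untouched.
#'
#' @param dataset An `"rgby_dataset"`.
#' @param hamming_threshold Maximum Hamming distance treated as duplicate,
#'   `>= 0`.
#' @param hash_size Grid side passed to [compute_image_hash()].
#' @return List with `dataset` (the kept `"rgby_dataset"`, counts
#'   recomputed), `removed_ids` (character vector) and `report` (data frame
#'   with columns `removed_id`, `kept_id`, `hamming`).
#' @export
deduplicate <- function(dataset, hamming_threshold = 16L, hash_size = 8L) {
  .stop_if(!inherits(dataset, "rgby_dataset"), "`dataset` must be an rgby_dataset")
  .stop_if(!is.numeric(hamming_threshold) || hamming_threshold < 0,
           "`hamming_threshold` must be non-negative")
  n <- length(dataset$samples)
  if (n == 0L) {
    return(list(dataset = dataset, removed_ids = character(),
                report = data.frame(removed_id = character(),
                                    kept_id = character(),
                                    hamming = integer())))
  }
  ids <- vapply(dataset$samples, `[[`, character(1), "id")
  ord <- order(ids)
  H <- do.call(rbind, lapply(dataset$samples[ord], compute_image_hash,
                             hash_size = hash_size)) * 1
  # pairwise Hamming distances via inner products on 0/1 bit rows
  ones <- rowSums(H)
  D <- outer(ones, ones, "+") - 2 * tcrossprod(H)
  keep <- logical(n)
  removed_id <- kept_id <- character(0)
  hamming <- integer(0)
  for (i in seq_len(n)) {
    kept_idx <- which(keep)
    near <- kept_idx[D[i, kept_idx] <= hamming_threshold]
    if (length(near) == 0L) {
      keep[i] <- TRUE
    } else {
      j <- near[which.min(D[i, near])]
      removed_id <- c(removed_id, ids[ord[i]])
      kept_id <- c(kept_id, ids[ord[j]])
      hamming <- c(hamming, as.integer(round(D[i, j])))
    }
  }
  kept_ord <- sort(ord[keep])
  out <- dataset
  out$samples <- dataset$samples[kept_ord]
  out$label_matrix <- dataset$label_matrix[kept_ord, , drop = FALSE]
  out$class_counts <- as.integer(colSums(out$label_matrix))
  list(dataset = out, removed_ids = removed_id,
       report = data.frame(removed_id = removed_id, kept_id = kept_id,
                           hamming = hamming))
}

#' Minority-class oversampling indices
#'
#' Builds a sampling multiset that replicates samples carrying rare labels
#' "a few times" without ballooning the dataset: a sample whose rarest
#' label has fewer positives than the median class count is replicated
#' `floor(min(target_ratio, median_count / rarest_count))` times (at least
#' once); samples carrying only majority labels appear exactly once.  The
#' cap keeps replication moderate -- oversampling too aggressively causes
#' the network to overfit the few minority samples.
#'
#' @param counts Per-class positive counts (see [class_count_table()]).
#' @param labels `N x C` binary label matrix the counts were derived from.
#' @param target_ratio Maximum replication factor per sample, `>= 1`
#'   (default 4).
#' @return Integer vector of sample indices (the sampling multiset); every
#'   original index appears at least once.
#' @export
oversample_minority <- function(counts, labels, target_ratio = 4) {
  .stop_if(!is.matrix(labels) || any(labels != 0 & labels != 1),
           "`labels` must be a binary matrix")
  .stop_if(length(counts) != ncol(labels),
           "`counts` length must match the number of classes")
  .stop_if(!is.numeric(target_ratio) || length(target_ratio) != 1L ||
             target_ratio < 1, "`target_ratio` must be >= 1")
  med <- stats::median(counts[counts > 0])
  reps <- vapply(seq_len(nrow(labels)), function(i) {
    set <- which(labels[i, ] == 1L)
    if (length(set) == 0L) return(1L)
    rarest <- min(counts[set])
    if (rarest >= med || rarest == 0L) return(1L)
    max(1L, as.integer(floor(min(target_ratio, med / rarest))))
  }, integer(1))
  rep(seq_len(nrow(labels)), times = reps)
}

#' Multi-label stratified k-fold assignment
#'
#' Iterative stratification: classes are processed from rarest to most
#' frequent, and each still-unassigned sample of the current class goes to
#' the fold with the largest remaining demand for that class (ties broken
#' toward the fold with the most remaining capacity, then at random under
#' the supplied seed).  Fold sizes are capped at their balanced targets, so
#' the folds partition the samples with sizes differing by at most 1.  For
#' every class with at least `n_folds` positives the per-fold positive
#' counts then sit within +-1 of perfect proportionality.
#'
#' @param labels `N x C` binary label matrix.
#' @param n_folds Number of folds, `>= 2`.
#' @param seed Integer RNG seed; the assignment is deterministic given
#'   `labels` and `seed`.
#' @return An object of class `"fold_assignment"`: list with `fold`
#'   (integer vector of fold indices in `1..n_folds`, one per sample) and
#'   `n_folds`.  Warns when a class has fewer positives than folds.
#' @export
stratified_multilabel_split <- function(labels, n_folds, seed = 1L) {
  .stop_if(!is.matrix(labels) || any(labels != 0 & labels != 1),
           "`labels` must be a binary matrix")
  .stop_if(!.is_count(n_folds, 2L), "`n_folds` must be an integer >= 2")
  n <- nrow(labels); C <- ncol(labels)
  .stop_if(n < n_folds, "need at least one sample per fold")
  counts <- colSums(labels)
  .stop_if(any(counts == 0L), "every class must have at least one positive sample")
  if (any(counts < n_folds)) {
    warning(sum(counts < n_folds),
            " class(es) have fewer positive samples than folds")
  }
  .with_seed(seed, {
    fold <- integer(n)                       # 0 = unassigned
    desired <- outer(rep(1 / n_folds, n_folds), counts)   # folds x classes
    cap <- rep(floor(n / n_folds), n_folds)
    cap[seq_len(n %% n_folds)] <- cap[seq_len(n %% n_folds)] + 1L
    size <- integer(n_folds)
    remaining <- colSums(labels)
    for (cls in order(counts)) {
      todo <- which(fold == 0L & labels[, cls] == 1L)
      for (i in todo[sample.int(length(todo))]) {
        open <- which(size < cap)
        d <- desired[open, cls]
        best <- open[d == max(d)]
        if (length(best) > 1L) {
          room <- cap[best] - size[best]
          best <- best[room == max(room)]
          if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
        }
        fold[i] <- best
        size[best] <- size[best] + 1L
        set <- which(labels[i, ] == 1L)
        desired[best, set] <- desired[best, set] - 1
      }
    }
    # samples with no labels would be unreachable, but labels are validated
    # to be non-empty per class; any stragglers fill the open folds
    for (i in which(fold == 0L)) {
      open <- which(size < cap)
      best <- open[which.max(cap[open] - size[open])]
      fold[i] <- best
      size[best] <- size[best] + 1L
    }
    fold <- .repair_fold_balance(labels, fold, n_folds)
    structure(list(fold = fold, n_folds = as.integer(n_folds)),
              class = "fold_assignment")
  })
}

# Size-preserving repair of per-class fold balance.  Greedy rare-first
# assignment leaves the most frequent classes (placed last, against nearly
# full folds) a few positives off their proportional share; this pass swaps
# sample pairs between the most over- and under-represented folds of the
# worst class whenever the swap strictly lowers the total squared deviation
# of per-fold class counts from proportionality.  Swapping keeps fold sizes
# untouched.
.repair_fold_balance <- function(labels, fold, n_folds, max_iter = NULL) {
  C <- ncol(labels)
  n_c <- colSums(labels)
  target <- outer(tabulate(fold, n_folds) / nrow(labels), n_c)  # folds x C
  counts <- t(sapply(seq_len(n_folds), function(j)
    colSums(labels[fold == j, , drop = FALSE])))
  if (is.null(max_iter)) max_iter <- 20L * C
  checked <- n_c >= n_folds
  for (iter in seq_len(max_iter)) {
    dev <- counts - target
    worst <- abs(dev) * rep(checked, each = n_folds)
    if (max(worst) <= 1) break
    cls <- which.max(apply(worst, 2L, max))
    j_hi <- which.max(dev[, cls])
    j_lo <- which.min(dev[, cls])
    A <- which(fold == j_hi & labels[, cls] == 1L)
    B <- which(fold == j_lo & labels[, cls] == 0L)
    if (length(A) == 0L || length(B) == 0L) break
    diff_dev <- dev[j_hi, ] - dev[j_lo, ]
    score_a <- drop(labels[A, , drop = FALSE] %*% diff_dev)
    score_b <- drop(labels[B, , drop = FALSE] %*% diff_dev)
    a_try <- A[order(-score_a)][seq_len(min(5L, length(A)))]
    b_try <- B[order(score_b)][seq_len(min(5L, length(B)))]
    best_gain <- 0; best_pair <- NULL
    for (a in a_try) for (b in b_try) {
      v <- labels[a, ] - labels[b, ]
      gain <- sum(2 * v * diff_dev - 2 * v^2)
      if (gain > best_gain + 1e-9) { best_gain <- gain; best_pair <- c(a, b) }
    }
    if (is.null(best_pair)) break
    a <- best_pair[1L]; b <- best_pair[2L]
    counts[j_hi, ] <- counts[j_hi, ] - labels[a, ] + labels[b, ]
    counts[j_lo, ] <- counts[j_lo, ] + labels[a, ] - labels[b, ]
    fold[a] <- j_lo
    fold[b] <- j_hi
  }
  fold
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("Fold assignment over", length(x$fold), "samples:\n")
  print(table(fold = x$fold))
  invisible(x)
}

#' Resize and randomly crop a four-channel sample
#'
#' Training-time input policy for full-sized microscopy images: square
#' inputs with side up to 2048 are resized (bilinear) to 768 and a 512 x
#' 512 patch is cropped; larger inputs are resized to 1024 and cropped to
#' 768.  The crop offset is drawn uniformly and applied identically to all
#' channels, so the four stains stay pixel-aligned.
#'
#' @param channels Named list of square channel matrices of identical size
#'   (or an element of `rgby_dataset$samples`).
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (set the seed beforehand for a reproducible patch).
#' @return List of cropped channel matrices (side 512 or 768).
#' @export
resize_and_crop <- function(channels, seed = NULL) {
  if (is.list(channels) && !is.null(channels$channels)) {
    channels <- channels$channels
  }
  .stop_if(!is.list(channels) || length(channels) == 0L ||
             !all(vapply(channels, is.matrix, logical(1))),
           "`channels` must be a list of channel matrices")
  sides <- vapply(channels, function(ch) c(nrow(ch), ncol(ch)), integer(2))
  .stop_if(any(sides[1, ] != sides[2, ]), "input images must be square")
  .stop_if(length(unique(sides[1, ])) != 1L,
           "all channels must have identical dimensions")
  side <- sides[1, 1]
  if (side <= 2048L) { resize_to <- 768L; crop_to <- 512L }
  else { resize_to <- 1024L; crop_to <- 768L }
  draw <- function() {
    ox <- sample.int(resize_to - crop_to + 1L, 1L)
    oy <- sample.int(resize_to - crop_to + 1L, 1L)
    c(ox, oy)
  }
  off <- if (is.null(seed)) draw() else .with_seed(seed, draw())
  lapply(channels, function(ch) {
    r <- EBImage::resize(ch, w = resize_to, h = resize_to)
    r[off[1]:(off[1] + crop_to - 1L), off[2]:(off[2] + crop_to - 1L)]
  })
}
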