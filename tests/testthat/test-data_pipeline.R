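test_that("class count table equals per-class positive tallies", {
  y <- matrix(c(1, 0, 1,
                1, 1, 0), 3, 2)
  expect_identical(class_count_table(y), c(2L, 2L))
  expect_gte(sum(class_count_table(small_dataset())), 120)  # multi-label
})

test_that("image hashes are deterministic and robust to light perturbation", {
  ds <- small_dataset()
  h1 <- compute_image_hash(ds$samples[[1]])
  expect_length(h1, 4 * 64)
  expect_identical(h1, compute_image_hash(ds$samples[[1]]))
  expect_identical(hamming_distance(h1, h1), 0L)
  # light uniform noise moves few bits (<= 10% of the fingerprint)
  set.seed(31)
  perturbed <- lapply(ds$samples[[1]]$channels, function(ch)
    ch + matrix(sample(c(-1L, 0L, 1L), length(ch), replace = TRUE),
                nrow(ch)))
  h2 <- compute_image_hash(perturbed)
  expect_lte(hamming_distance(h1, h2), 0.1 * length(h1))
  expect_error(compute_image_hash(matrix(numeric(0), 0, 0)), "empty")
})

test_that("independent samples sit far apart in Hamming distance", {
  ds <- small_dataset()
  set.seed(32)
  H <- lapply(ds$samples, compute_image_hash)
  d <- replicate(100, {
    ij <- sample(length(H), 2)
    hamming_distance(H[[ij[1]]], H[[ij[2]]])
  })
  # empirical distribution clears the dedup threshold (16 bits)
  expect_gt(min(d), 16)
  expect_gt(mean(d), 40)
})

test_that("dedup removes exactly the injected exact copies at threshold 0", {
  ds <- generate_dataset(synthetic_spec(100, n_classes = 8, image_size = 32,
                                        seed = 13))
  inj <- inject_duplicates(ds, 0.2, perturbation_amplitude = 0, seed = 5)
  res <- deduplicate(inj$dataset, hamming_threshold = 0)
  # brute-force pixel-equality oracle of duplicate pairs
  expect_identical(length(res$removed_ids), 20L)
  # pair coverage: every injected duplicate pair has exactly one survivor
  kept_ids <- vapply(res$dataset$samples, `[[`, character(1), "id")
  for (k in seq_len(nrow(inj$duplicate_map))) {
    pair <- unlist(inj$duplicate_map[k, ])
    expect_identical(sum(pair %in% kept_ids), 1L)
  }
  # an all-unique dataset loses nothing
  res_u <- deduplicate(ds, hamming_threshold = 0)
  expect_length(res_u$removed_ids, 0)
  expect_identical(res_u$dataset$label_matrix, ds$label_matrix)
  # the report names each removal and its kept twin
  expect_identical(nrow(res$report), 20L)
  expect_true(all(res$report$hamming == 0L))
})

test_that("dedup recall on perturbed duplicates meets the default threshold", {
  ds <- generate_dataset(synthetic_spec(100, n_classes = 8, image_size = 32,
                                        seed = 14))
  inj <- inject_duplicates(ds, 0.2, perturbation_amplitude = 2, seed = 6)
  res <- deduplicate(inj$dataset)          # default 16-bit threshold
  removed_dups <- intersect(res$removed_ids, inj$duplicate_map$duplicate_id)
  kept_ids <- vapply(res$dataset$samples, `[[`, character(1), "id")
  covered <- sum(!(inj$duplicate_map$duplicate_id %in% kept_ids &
                     inj$duplicate_map$source_id %in% kept_ids))
  expect_gte(covered / nrow(inj$duplicate_map), 0.95)
  # no false removals of unique samples
  expect_lte(length(res$removed_ids), nrow(inj$duplicate_map))
})

test_that("minority oversampling follows the median-capped replication rule", {
  # toy two-class table: counts {100, 10}, rare-only samples replicated
  # floor(min(3, 55/10)) = 3 times
  y <- rbind(matrix(rep(c(1, 0), 100), ncol = 2, byrow = TRUE),
             matrix(rep(c(0, 1), 10), ncol = 2, byrow = TRUE))
  counts <- class_count_table(y)
  idx <- oversample_minority(counts, y, target_ratio = 3)
  tab <- tabulate(idx, nrow(y))
  expect_true(all(tab[1:100] == 1L))       # majority-only: once
  expect_true(all(tab[101:110] == 3L))     # rare-only: three times
  # every original index covered at least once, labels preserved by indexing
  expect_true(all(tab >= 1L))
  expect_identical(y[idx[1], ], y[1, ])
  # balanced counts or ratio 1: identity multiset
  yb <- matrix(1, 6, 2)
  expect_identical(oversample_minority(class_count_table(yb), yb, 4), 1:6)
  expect_identical(oversample_minority(counts, y, target_ratio = 1), 1:110)
  expect_error(oversample_minority(counts, y, target_ratio = 0.5), ">= 1")
})

test_that("stratified split balances folds and per-class positives", {
  # single-label balanced 2-class, 100 samples, 5 folds: exactly 10
  # positives of each class per fold
  y <- rbind(matrix(rep(c(1, 0), 50), ncol = 2, byrow = TRUE),
             matrix(rep(c(0, 1), 50), ncol = 2, byrow = TRUE))
  f <- stratified_multilabel_split(y, 5, seed = 2)
  expect_identical(sort(unique(f$fold)), 1:5)
  for (c in 1:2) {
    expect_true(all(tabulate(f$fold[y[, c] == 1], 5) == 10L))
  }
  # 28-class long tail: per-class fold counts within +-1 of n_c / 5
  ds <- generate_dataset(synthetic_spec(1000, seed = 7))
  Y <- ds$label_matrix
  fa <- suppressWarnings(stratified_multilabel_split(Y, 5, seed = 1))
  sizes <- tabulate(fa$fold, 5)
  expect_lte(max(sizes) - min(sizes), 1L)  # partition balance
  expect_identical(sum(sizes), nrow(Y))    # disjoint and exhaustive
  counts <- class_count_table(Y)
  for (c in which(counts >= 5)) {
    per_fold <- tabulate(fa$fold[Y[, c] == 1], 5)
    expect_lte(max(abs(per_fold - counts[c] / 5)), 1)
  }
  # determinism and warning for ultra-rare classes
  expect_identical(fa, suppressWarnings(stratified_multilabel_split(Y, 5, seed = 1)))
  if (any(counts < 5)) {
    expect_warning(stratified_multilabel_split(Y, 5, seed = 1), "fewer")
  }
  expect_error(stratified_multilabel_split(Y[0, , drop = FALSE], 5), "at least")
})

test_that("resize and crop follows the two-tier policy with aligned channels", {
  # synthetic full-sized inputs: a coordinate marker checks pixel alignment
  mk <- function(side) {
    base <- matrix(0, side, side)
    base[side %/% 3, side %/% 2] <- 255
    list(red = base, green = base * 0.5, blue = base, yellow = base)
  }
  p2048 <- resize_and_crop(mk(2048), seed = 9)
  expect_identical(dim(p2048$green), c(512L, 512L))
  big <- mk(3072)[c("green", "blue")]      # two channels keep memory modest
  p3072 <- resize_and_crop(big, seed = 9)
  expect_identical(dim(p3072$green), c(768L, 768L))
  # channel synchrony: the marker lands at the same coordinates everywhere
  pos <- which(p2048$red == max(p2048$red), arr.ind = TRUE)[1, ]
  for (ch in p2048) {
    if (max(ch) > 0) {
      expect_identical(which(ch == max(ch), arr.ind = TRUE)[1, ], pos)
    }
  }
  # fixed seed reproduces the identical patch
  expect_identical(resize_and_crop(mk(2048), seed = 9), p2048)
  bad <- list(red = matrix(0, 10, 12))
  expect_error(resize_and_crop(bad), "square")
})
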