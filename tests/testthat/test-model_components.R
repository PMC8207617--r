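test_that("4-channel input adaptation preserves and extends 3-channel kernels", {
  set.seed(7)
  w3 <- array(rnorm(8 * 3 * 3 * 3), dim = c(8, 3, 3, 3))
  for (strat in c("zero", "mean_rgb", "copy_red")) {
    w4 <- adapt_input_layer(w3, strat)
    expect_identical(dim(w4), c(8L, 4L, 3L, 3L))
    expect_identical(w4[, 1:3, , ], w3)   # first three kernels untouched
  }
  # zero strategy: forward on (RGB, arbitrary Y) equals the 3-channel
  # forward on RGB exactly -- simulate one output position as a dot product
  w4 <- adapt_input_layer(w3, "zero")
  x_rgb <- array(rnorm(3 * 3 * 3), dim = c(3, 3, 3))
  x_y <- array(rnorm(9), dim = c(1, 3, 3))
  for (f in 1:8) {
    out3 <- sum(w3[f, , , ] * x_rgb)
    out4 <- sum(w4[f, 1:3, , ] * x_rgb) + sum(w4[f, 4, , ] * x_y[1, , ])
    expect_identical(out4, out3)
  }
  # mean_rgb on identical kernels reproduces the kernel
  wk <- array(rep(rnorm(9), each = 2 * 3), dim = c(2, 3, 3, 3))
  wk[, 1, , ] <- wk[, 2, , ] <- wk[, 3, , ]
  w4 <- adapt_input_layer(wk, "mean_rgb")
  expect_equal(w4[, 4, , ], wk[, 1, , ])
  # copy_red is bitwise equal to the first channel
  w4 <- adapt_input_layer(w3, "copy_red")
  expect_identical(w4[, 4, , ], w3[, 1, , ])
  expect_error(adapt_input_layer(array(0, c(4, 4, 3, 3))), "3 input channels")
})

test_that("ACP pooling concatenates spatial means and maxima", {
  set.seed(8)
  fm <- array(rnorm(6 * 5 * 7), dim = c(6, 5, 7))
  v <- acp_pool(fm)
  expect_length(v, 12)
  for (c in 1:6) {
    expect_equal(v[c], mean(fm[c, , ]))
    expect_equal(v[6 + c], max(fm[c, , ]))
  }
  # output length depends only on the channel count
  expect_length(acp_pool(array(0, c(6, 1, 1))), 12)
  expect_length(acp_pool(array(0, c(6, 31, 2))), 12)
  # constant map: both halves equal the constant
  expect_equal(acp_pool(array(3.5, c(4, 9, 9))), rep(3.5, 8))
  expect_error(acp_pool(array(0, c(0, 2, 2))), "at least 1")
})

test_that("ACP pooling is channel-permutation equivariant and mean <= max", {
  set.seed(9)
  for (rep in 1:20) {
    C <- sample(2:10, 1)
    fm <- array(rnorm(C * 6 * 6), dim = c(C, 6, 6))
    v <- acp_pool(fm)
    expect_true(all(v[1:C] <= v[C + 1:C] + 1e-15))
    perm <- sample(C)
    vp <- acp_pool(fm[perm, , , drop = FALSE])
    expect_equal(vp, c(v[perm], v[C + perm]))
  }
})

test_that("classifier heads follow the buffering-layer contract", {
  # one buffering layer mirroring the 50-layer-backbone settings:
  # 4096 ACP features -> 1024 (0.5 dropout) -> 28
  spec <- head_spec(4096, buffering_sizes = 1024, dropout_rates = 0.5)
  h <- build_head(spec)
  expect_identical(h$dims, c(4096L, 1024L, 28L))
  expect_identical(h$n_parameters, (4096L + 1L) * 1024L + (1024L + 1L) * 28L)
  # no buffering: single linear map
  h0 <- build_head(head_spec(4096, n_classes = 28))
  expect_identical(h0$dims, c(4096L, 28L))
  expect_identical(h0$n_parameters, (4096L + 1L) * 28L)
  # two buffering layers (101-layer settings): 4096 -> 1024 with dropouts
  h2 <- build_head(head_spec(4096, buffering_sizes = c(4096, 1024),
                             dropout_rates = c(0.25, 0.5)))
  expect_identical(h2$dims, c(4096L, 4096L, 1024L, 28L))
  expect_error(head_spec(512, buffering_sizes = c(128, 256)), "decreasing")
  expect_error(head_spec(512, buffering_sizes = 128, dropout_rates = c(0.5, 0.5)),
               "length")
})

test_that("head forward matches a hand-rolled dense computation", {
  set.seed(10)
  h <- build_head(head_spec(6, buffering_sizes = 4,
                            dropout_rates = 0, n_classes = 3))
  x <- matrix(rnorm(12), 2, 6)
  manual <- pmax(x %*% t(h$layers[[1]]$W) +
                   matrix(h$layers[[1]]$b, 2, 4, byrow = TRUE), 0)
  manual <- manual %*% t(h$layers[[2]]$W) +
    matrix(h$layers[[2]]$b, 2, 3, byrow = TRUE)
  expect_equal(head_forward(h, x), manual)
  expect_error(head_forward(h, matrix(0, 2, 5)), "width")
})

test_that("hard sampler selects exactly the top-K losses", {
  expect_identical(hard_sample_select(c(0.1, 0.9, 0.5, 0.7), K = 2), c(2L, 4L))
  # K = B keeps everything and the mined loss is the plain mean
  l <- c(0.4, 0.2, 0.9)
  expect_identical(hard_sample_select(l, K = 3), 1:3)
  expect_equal(hard_mined_loss(l, K = 3), mean(l))
  # ties break toward the lower index
  expect_identical(hard_sample_select(c(0.5, 0.5, 0.5), K = 2), c(1L, 2L))
  # idempotence: top-K of the selected K is the same set
  set.seed(11)
  for (rep in 1:20) {
    l <- runif(12)
    K <- sample(1:12, 1)
    sel <- hard_sample_select(l, K)
    expect_identical(hard_sample_select(l[sel], K), seq_len(K))
  }
  expect_error(hard_sample_select(c(1, 2), K = 3), "K <= B")
  expect_error(hard_sample_select(c(1, 2), K = 0), "K <= B")
})

test_that("hard selection maximizes the summed loss over all K-subsets", {
  # exhaustive-subset oracle for every batch size up to 10
  set.seed(12)
  for (B in 2:10) {
    l <- runif(B)
    for (K in 1:B) {
      sel <- hard_sample_select(l, K)
      best <- max(combn(B, K, function(s) sum(l[s])))
      expect_equal(sum(l[sel]), best)
    }
  }
})
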