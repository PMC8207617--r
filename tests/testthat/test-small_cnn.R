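test_that("the compact CNN wires ACP pooling and the adapted input layer", {
  m <- small_cnn(12, n_classes = 5, conv_filters = 4, seed = 2)
  # ACP feature width is twice the filter count
  expect_identical(m$head$dims[1], 8L)
  # forward features match acp_pool applied to the conv feature map
  set.seed(3)
  x <- matrix(runif(4 * 144), 1)
  fwd <- protclass:::.cnn_forward(m, x)
  s1 <- 12 - 3 + 1
  fmap <- array(0, dim = c(4, s1, s1))
  for (f in 1:4) fmap[f, , ] <- matrix(pmax(fwd$relu_mask[, f] *
                                              (fwd$Ccols %*% m$Wc[f, ] + m$bc[f]), 0),
                                       s1, s1)
  expect_equal(as.vector(fwd$feat), acp_pool(fmap), tolerance = 1e-12)
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(42)
  side <- 8; n <- 6; C <- 4
  X <- matrix(runif(n * 4 * side^2), n)
  Y <- matrix(rbinom(n * C, 1, 0.4), n)
  w <- runif(C, 0.5, 2)
  K <- 4L
  m <- small_cnn(side, n_classes = C, conv_filters = 3, head_buffering = 4,
                 seed = 3)
  loss_of <- function(model) {
    f <- protclass:::.cnn_forward(model, X)
    ls <- per_sample_loss(bce_loss(f$probs, Y), w)
    mean(ls[hard_sample_select(ls, K)])
  }
  fwd <- protclass:::.cnn_forward(m, X)
  ls <- per_sample_loss(bce_loss(fwd$probs, Y), w)
  sel <- hard_sample_select(ls, K)
  G <- sweep(fwd$probs - Y, 2, w, "*") / length(sel)
  G[setdiff(seq_len(n), sel), ] <- 0
  vel <- list(Wc = m$Wc * 0, bc = m$bc * 0,
              head = lapply(m$head$layers, function(l)
                list(W = l$W * 0, b = l$b * 0)))
  upd <- protclass:::.cnn_backward_update(m, fwd, G, vel, c(1, 1), 0, 0)
  eps <- 1e-6
  check_block <- function(get, set, n_probe = 20) {
    vals <- get(m)
    probe <- sample(length(vals), min(n_probe, length(vals)))
    for (i in probe) {
      num <- (loss_of(set(m, i, eps)) - loss_of(set(m, i, -eps))) / (2 * eps)
      expect_equal((get(m) - get(upd))[i], num, tolerance = 1e-6)
    }
  }
  check_block(function(mod) mod$Wc,
              function(mod, i, d) { mod$Wc[i] <- mod$Wc[i] + d; mod })
  check_block(function(mod) mod$head$layers[[1]]$W,
              function(mod, i, d) {
                mod$head$layers[[1]]$W[i] <- mod$head$layers[[1]]$W[i] + d; mod
              })
  check_block(function(mod) mod$head$layers[[2]]$W,
              function(mod, i, d) {
                mod$head$layers[[2]]$W[i] <- mod$head$layers[[2]]$W[i] + d; mod
              })
})

test_that("training reduces the loss on a small separable problem", {
  set.seed(5)
  ds <- generate_dataset(synthetic_spec(160, n_classes = 4, image_size = 32,
                                        tail_exponent = 1, seed = 17))
  X <- cnn_input_matrix(ds, pool = 2)
  Y <- ds$label_matrix
  m <- small_cnn(attr(X, "side"), n_classes = 4, conv_filters = 6, seed = 1)
  trained <- train_small_cnn(m, X, Y, epochs = 6, batch_size = 32,
                             base_lr = 0.1, cycle_epochs = 3, seed = 1)
  expect_lt(tail(trained$history$loss, 1), trained$history$loss[1] * 0.9)
  # training is reproducible under a fixed seed
  trained2 <- train_small_cnn(m, X, Y, epochs = 6, batch_size = 32,
                              base_lr = 0.1, cycle_epochs = 3, seed = 1)
  expect_identical(trained$Wc, trained2$Wc)
  p <- predict_probs(trained, X)
  expect_identical(dim(p), c(160L, 4L))
  expect_true(all(p > 0 & p < 1))
})

test_that("E-loss weighting and hard mining shift training toward rare classes", {
  set.seed(6)
  ds <- generate_dataset(synthetic_spec(300, n_classes = 6, image_size = 32,
                                        tail_exponent = 2, seed = 19))
  X <- cnn_input_matrix(ds, pool = 2)
  Y <- ds$label_matrix
  counts <- class_count_table(Y)
  w <- suppressWarnings(eloss_weights(pmax(counts, 1L), alpha = 0.99))
  m <- small_cnn(attr(X, "side"), n_classes = 6, conv_filters = 6, seed = 2)
  plain <- train_small_cnn(m, X, Y, epochs = 6, batch_size = 32,
                           base_lr = 0.1, cycle_epochs = 3, seed = 2)
  mined <- train_small_cnn(m, X, Y, epochs = 6, batch_size = 32,
                           base_lr = 0.1, cycle_epochs = 3,
                           class_weights = w, hard_fraction = 0.5, seed = 2)
  rare <- which(counts == min(counts))[1]
  # the treated model pushes the rare class's mean probability on its
  # positives at least as high as the plain model does
  pos <- Y[, rare] == 1
  if (sum(pos) >= 2) {
    expect_gte(mean(predict_probs(mined, X)[pos, rare]),
               mean(predict_probs(plain, X)[pos, rare]) * 0.9)
  }
  expect_error(train_small_cnn(m, X, Y, epochs = 5, cycle_epochs = 2),
               "multiple")
})
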