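# A compact four-channel convolutional classifier, trained with plain R
# matrix algebra (im2col convolution + BLAS).  It is deliberately small: its
# job is to exercise the full imbalance-handling workflow -- 4-channel input
# adaptation, ACP pooling, buffering head, E-loss, hard example mining and
# cyclic schedules -- end-to-end at desk scale, not to compete with large
# pretrained backbones.

#' Flatten a dataset into CNN input rows
#'
#' Block-averages every channel by `pool` (the fixed downsampling stem of
#' the compact CNN), scales intensities to `[0, 1]` and concatenates the
#' four channels into one row per sample (channel-major, column-major
#' within a channel).
#'
#' @param dataset An `"rgby_dataset"`.
#' @param pool Integer downsampling factor of the stem (default 4; a 64 px
#'   image becomes a 16 x 16 x 4 input).
#' @return `N x (4 * side^2)` numeric matrix with sample ids as row names
#'   and the input `side` stored in `attr(, "side")`.
#' @export
cnn_input_matrix <- function(dataset, pool = 4L) {
  .stop_if(!inherits(dataset, "rgby_dataset"), "`dataset` must be an rgby_dataset")
  .stop_if(!.is_count(pool, 1L), "`pool` must be a positive integer")
  s <- dataset$spec$image_size
  side <- s %/% pool
  .stop_if(side < 4L, "pooled input side must be at least 4")
  X <- matrix(0, length(dataset$samples), 4L * side^2)
  for (i in seq_along(dataset$samples)) {
    chans <- dataset$samples[[i]]$channels
    X[i, ] <- unlist(lapply(.CHANNEL_NAMES, function(ch)
      as.vector(.block_mean(chans[[ch]], side))), use.names = FALSE) /
      .INTENSITY_MAX
  }
  rownames(X) <- vapply(dataset$samples, `[[`, character(1), "id")
  attr(X, "side") <- side
  X
}

# Column indices of the im2col expansion: idx[p, o] maps output position p
# (valid convolution, column-major) and kernel offset o (channel-major,
# then kernel column, then kernel row) into the flattened input row.
.im2col_index <- function(side, kernel, in_channels = 4L) {
  s1 <- side - kernel + 1L
  pr <- rep(seq_len(s1), times = s1)
  pc <- rep(seq_len(s1), each = s1)
  idx <- matrix(0L, s1 * s1, in_channels * kernel^2)
  o <- 0L
  for (ch in seq_len(in_channels)) {
    for (kc in seq_len(kernel)) {
      for (kr in seq_len(kernel)) {
        o <- o + 1L
        idx[, o] <- (ch - 1L) * side^2 + (pc + kc - 2L) * side + (pr + kr - 1L)
      }
    }
  }
  idx
}

#' Build a compact four-channel CNN
#'
#' Architecture: fixed block-average stem (see [cnn_input_matrix()]), one
#' valid 3 x 3 convolution with `conv_filters` output channels and ReLU,
#' [acp_pool()] over the resulting feature map (length `2 * conv_filters`
#' features), and a [build_head()] classifier with optional buffering
#' layers.  The convolution kernels are created for 3-channel input with
#' He-uniform initialization and extended to 4 channels through
#' [adapt_input_layer()], mirroring how a pretrained RGB backbone is
#' adapted to RGBY data.
#'
#' @param input_side Side of the pooled square input (e.g. 16).
#' @param n_classes Number of output classes (default 28).
#' @param conv_filters Number of convolution filters (default 12).
#' @param kernel Convolution kernel side (default 3).
#' @param head_buffering Integer vector of buffering-layer widths for the
#'   head (default none: a single linear map).
#' @param init_strategy Fourth-channel initialization passed to
#'   [adapt_input_layer()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `"small_cnn"`.
#' @export
small_cnn <- function(input_side, n_classes = 28L, conv_filters = 12L,
                      kernel = 3L, head_buffering = integer(),
                      init_strategy = "mean_rgb", seed = 1L) {
  .stop_if(!.is_count(input_side, 4L), "`input_side` must be an integer >= 4")
  .stop_if(!.is_count(conv_filters, 1L), "`conv_filters` must be positive")
  .stop_if(!.is_count(kernel, 1L) || kernel >= input_side,
           "`kernel` must be a positive integer below `input_side`")
  .with_seed(seed, {
    bound <- sqrt(6 / (3 * kernel^2))
    w3 <- array(stats::runif(conv_filters * 3L * kernel^2, -bound, bound),
                dim = c(conv_filters, 3L, kernel, kernel))
    w4 <- adapt_input_layer(w3, init_strategy)
    # flatten to filters x offsets, offset order matching .im2col_index()
    Wc <- matrix(aperm(w4, c(1L, 3L, 4L, 2L)), nrow = conv_filters)
    head <- build_head(head_spec(2L * conv_filters,
                                 buffering_sizes = head_buffering,
                                 dropout_rates = rep(0, length(head_buffering)),
                                 n_classes = n_classes))
    structure(
      list(input_side = as.integer(input_side),
           n_classes = as.integer(n_classes),
           conv_filters = as.integer(conv_filters), kernel = as.integer(kernel),
           Wc = Wc, bc = numeric(conv_filters), head = head,
           im2col = .im2col_index(input_side, kernel)),
      class = "small_cnn"
    )
  })
}

#' @export
print.small_cnn <- function(x, ...) {
  s1 <- x$input_side - x$kernel + 1L
  cat(sprintf(
    "Compact 4-channel CNN: %dx%dx4 input -> conv%dx%d (%d filters) -> ACP (%d features) -> head %s\n",
    x$input_side, x$input_side, x$kernel, x$kernel, x$conv_filters,
    2L * x$conv_filters, paste(x$head$dims, collapse = " -> ")))
  cat(sprintf("  feature map %dx%d, %d parameters\n", s1, s1,
              length(x$Wc) + length(x$bc) + x$head$n_parameters))
  invisible(x)
}

# Forward pass over a batch (rows of X); returns caches for backprop.
.cnn_forward <- function(model, Xb) {
  B <- nrow(Xb)
  P <- nrow(model$im2col)
  n_off <- ncol(model$im2col)
  Ccols <- matrix(0, B * P, n_off)
  for (o in seq_len(n_off)) {
    Ccols[, o] <- as.vector(t(Xb[, model$im2col[, o], drop = FALSE]))
  }
  H <- tcrossprod(Ccols, model$Wc)                    # (B*P) x F
  H <- sweep(H, 2L, model$bc, "+")
  R <- pmax(H, 0)
  f_n <- model$conv_filters
  means <- rowsum(R, rep(seq_len(B), each = P)) / P   # B x F
  maxs <- matrix(0, B, f_n)
  argmax <- matrix(0L, B, f_n)
  for (f in seq_len(f_n)) {
    Mf <- matrix(R[, f], P, B)
    argmax[, f] <- max.col(t(Mf), ties.method = "first")
    maxs[, f] <- Mf[cbind(argmax[, f], seq_len(B))]
  }
  feat <- cbind(means, maxs)                          # B x 2F (ACP order)
  acts <- list(feat)
  z <- feat
  nl <- length(model$head$layers)
  for (l in seq_len(nl)) {
    z <- sweep(tcrossprod(z, model$head$layers[[l]]$W), 2L,
               model$head$layers[[l]]$b, "+")
    if (l < nl) z <- pmax(z, 0)
    acts[[l + 1L]] <- z
  }
  list(logits = z, probs = 1 / (1 + exp(-z)), feat = feat, acts = acts,
       Ccols = Ccols, relu_mask = H > 0, argmax = argmax, B = B, P = P)
}

#' Predict class probabilities with a compact CNN
#'
#' @param model A `"small_cnn"`.
#' @param X Input matrix from [cnn_input_matrix()].
#' @param batch_size Prediction chunk size (memory control).
#' @return `N x n_classes` matrix of sigmoid probabilities, sample ids as
#'   row names.
#' @export
predict_probs <- function(model, X, batch_size = 512L) {
  .stop_if(!inherits(model, "small_cnn"), "`model` must be a small_cnn")
  out <- matrix(0, nrow(X), model$n_classes)
  starts <- seq(1L, nrow(X), by = batch_size)
  for (s in starts) {
    e <- min(s + batch_size - 1L, nrow(X))
    out[s:e, ] <- .cnn_forward(model, X[s:e, , drop = FALSE])$probs
  }
  rownames(out) <- rownames(X)
  out
}

#' Train a compact CNN with the imbalance-handling machinery
#'
#' Minimizes per-class binary cross-entropy with optional effective-number
#' class weights ([eloss_weights()]) and optional batch-level hard example
#' mining ([hard_sample_select()]; class weighting is applied before the
#' top-K selection, so rare-class samples rank high).  Optimization is SGD
#' with momentum and weight decay under a cyclic cosine-annealed schedule
#' ([cosine_cycle_lr()]) with two discriminative layer groups: the
#' convolution ("encoder") trains at one third of the head rate
#' ([discriminative_lrs()]).
#'
#' @param model A `"small_cnn"`.
#' @param X Input matrix from [cnn_input_matrix()].
#' @param Y `N x n_classes` binary label matrix.
#' @param epochs Training epochs.
#' @param batch_size Batch size `B`.
#' @param base_lr Head learning rate `lr` (encoder trains at `lr/3`).
#' @param cycle_epochs Epochs per cosine cycle; `epochs` must be a
#'   multiple.
#' @param class_weights Optional `"eloss_weights"` (or numeric vector of
#'   length `n_classes`); `NULL` for plain BCE.
#' @param hard_fraction Optional fraction in `(0, 1]` of each batch kept by
#'   the hard sampler (`K = ceiling(hard_fraction * B)`); `NULL` disables
#'   mining.
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 weight decay (default 1e-6).
#' @param seed Integer seed for batch shuffling.
#' @return The trained `"small_cnn"`, with a `history` element (data frame
#'   of per-epoch mean training loss).
#' @export
train_small_cnn <- function(model, X, Y, epochs = 8L, batch_size = 64L,
                            base_lr = 0.05, cycle_epochs = 2L,
                            class_weights = NULL, hard_fraction = NULL,
                            momentum = 0.9, weight_decay = 1e-6, seed = 1L) {
  .stop_if(!inherits(model, "small_cnn"), "`model` must be a small_cnn")
  .stop_if(!is.matrix(X) || !is.matrix(Y) || nrow(X) != nrow(Y),
           "`X` and `Y` must be matrices with matching rows")
  .stop_if(ncol(Y) != model$n_classes, "`Y` must have n_classes columns")
  .stop_if(epochs %% cycle_epochs != 0L,
           "`epochs` must be a multiple of `cycle_epochs`")
  if (!is.null(hard_fraction)) {
    .stop_if(hard_fraction <= 0 || hard_fraction > 1,
             "`hard_fraction` must lie in (0, 1]")
  }
  w <- if (is.null(class_weights)) rep(1, model$n_classes)
       else if (inherits(class_weights, "eloss_weights")) class_weights$weights
       else class_weights
  .stop_if(length(w) != model$n_classes,
           "`class_weights` must have one weight per class")
  n <- nrow(X)
  steps_per_epoch <- ceiling(n / batch_size)
  sched <- lr_schedule(discriminative_lrs(base_lr, 2L),
                       cycle_length = cycle_epochs * steps_per_epoch,
                       n_cycles = epochs %/% cycle_epochs)
  vel <- list(Wc = model$Wc * 0, bc = model$bc * 0,
              head = lapply(model$head$layers,
                            function(l) list(W = l$W * 0, b = l$b * 0)))
  history <- numeric(epochs)
  step <- 0L
  .with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (bs in seq(1L, n, by = batch_size)) {
        be <- min(bs + batch_size - 1L, n)
        rows <- ord[bs:be]
        Xb <- X[rows, , drop = FALSE]
        Yb <- Y[rows, , drop = FALSE]
        lrs <- cosine_cycle_lr(step, sched)
        fwd <- .cnn_forward(model, Xb)
        lmat <- bce_loss(fwd$probs, Yb)
        ls <- per_sample_loss(lmat, w)
        sel <- if (is.null(hard_fraction)) seq_len(fwd$B)
               else hard_sample_select(ls, ceiling(hard_fraction * fwd$B))
        ep_loss <- ep_loss + mean(ls[sel])
        # gradient of mean selected weighted BCE w.r.t. logits
        G <- sweep(fwd$probs - Yb, 2L, w, "*") / length(sel)
        G[setdiff(seq_len(fwd$B), sel), ] <- 0
        model <- .cnn_backward_update(model, fwd, G, vel, lrs, momentum,
                                      weight_decay)
        vel <- model$.vel
        model$.vel <- NULL
        step <- step + 1L
      }
      history[ep] <- ep_loss / steps_per_epoch
    }
  })
  model$history <- data.frame(epoch = seq_len(epochs), loss = history)
  model
}

# One SGD-with-momentum update from the logit gradient G (B x n_classes).
.cnn_backward_update <- function(model, fwd, G, vel, lrs, momentum,
                                 weight_decay) {
  nl <- length(model$head$layers)
  grads <- vector("list", nl)
  d <- G
  for (l in rev(seq_len(nl))) {
    a_in <- fwd$acts[[l]]
    grads[[l]] <- list(W = crossprod(d, a_in) + weight_decay * model$head$layers[[l]]$W,
                       b = colSums(d))
    if (l > 1L) {
      d <- (d %*% model$head$layers[[l]]$W) * (fwd$acts[[l]] > 0)
    } else {
      d <- d %*% model$head$layers[[l]]$W            # gradient w.r.t. feat
    }
  }
  f_n <- model$conv_filters
  B <- fwd$B; P <- fwd$P
  d_mean <- d[, seq_len(f_n), drop = FALSE]
  d_max <- d[, f_n + seq_len(f_n), drop = FALSE]
  dR <- d_mean[rep(seq_len(B), each = P), , drop = FALSE] / P
  # route the max half to each sample's argmax position
  rows_max <- (rep(seq_len(B), times = f_n) - 1L) * P + as.vector(fwd$argmax)
  idx <- cbind(rows_max, rep(seq_len(f_n), each = B))
  dR[idx] <- dR[idx] + as.vector(d_max)
  dH <- dR * fwd$relu_mask
  gWc <- crossprod(dH, fwd$Ccols) + weight_decay * model$Wc
  gbc <- colSums(dH)
  # group 1 (encoder = convolution) at lrs[1], group 2 (head) at lrs[2]
  vel$Wc <- momentum * vel$Wc - lrs[1L] * gWc
  vel$bc <- momentum * vel$bc - lrs[1L] * gbc
  model$Wc <- model$Wc + vel$Wc
  model$bc <- model$bc + vel$bc
  for (l in seq_len(nl)) {
    vel$head[[l]]$W <- momentum * vel$head[[l]]$W - lrs[2L] * grads[[l]]$W
    vel$head[[l]]$b <- momentum * vel$head[[l]]$b - lrs[2L] * grads[[l]]$b
    model$head$layers[[l]]$W <- model$head$layers[[l]]$W + vel$head[[l]]$W
    model$head$layers[[l]]$b <- model$head$layers[[l]]$b + vel$head[[l]]$b
  }
  model$.vel <- vel
  model
}
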