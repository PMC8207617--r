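#' Adapt a 3-channel convolution input layer to 4 channels
#'
#' Extends pretrained first-layer convolution weights from RGB to RGBY input
#' so all four microscopy stains (microtubules, protein, nucleus, reticulum)
#' can be fed to a backbone trained on 3-channel images.  The first three
#' channel kernels are copied unchanged; the fourth is initialized according
#' to `init_strategy`:
#'
#' * `"mean_rgb"` (default): mean of the three existing channel kernels --
#'   the yellow channel starts as a neutral mixture of learned filters;
#' * `"zero"`: all-zero kernel, so the adapted layer reproduces the original
#'   3-channel output exactly until training moves it;
#' * `"copy_red"`: copy of the red-channel kernel (yellow and red stains both
#'   image filamentous structures).
#'
#' @param weights 4-d numeric array of convolution weights with dimensions
#'   `(out_channels, 3, kernel_h, kernel_w)`.
#' @param init_strategy One of `"mean_rgb"`, `"zero"`, `"copy_red"`.
#' @return Array with dimensions `(out_channels, 4, kernel_h, kernel_w)`.
#' @export
adapt_input_layer <- function(weights,
                              init_strategy = c("mean_rgb", "zero", "copy_red")) {
  init_strategy <- match.arg(init_strategy)
  .stop_if(!is.array(weights) || length(dim(weights)) != 4L,
           "`weights` must be a 4-d array (out, in, kh, kw)")
  .stop_if(dim(weights)[2] != 3L, "`weights` must have 3 input channels")
  d <- dim(weights)
  out <- array(0, dim = c(d[1], 4L, d[3], d[4]))
  out[, 1:3, , ] <- weights
  out[, 4, , ] <- switch(
    init_strategy,
    zero     = 0,
    mean_rgb = (weights[, 1, , ] + weights[, 2, , ] + weights[, 3, , ]) / 3,
    copy_red = weights[, 1, , ]
  )
  out
}

#' Adaptive concatenate pooling (ACP)
#'
#' Pools an encoder feature map of any spatial size down to a fixed-length
#' vector by concatenating global average pooling and global max pooling in
#' the channel dimension.  For a `C x H x W` input the output has length
#' `2C`: entries `1..C` are the per-channel spatial means, entries
#' `(C+1)..2C` the per-channel spatial maxima.  Averaging summarizes
#' diffuse staining while the maximum preserves sharp punctate signal, so
#' the classifier head sees both.
#'
#' @param feature_map 3-d numeric array `C x H x W` with `H, W >= 1` (a
#'   `C`-row matrix is accepted as `C x H x 1`).
#' @return Numeric vector of length `2 * C`.
#' @examples
#' fm <- array(rnorm(8 * 5 * 7), dim = c(8, 5, 7))
#' length(acp_pool(fm))  # 16
#' @export
acp_pool <- function(feature_map) {
  if (is.matrix(feature_map)) {
    feature_map <- array(feature_map, dim = c(dim(feature_map), 1L))
  }
  .stop_if(!is.array(feature_map) || length(dim(feature_map)) != 3L ||
             !is.numeric(feature_map),
           "`feature_map` must be a numeric C x H x W array")
  d <- dim(feature_map)
  .stop_if(any(d < 1L), "all dimensions must be at least 1")
  flat <- matrix(feature_map, nrow = d[1])     # C x (H*W)
  c(rowMeans(flat), apply(flat, 1L, max))
}

#' Specification of a buffering-layer classifier head
#'
#' Describes the fully connected head placed after [acp_pool()]: zero or
#' more intermediate "buffering" layers of strictly decreasing width (each
#' followed by ReLU and dropout) and a final linear map to `n_classes`
#' output units.  Buffering layers shrink the large pooled feature vector
#' gradually instead of in a single linear map, limiting the feature
#' information lost in the reduction.
#'
#' @param in_features Width of the pooled feature vector (e.g. `2C` after
#'   ACP).
#' @param buffering_sizes Integer vector of buffering-layer widths, strictly
#'   decreasing; may be empty for a single linear map.
#' @param dropout_rates Dropout probability after each buffering layer, in
#'   `[0, 1)`, same length as `buffering_sizes`.
#' @param n_classes Number of output units (default 28).
#' @return An object of class `"head_spec"`.
#' @export
head_spec <- function(in_features, buffering_sizes = integer(),
                      dropout_rates = rep(0.5, length(buffering_sizes)),
                      n_classes = 28L) {
  .stop_if(!.is_count(in_features, 1L), "`in_features` must be positive")
  .stop_if(!.is_count(n_classes, 1L), "`n_classes` must be positive")
  buffering_sizes <- as.integer(buffering_sizes)
  .stop_if(any(buffering_sizes < 1L), "buffering sizes must be positive")
  .stop_if(length(buffering_sizes) > 1L && any(diff(buffering_sizes) >= 0L),
           "buffering sizes must be strictly decreasing")
  .stop_if(length(dropout_rates) != length(buffering_sizes),
           "`dropout_rates` must match `buffering_sizes` in length")
  .stop_if(any(dropout_rates < 0 | dropout_rates >= 1),
           "dropout rates must lie in [0, 1)")
  structure(
    list(in_features = as.integer(in_features),
         buffering_sizes = buffering_sizes,
         dropout_rates = as.numeric(dropout_rates),
         n_classes = as.integer(n_classes)),
    class = "head_spec"
  )
}

#' Build a classifier head from its specification
#'
#' Instantiates the fully connected layers described by a [head_spec()]:
#' weight matrices with He-uniform initialization and zero biases.  The
#' returned object carries the layer dimension chain and total parameter
#' count and can be evaluated with [head_forward()].
#'
#' @param spec A `"head_spec"` object.
#' @return An object of class `"classifier_head"` with elements `spec`,
#'   `dims` (dimension chain `in -> buffering ... -> n_classes`), `layers`
#'   (list of `W`/`b` pairs) and `n_parameters`.
#' @examples
#' h <- build_head(head_spec(4096, buffering_sizes = 1024,
#'                           dropout_rates = 0.5, n_classes = 28))
#' h$dims          # 4096 1024 28
#' h$n_parameters  # (4096+1)*1024 + (1024+1)*28
#' @export
build_head <- function(spec) {
  .stop_if(!inherits(spec, "head_spec"), "`spec` must be a head_spec")
  dims <- c(spec$in_features, spec$buffering_sizes, spec$n_classes)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    bound <- sqrt(6 / fan_in)
    layers[[l]] <- list(
      W = matrix(stats::runif(dims[l + 1L] * fan_in, -bound, bound),
                 nrow = dims[l + 1L], ncol = fan_in),
      b = numeric(dims[l + 1L])
    )
  }
  n_par <- sum((dims[-length(dims)] + 1L) * dims[-1L])
  structure(
    list(spec = spec, dims = dims, layers = layers, n_parameters = n_par),
    class = "classifier_head"
  )
}

#' @export
print.classifier_head <- function(x, ...) {
  cat("Classifier head:", paste(x$dims, collapse = " -> "),
      sprintf("(%d parameters)\n", x$n_parameters))
  if (length(x$spec$dropout_rates)) {
    cat("  dropout after buffering layers:",
        paste(x$spec$dropout_rates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Forward pass through a classifier head
#'
#' Applies the head's linear layers to a batch of feature vectors, with ReLU
#' after every buffering layer and (in training mode) inverted dropout at
#' the configured rates.  The final layer emits raw logits.
#'
#' @param head A `"classifier_head"` from [build_head()].
#' @param x Numeric matrix `N x in_features` (a vector is treated as one
#'   row).
#' @param training If `TRUE`, apply dropout using the current RNG state.
#' @return `N x n_classes` matrix of logits.
#' @export
head_forward <- function(head, x, training = FALSE) {
  .stop_if(!inherits(head, "classifier_head"), "`head` must be a classifier_head")
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  .stop_if(ncol(x) != head$dims[1L], "feature width does not match the head")
  nl <- length(head$layers)
  for (l in seq_len(nl)) {
    x <- tcrossprod(x, head$layers[[l]]$W)
    x <- sweep(x, 2L, head$layers[[l]]$b, "+")
    if (l < nl) {
      x <- pmax(x, 0)
      rate <- head$spec$dropout_rates[l]
      if (training && rate > 0) {
        keep <- matrix(stats::runif(length(x)) >= rate, nrow(x), ncol(x))
        x <- x * keep / (1 - rate)
      }
    }
  }
  x
}

#' Select the hardest samples of a batch by loss
#'
#' Online hard example mining: given the per-sample losses of a batch of
#' size `B`, returns the indices of the `K` largest losses.  Restricting the
#' batch loss to this subset focuses the gradient on difficult samples --
#' under long-tail imbalance these are predominantly minority-class samples,
#' so majority classes contribute almost nothing during backpropagation.
#' Ties are broken toward the lower index for determinism.
#'
#' @param losses Non-negative numeric vector of per-sample losses (length
#'   `B`).
#' @param K Number of samples to keep, `1 <= K <= B`.  The default
#'   `ceiling(B / 2)` keeps half the batch.
#' @return Sorted integer vector of `K` indices into `losses`.
#' @examples
#' hard_sample_select(c(0.1, 0.9, 0.5, 0.7), K = 2)  # 2 4
#' @export
hard_sample_select <- function(losses, K = ceiling(length(losses) / 2)) {
  .stop_if(!is.numeric(losses) || length(losses) == 0L ||
             any(!is.finite(losses)),
           "`losses` must be a non-empty finite numeric vector")
  B <- length(losses)
  .stop_if(!.is_count(K, 1L) || K > B, "`K` must satisfy 1 <= K <= B")
  ord <- order(-losses, seq_len(B))   # ties: lower index wins
  sort(ord[seq_len(K)])
}

#' Batch loss after hard example mining
#'
#' Mean of the `K` largest per-sample losses, the quantity backpropagated
#' when the hard sampler is active.  With `K = length(losses)` this is the
#' plain batch mean.
#'
#' @inheritParams hard_sample_select
#' @return Scalar loss.
#' @export
hard_mined_loss <- function(losses, K = ceiling(length(losses) / 2)) {
  mean(losses[hard_sample_select(losses, K)])
}
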