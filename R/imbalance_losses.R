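#' Effective number of samples
#'
#' Computes the effective number \eqn{Q_n = (1 - \alpha^n) / (1 - \alpha)} of
#' `n` samples of one class under feature-space overlap.  The model assumes
#' each sample occupies unit volume inside a class volume \eqn{V}; a new
#' sample coincides with already-covered volume with probability
#' \eqn{p = Q_{n-1}/V}, giving the recurrence
#' \eqn{Q_n = \alpha Q_{n-1} + 1} with \eqn{\alpha = (V-1)/V} and
#' \eqn{Q_1 = 1}.  The closed form above is its solution.  At `alpha = 0`
#' (\eqn{V = 1}) every sample overlaps and \eqn{Q_n = 1}; at `alpha = 1`
#' (the \eqn{V \to \infty} limit) there is no overlap and \eqn{Q_n = n}.
#'
#' @param n Vector of positive integer sample counts.
#' @param alpha Overlap parameter in `[0, 1]` (scalar).
#' @return Numeric vector of effective numbers, same length as `n`.
#' @examples
#' effective_number(1, 0.9)        # 1 for any alpha
#' effective_number(2, 0.9)        # 1.9
#' effective_number(1000, 1)       # 1000: no-overlap limit
#' @export
effective_number <- function(n, alpha) {
  .stop_if(!is.numeric(n) || length(n) == 0L || any(!is.finite(n)) ||
             any(n < 1) || any(n != round(n)),
           "`n` must contain positive integers")
  .stop_if(!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
             alpha < 0 || alpha > 1,
           "`alpha` must be a single value in [0, 1]")
  if (alpha == 1) return(as.numeric(n))
  if (alpha == 0) return(rep(1, length(n)))
  (1 - alpha^n) / (1 - alpha)
}

#' Effective-number class weights (E-loss weights)
#'
#' Converts per-class positive sample counts \eqn{n_c} into loss weights
#' \eqn{w_c = 1 / Q_{n_c} = (1 - \alpha) / (1 - \alpha^{n_c})}.  The weights
#' interpolate between uniform weighting (`alpha = 0`) and inverse-frequency
#' weighting \eqn{1 / n_c} (`alpha = 1`), discounting majority classes by how
#' much their samples overlap in feature space.
#'
#' Classes with a zero count receive weight 0 with a warning: they carry no
#' training signal, and an infinite or arbitrary weight would poison the sum.
#'
#' @param counts Non-negative integer vector of per-class positive counts
#'   (see [class_count_table()]).
#' @param alpha Overlap parameter in `[0, 1]`; default `0.99`, a single value
#'   shared by all classes.
#' @param normalize If `TRUE` (default) the non-zero weights are rescaled to
#'   sum to the number of counted classes, so the overall loss magnitude --
#'   and with it a tuned learning rate -- is comparable across `alpha`.
#' @return An object of class `"eloss_weights"`: list with elements
#'   `weights` (numeric, one per class), `alpha`, `counts`, `normalized`.
#' @seealso [effective_number()], [eloss()]
#' @examples
#' eloss_weights(c(5, 5, 5), alpha = 0)$weights      # uniform
#' eloss_weights(c(2), alpha = 0.9, normalize = FALSE)$weights  # 1/1.9
#' @export
eloss_weights <- function(counts, alpha = 0.99, normalize = TRUE) {
  .stop_if(!is.numeric(counts) || length(counts) == 0L ||
             any(!is.finite(counts)) || any(counts < 0) ||
             any(counts != round(counts)),
           "`counts` must contain non-negative integers")
  .stop_if(!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
             alpha < 0 || alpha > 1,
           "`alpha` must be a single value in [0, 1]")
  w <- numeric(length(counts))
  pos <- counts > 0
  if (any(!pos)) {
    warning(sum(!pos), " class(es) with zero count receive weight 0")
  }
  w[pos] <- 1 / effective_number(counts[pos], alpha)
  if (normalize && any(pos)) {
    w[pos] <- w[pos] * sum(pos) / sum(w[pos])
  }
  structure(
    list(weights = w, alpha = alpha, counts = as.integer(counts),
         normalized = normalize),
    class = "eloss_weights"
  )
}

#' @export
print.eloss_weights <- function(x, ...) {
  cat("E-loss weights over", length(x$weights), "classes (alpha =", x$alpha,
      if (x$normalized) ", normalized)\n" else ")\n")
  print(summary(x$weights))
  invisible(x)
}

#' Effective-number weighted loss (E-loss)
#'
#' Combines per-class base losses into the scalar
#' \eqn{EL = \sum_c w_c \, L(p_c, y_c)} where the weights come from
#' [eloss_weights()].  The base loss is pluggable: any per-class loss vector
#' (binary cross-entropy, focal, ...) can be supplied.
#'
#' @param per_class_losses Numeric vector of per-class base losses
#'   \eqn{L(p_c, y_c)} (typically each class's loss averaged over a batch).
#' @param weights An `"eloss_weights"` object or a bare numeric vector of the
#'   same length.
#' @return Scalar weighted loss.
#' @export
eloss <- function(per_class_losses, weights) {
  w <- if (inherits(weights, "eloss_weights")) weights$weights else weights
  .stop_if(!is.numeric(per_class_losses) || !is.numeric(w),
           "losses and weights must be numeric")
  .stop_if(length(per_class_losses) != length(w),
           "length of `per_class_losses` and `weights` must match")
  sum(w * per_class_losses)
}

# Clamp probabilities away from {0, 1} before taking logs.
.P_EPS <- 1e-7

#' Elementwise binary cross-entropy
#'
#' @param probs Predicted probabilities in `(0, 1)` (vector or matrix).
#' @param targets Binary targets of the same shape.
#' @param eps Clamping tolerance applied to `probs` before the logarithm.
#' @return Losses of the same shape as `probs`.
#' @export
bce_loss <- function(probs, targets, eps = .P_EPS) {
  .check_prob_target(probs, targets, eps)
  p <- .clamp(probs, eps, 1 - eps)
  -(targets * log(p) + (1 - targets) * log(1 - p))
}

#' Elementwise focal loss
#'
#' Focal modulation of binary cross-entropy: with
#' \eqn{p_t = y p + (1-y)(1-p)}, the loss is
#' \eqn{(1 - p_t)^\gamma \, (-\log p_t)}.  At `gamma = 0` this reduces
#' exactly to [bce_loss()]; larger `gamma` down-weights well-classified
#' examples, complementing class-level weighting for label imbalance.
#'
#' @inheritParams bce_loss
#' @param gamma Focusing parameter, `>= 0`.
#' @return Losses of the same shape as `probs`.
#' @export
focal_base_loss <- function(probs, targets, gamma = 2, eps = .P_EPS) {
  .check_prob_target(probs, targets, eps)
  .stop_if(!is.numeric(gamma) || length(gamma) != 1L || gamma < 0,
           "`gamma` must be a single non-negative value")
  p <- .clamp(probs, eps, 1 - eps)
  pt <- targets * p + (1 - targets) * (1 - p)
  (1 - pt)^gamma * (-log(pt))
}

.check_prob_target <- function(probs, targets, eps) {
  .stop_if(!is.numeric(probs) || any(!is.finite(probs)) ||
             any(probs < -eps) || any(probs > 1 + eps),
           "`probs` must lie in [0, 1]")
  .stop_if(!identical(dim(probs), dim(targets)) ||
             length(probs) != length(targets),
           "`probs` and `targets` must have identical shape")
  .stop_if(any(targets != 0 & targets != 1), "`targets` must be binary")
}

#' Batch E-loss for multi-label predictions
#'
#' Evaluates the effective-number weighted loss on an `N x C` probability
#' matrix: each class's base loss (binary cross-entropy or focal) is averaged
#' over the batch, then the weighted sum over classes is taken.
#'
#' @param probs `N x C` matrix of predicted probabilities.
#' @param targets `N x C` binary label matrix.
#' @param weights `"eloss_weights"` object (or numeric vector of length `C`).
#' @param base Base loss, `"bce"` or `"focal"`.
#' @param gamma Focusing parameter when `base = "focal"`.
#' @return Scalar loss.
#' @export
multilabel_eloss <- function(probs, targets, weights, base = c("bce", "focal"),
                             gamma = 2) {
  base <- match.arg(base)
  lmat <- if (base == "bce") bce_loss(probs, targets)
          else focal_base_loss(probs, targets, gamma)
  eloss(colMeans(lmat), weights)
}

#' Per-sample weighted losses for hard example mining
#'
#' Reduces an `N x C` elementwise loss matrix to one loss per sample,
#' applying the per-class weights first:
#' \eqn{\ell_i = \sum_c w_c \, L(p_{ic}, y_{ic})}.  Class weighting composes
#' before top-K selection so that rare-class samples rank high in the batch
#' ordering used by [hard_sample_select()].
#'
#' @param loss_matrix `N x C` matrix of elementwise losses.
#' @param weights `"eloss_weights"` object, numeric vector of length `C`, or
#'   `NULL` for uniform weights.
#' @return Numeric vector of length `N`.
#' @export
per_sample_loss <- function(loss_matrix, weights = NULL) {
  .stop_if(!is.matrix(loss_matrix), "`loss_matrix` must be a matrix")
  w <- if (is.null(weights)) rep(1, ncol(loss_matrix))
       else if (inherits(weights, "eloss_weights")) weights$weights
       else weights
  .stop_if(length(w) != ncol(loss_matrix),
           "`weights` length must equal the number of classes")
  drop(loss_matrix %*% w)
}
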