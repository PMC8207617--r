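#' Per-class confusion counts for multi-label predictions
#'
#' Tallies true positives, false positives and false negatives column-wise
#' (per class) over an `N x C` binary ground-truth matrix and an equally
#' shaped prediction matrix.
#'
#' @param y_true `N x C` binary matrix of ground-truth labels.
#' @param y_pred `N x C` binary matrix of predicted labels.
#' @return An object of class `"confusion_counts"`: list with integer
#'   vectors `tp`, `fp`, `fn` of length `C`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  .stop_if(!is.matrix(y_true) || !is.matrix(y_pred),
           "`y_true` and `y_pred` must be matrices")
  .stop_if(!identical(dim(y_true), dim(y_pred)),
           "`y_true` and `y_pred` must have identical shape")
  .stop_if(any(y_true != 0 & y_true != 1) || any(y_pred != 0 & y_pred != 1),
           "label matrices must be binary")
  structure(
    list(tp = as.integer(colSums(y_pred == 1 & y_true == 1)),
         fp = as.integer(colSums(y_pred == 1 & y_true == 0)),
         fn = as.integer(colSums(y_pred == 0 & y_true == 1))),
    class = "confusion_counts"
  )
}

#' Macro-averaged F1 report
#'
#' Computes per-class precision `P = TP / (TP + FP)`, recall
#' `R = TP / (TP + FN)` and `F1 = 2PR / (P + R)`, plus their macro average
#' `mean(F1)` over all `N` classes.  Macro averaging weights every class
#' equally, so rare protein classes count as much as dominant ones.  All
#' `0/0` cases (no predictions, no positives, or `P + R = 0`) resolve to 0
#' by convention; zero-support classes still enter the macro mean.
#'
#' @param counts A `"confusion_counts"` object.
#' @return An object of class `"f1_report"`: list with `per_class` (data
#'   frame with columns `class`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`) and `macro` (scalar).
#' @export
f1_macro <- function(counts) {
  .stop_if(!inherits(counts, "confusion_counts"),
           "`counts` must come from confusion_counts()")
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(
    list(per_class = data.frame(class = seq_along(tp) - 1L, tp = tp, fp = fp,
                                fn = fn, precision = precision,
                                recall = recall, f1 = f1),
         macro = mean(f1)),
    class = "f1_report"
  )
}

#' @export
print.f1_report <- function(x, digits = 4, ...) {
  cat(sprintf("Macro F1 over %d classes: %.*f\n",
              nrow(x$per_class), digits, x$macro))
  print(x$per_class, digits = digits)
  invisible(x)
}

#' Apply per-class decision thresholds to a probability matrix
#'
#' A prediction is positive iff the probability is greater than or equal to
#' the class threshold (closed lower bound, the fixed convention throughout
#' the package: at a tied grid value the rare-class-friendly, higher-recall
#' decision is taken).
#'
#' @param probs `N x C` matrix of probabilities in `[0, 1]`.
#' @param thresholds Scalar threshold or numeric vector of length `C`.
#' @return `N x C` binary (0/1) matrix.
#' @export
apply_thresholds <- function(probs, thresholds) {
  .stop_if(!is.matrix(probs), "`probs` must be a matrix")
  .stop_if(!(length(thresholds) %in% c(1L, ncol(probs))),
           "`thresholds` must be scalar or one per class")
  pred <- probs >= matrix(thresholds, nrow(probs), ncol(probs), byrow = TRUE)
  storage.mode(pred) <- "integer"
  pred
}

#' Macro F1 of thresholded probabilities
#'
#' Convenience wrapper: thresholds `probs` with [apply_thresholds()] and
#' returns the scalar macro F1.
#'
#' @inheritParams apply_thresholds
#' @param y_true `N x C` binary ground-truth matrix.
#' @return Scalar macro F1.
#' @export
macro_f1_score <- function(probs, y_true, thresholds = 0.5) {
  f1_macro(confusion_counts(y_true, apply_thresholds(probs, thresholds)))$macro
}

#' Decision-threshold search grid
#'
#' The default grid scans thresholds from 0.1 to 0.9 in steps of 0.05
#' (17 values), used by both the single and the greedy per-class search.
#'
#' @param lo,hi Grid bounds.
#' @param step Grid step.
#' @return Numeric vector of thresholds.
#' @export
threshold_grid <- function(lo = 0.1, hi = 0.9, step = 0.05) {
  .stop_if(!(lo > 0 && hi < 1 && lo <= hi && step > 0), "invalid grid")
  round(seq(lo, hi, by = step), 10)
}

# Per-class F1 of one class's probability column at each grid value;
# returns a vector over the grid.  0/0 conventions as in f1_macro().
.class_f1_over_grid <- function(p, y, grid) {
  pred <- outer(p, grid, ">=")
  tp <- colSums(pred & y == 1)
  fp <- colSums(pred & y == 0)
  fn <- sum(y == 1) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
}

#' Single shared decision threshold maximizing macro F1
#'
#' Evaluates macro F1 with one common threshold applied to every class, at
#' each grid value, and returns the argmax.  Ties are broken toward the
#' lower threshold.  The winning value is the usual initialization for the
#' per-class greedy search ([greedy_multi_threshold()]).
#'
#' @param probs `N x C` probability matrix.
#' @param y_true `N x C` binary ground-truth matrix.
#' @param grid Threshold grid (default [threshold_grid()]).
#' @return List with `threshold`, `score` and `trace` (data frame with
#'   columns `threshold`, `score`).
#' @export
search_single_threshold <- function(probs, y_true, grid = threshold_grid()) {
  .stop_if(length(grid) == 0L, "empty threshold grid")
  .stop_if(!is.matrix(probs) || !identical(dim(probs), dim(y_true)),
           "`probs` and `y_true` must be matrices of identical shape")
  f1_by_class <- vapply(
    seq_len(ncol(probs)),
    function(c) .class_f1_over_grid(probs[, c], y_true[, c], grid),
    numeric(length(grid))
  )                                         # |grid| x C
  scores <- rowMeans(f1_by_class)
  best <- which.max(scores)                 # first maximum: lowest threshold
  list(threshold = grid[best], score = scores[best],
       trace = data.frame(threshold = grid, score = scores))
}

#' Greedy per-class threshold optimization for macro F1
#'
#' Starting from a common initial threshold (typically the
#' [search_single_threshold()] optimum), performs one pass over the classes
#' in index order: for each class, the other thresholds are held fixed and
#' the class's threshold is set to the grid value maximizing validation
#' macro F1 (the current value is always among the candidates, so the score
#' trace is non-decreasing by construction; ties go to the lower
#' threshold).  Because macro F1 is a mean of per-class F1 scores and only
#' the active class's F1 depends on its threshold, each scan is evaluated
#' per class in closed form.
#'
#' Classes with no positive validation sample keep their initial threshold
#' (there is no signal to optimize) and are reported in `unoptimized`.
#'
#' @inheritParams search_single_threshold
#' @param init_threshold Initial common threshold in `(0, 1)`, default 0.3.
#' @param passes Number of greedy passes over the classes; default 1.
#' @return List with `thresholds` (numeric vector of length `C`), `score`
#'   (final macro F1), `trace` (macro F1 after each class update, the
#'   initial score first) and `unoptimized` (indices of zero-support
#'   classes).
#' @export
greedy_multi_threshold <- function(probs, y_true, init_threshold = 0.3,
                                   grid = threshold_grid(), passes = 1L) {
  .stop_if(!is.numeric(init_threshold) || length(init_threshold) != 1L ||
             init_threshold <= 0 || init_threshold >= 1,
           "`init_threshold` must lie in (0, 1)")
  .stop_if(length(grid) == 0L, "empty threshold grid")
  .stop_if(!is.matrix(probs) || !identical(dim(probs), dim(y_true)),
           "`probs` and `y_true` must be matrices of identical shape")
  .stop_if(!.is_count(passes, 1L), "`passes` must be a positive integer")
  C <- ncol(probs)
  thresholds <- rep(init_threshold, C)
  support <- colSums(y_true == 1)
  f1 <- vapply(seq_len(C), function(c)
    .class_f1_over_grid(probs[, c], y_true[, c], thresholds[c]), numeric(1))
  trace <- mean(f1)
  for (pass in seq_len(passes)) {
    for (c in seq_len(C)) {
      if (support[c] > 0) {
        cand <- sort(unique(c(grid, thresholds[c])))
        cand_f1 <- .class_f1_over_grid(probs[, c], y_true[, c], cand)
        best <- which.max(cand_f1)          # first maximum: lowest threshold
        thresholds[c] <- cand[best]
        f1[c] <- cand_f1[best]
      }
      trace <- c(trace, mean(f1))
    }
  }
  stopifnot(all(diff(trace) >= -1e-12))     # greedy keeps improvements only
  list(thresholds = thresholds, score = mean(f1), trace = trace,
       unoptimized = which(support == 0))
}

#' Average an ensemble of prediction matrices
#'
#' Elementwise arithmetic mean of probability matrices from several models
#' (e.g. different backbones or input sizes).  All matrices must have the
#' same shape and, when row names carry sample ids, the same sample
#' ordering.
#'
#' @param prob_matrices List of `N x C` probability matrices.
#' @return `N x C` matrix of averaged probabilities.
#' @export
ensemble_average <- function(prob_matrices) {
  .stop_if(!is.list(prob_matrices) || length(prob_matrices) == 0L,
           "`prob_matrices` must be a non-empty list")
  ref <- prob_matrices[[1L]]
  .stop_if(!is.matrix(ref), "elements must be matrices")
  for (m in prob_matrices[-1L]) {
    .stop_if(!is.matrix(m) || !identical(dim(m), dim(ref)),
             "all matrices must have identical shape")
    .stop_if(!identical(rownames(m), rownames(ref)),
             "sample ids (row names) must agree across matrices")
  }
  Reduce(`+`, prob_matrices) / length(prob_matrices)
}
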