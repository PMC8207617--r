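#' Discriminative learning rates for layer groups
#'
#' Pretrained encoder layers need smaller updates than a freshly initialized
#' head.  Since microscopy images still differ substantially from natural
#' images, the encoder rate is reduced only mildly: two groups train with
#' `[lr/3, lr]`, three groups with `[lr/4, lr/2, lr]`, the last group being
#' the head.
#'
#' @param base_lr Head learning rate `lr`, positive.
#' @param n_groups Number of layer groups, 2 or 3.
#' @return Numeric vector of per-group learning rates, increasing with group
#'   index (encoder first, head last).
#' @export
discriminative_lrs <- function(base_lr, n_groups = 2L) {
  .stop_if(!is.numeric(base_lr) || length(base_lr) != 1L || base_lr <= 0,
           "`base_lr` must be a single positive value")
  .stop_if(!(n_groups %in% c(2L, 3L)), "`n_groups` must be 2 or 3")
  if (n_groups == 2L) c(base_lr / 3, base_lr)
  else c(base_lr / 4, base_lr / 2, base_lr)
}

#' Cyclic cosine-annealed learning-rate schedule
#'
#' Describes cycle learning: within each cycle of `cycle_length` steps the
#' learning rate decays from `lr_max` to `lr_min` along a cosine, and at
#' every cycle boundary it restarts at `lr_max`.  The restart kicks the
#' optimizer out of sharp local minima; the cosine tail lets it settle.
#' `lr_max` may be a vector of per-group rates (see [discriminative_lrs()]);
#' all groups share the cosine phase.
#'
#' @param lr_max Positive numeric vector of per-group maximum rates.
#' @param cycle_length Steps per cycle, positive integer.
#' @param n_cycles Number of cycles, positive integer.
#' @param lr_min Floor rate, `0 <= lr_min <= min(lr_max)`; default 0 (pure
#'   cosine to zero).
#' @return An object of class `"lr_schedule"`.
#' @seealso [cosine_cycle_lr()]
#' @export
lr_schedule <- function(lr_max, cycle_length, n_cycles = 1L, lr_min = 0) {
  .stop_if(!is.numeric(lr_max) || length(lr_max) == 0L || any(lr_max <= 0),
           "`lr_max` must be positive")
  .stop_if(!.is_count(cycle_length, 1L), "`cycle_length` must be positive")
  .stop_if(!.is_count(n_cycles, 1L), "`n_cycles` must be positive")
  .stop_if(!is.numeric(lr_min) || length(lr_min) != 1L || lr_min < 0 ||
             lr_min > min(lr_max),
           "`lr_min` must lie in [0, min(lr_max)]")
  structure(
    list(lr_max = as.numeric(lr_max), cycle_length = as.integer(cycle_length),
         n_cycles = as.integer(n_cycles), lr_min = lr_min),
    class = "lr_schedule"
  )
}

#' Per-step learning rates under cosine cycle annealing
#'
#' Evaluates an [lr_schedule()] at step `step` (0-based): with
#' `t = step %% cycle_length`,
#' \deqn{lr(t) = lr_{min} + (lr_{max} - lr_{min}) (1 + \cos(\pi t / T)) / 2}
#' so `lr(0) = lr_max` at every cycle start and the rate decays toward
#' `lr_min` by the end of the cycle.
#'
#' @param step Integer vector of 0-based steps in
#'   `[0, cycle_length * n_cycles)`.
#' @param schedule An `"lr_schedule"` object.
#' @return For a single step, a numeric vector of per-group rates; for
#'   several steps, a matrix with one row per step and one column per group.
#' @export
cosine_cycle_lr <- function(step, schedule) {
  .stop_if(!inherits(schedule, "lr_schedule"), "`schedule` must be an lr_schedule")
  total <- schedule$cycle_length * schedule$n_cycles
  .stop_if(!is.numeric(step) || any(step != round(step)) ||
             any(step < 0) || any(step >= total),
           "`step` must lie in [0, cycle_length * n_cycles)")
  t <- step %% schedule$cycle_length
  frac <- (1 + cos(pi * t / schedule$cycle_length)) / 2
  out <- outer(frac, schedule$lr_max - schedule$lr_min) + schedule$lr_min
  if (length(step) == 1L) drop(out) else out
}

#' Exponential learning-rate range test (LR finder)
#'
#' Probes a loss function at exponentially increasing learning rates
#' `lr_start * multiplier^k`, starting from a deliberately small rate
#' (default `1e-5`).  The raw losses are smoothed with a bias-corrected
#' exponential moving average; probing stops once the smoothed loss exceeds
#' `divergence_factor` times its running minimum (the model has diverged) or
#' after `max_steps`.  The suggested rate is the largest probed rate at
#' which the smoothed loss was still decreasing.
#'
#' @param loss_probe Function taking a learning rate and returning the
#'   training loss observed at that rate (typically one optimizer step on
#'   the next batch).
#' @param lr_start First probed rate, positive.
#' @param multiplier Geometric growth factor, `> 1`.
#' @param max_steps Maximum number of probes.
#' @param smoothing Exponential moving-average factor in `[0, 1)`.
#' @param divergence_factor Stop when the smoothed loss exceeds this multiple
#'   of its running minimum.
#' @return List with `suggestion` (the proposed learning rate) and `trace`,
#'   a data frame with columns `step`, `lr`, `loss`, `smoothed`.
#' @export
lr_find <- function(loss_probe, lr_start = 1e-5, multiplier = 1.25,
                    max_steps = 100L, smoothing = 0.98,
                    divergence_factor = 4) {
  .stop_if(!is.function(loss_probe), "`loss_probe` must be a function")
  .stop_if(!is.numeric(lr_start) || lr_start <= 0, "`lr_start` must be positive")
  .stop_if(!is.numeric(multiplier) || multiplier <= 1, "`multiplier` must exceed 1")
  .stop_if(!.is_count(max_steps, 1L), "`max_steps` must be positive")
  .stop_if(smoothing < 0 || smoothing >= 1, "`smoothing` must lie in [0, 1)")
  lrs <- losses <- smoothed <- numeric(0)
  avg <- 0
  best <- Inf
  for (k in seq_len(max_steps)) {
    lr <- lr_start * multiplier^(k - 1L)
    loss <- loss_probe(lr)
    if (!is.numeric(loss) || length(loss) != 1L || !is.finite(loss)) {
      if (length(losses) == 0L) stop("loss probe never returned a finite loss",
                                     call. = FALSE)
      break
    }
    avg <- smoothing * avg + (1 - smoothing) * loss
    sm <- avg / (1 - smoothing^k)        # bias-corrected EMA
    lrs <- c(lrs, lr); losses <- c(losses, loss); smoothed <- c(smoothed, sm)
    best <- min(best, sm)
    if (sm > divergence_factor * best) break
  }
  if (length(losses) == 0L) stop("loss probe never returned a finite loss",
                                 call. = FALSE)
  decreasing <- which(diff(smoothed) < 0) + 1L   # steps where loss still fell
  suggestion <- if (length(decreasing)) lrs[max(decreasing)] else lrs[length(lrs)]
  list(suggestion = suggestion,
       trace = data.frame(step = seq_along(lrs), lr = lrs, loss = losses,
                          smoothed = smoothed))
}
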