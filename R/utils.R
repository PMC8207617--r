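#' @keywords internal
"_PACKAGE"

# intensity range of stored channel images
.INTENSITY_MAX <- 255

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

.stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random seed set to `seed` and restores the
#' previous RNG state afterwards, so library calls never disturb a caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Block-mean downsampling of a matrix to an `out x out` grid.  Rows/columns
# are binned as evenly as possible, so the input side does not need to be a
# multiple of `out` (used by both the perceptual hash and the CNN stem).
.block_mean <- function(img, out) {
  nr <- nrow(img); nc <- ncol(img)
  .stop_if(nr < out || nc < out, "image smaller than the target grid")
  ri <- floor((seq_len(nr) - 1L) * out / nr) + 1L
  ci <- floor((seq_len(nc) - 1L) * out / nc) + 1L
  sums <- rowsum(t(rowsum(img, ri)), ci)           # out x out (transposed)
  cnt <- tcrossprod(tabulate(ci, out), tabulate(ri, out))
  t(sums / cnt)
}
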