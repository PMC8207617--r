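# File formats: HPA-challenge dataset layout (per-channel PNG/TIFF images +
# train.csv), prediction/threshold/submission CSVs, and YAML experiment
# configs.

.CHANNEL_NAMES <- c("red", "green", "blue", "yellow")

#' Write a dataset in the HPA challenge layout
#'
#' Emits one grayscale PNG per channel, named `<id>_red.png`,
#' `<id>_green.png`, `<id>_blue.png`, `<id>_yellow.png`, plus a `train.csv`
#' with header `Id,Target` whose `Target` column holds space-separated
#' 0-based class indices.
#'
#' @param dataset An `"rgby_dataset"`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path to the written `train.csv`.
#' @export
write_hpa_dataset <- function(dataset, dir) {
  .stop_if(!inherits(dataset, "rgby_dataset"), "`dataset` must be an rgby_dataset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (smp in dataset$samples) {
    for (ch in .CHANNEL_NAMES) {
      png::writePNG(smp$channels[[ch]] / .INTENSITY_MAX,
                    file.path(dir, sprintf("%s_%s.png", smp$id, ch)))
    }
  }
  targets <- vapply(dataset$samples, function(smp)
    paste(which(smp$labels == 1L) - 1L, collapse = " "), character(1))
  df <- data.frame(Id = vapply(dataset$samples, `[[`, character(1), "id"),
                   Target = targets)
  path <- file.path(dir, "train.csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_channel_image <- function(dir, id, ch) {
  for (ext in c("png", "tif", "tiff")) {
    path <- file.path(dir, sprintf("%s_%s.%s", id, ch, ext))
    if (file.exists(path)) {
      img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
      if (length(dim(img)) == 3L) img <- img[, , 1L]   # collapse gray RGB
      out <- round(img * .INTENSITY_MAX)
      storage.mode(out) <- "integer"
      return(out)
    }
  }
  stop("missing image file for sample '", id, "', channel '", ch, "'",
       call. = FALSE)
}

#' Read a dataset from the HPA challenge layout
#'
#' Counterpart of [write_hpa_dataset()]: reads `train.csv` (`Id,Target`
#' with space-separated 0-based class indices) and the four per-channel
#' PNG or TIFF files of every sample.
#'
#' @param dir Directory holding `train.csv` and the channel images.
#' @param n_classes Number of classes (default 28).
#' @return An `"rgby_dataset"`.
#' @export
read_hpa_dataset <- function(dir, n_classes = 28L) {
  csv <- file.path(dir, "train.csv")
  .stop_if(!file.exists(csv), paste("no train.csv under", dir))
  df <- utils::read.csv(csv, colClasses = "character")
  .stop_if(!all(c("Id", "Target") %in% names(df)),
           "train.csv must have columns Id and Target")
  samples <- vector("list", nrow(df))
  Y <- matrix(0L, nrow(df), n_classes)
  for (i in seq_len(nrow(df))) {
    idx <- as.integer(strsplit(trimws(df$Target[i]), "\\s+")[[1]])
    .stop_if(any(is.na(idx)) || any(idx < 0L | idx >= n_classes),
             "class indices out of range in train.csv")
    labels <- integer(n_classes)
    labels[idx + 1L] <- 1L
    Y[i, ] <- labels
    chans <- lapply(.CHANNEL_NAMES, function(ch)
      .read_channel_image(dir, df$Id[i], ch))
    names(chans) <- .CHANNEL_NAMES
    samples[[i]] <- list(id = df$Id[i], channels = chans, labels = labels,
                         placements = NULL)
  }
  size <- nrow(samples[[1L]]$channels$green)
  spec <- synthetic_spec(n_samples = nrow(df), n_classes = n_classes,
                         image_size = max(16L, size))
  structure(list(samples = samples, label_matrix = Y,
                 class_counts = as.integer(colSums(Y)), spec = spec),
            class = "rgby_dataset")
}

#' Write a fold assignment as CSV
#'
#' @param assignment A `"fold_assignment"`.
#' @param ids Character vector of sample ids, same length as the
#'   assignment.
#' @param path Output CSV path (columns `Id,fold`).
#' @return Invisibly, `path`.
#' @export
write_fold_csv <- function(assignment, ids, path) {
  .stop_if(!inherits(assignment, "fold_assignment"),
           "`assignment` must be a fold_assignment")
  .stop_if(length(ids) != length(assignment$fold),
           "`ids` must match the assignment length")
  utils::write.csv(data.frame(Id = ids, fold = assignment$fold), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a deduplication report as CSV
#'
#' @param report The `report` data frame returned by [deduplicate()]
#'   (columns `removed_id`, `kept_id`, `hamming`).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_dedup_report <- function(report, path) {
  .stop_if(!is.data.frame(report) ||
             !all(c("removed_id", "kept_id", "hamming") %in% names(report)),
           "`report` must be a deduplication report data frame")
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write prediction matrices as CSV
#'
#' Prediction CSVs have an `Id` column followed by one probability column
#' per class (`class_0` ... `class_<C-1>`).
#'
#' @param probs `N x C` probability matrix with sample ids as row names.
#' @param path CSV path.
#' @return `write_predictions_csv` invisibly returns `path`;
#'   `read_predictions_csv` returns the probability matrix with ids as row
#'   names.
#' @export
write_predictions_csv <- function(probs, path) {
  .stop_if(!is.matrix(probs) || is.null(rownames(probs)),
           "`probs` must be a matrix with sample ids as row names")
  df <- data.frame(Id = rownames(probs), probs, check.names = FALSE)
  names(df)[-1L] <- sprintf("class_%d", seq_len(ncol(probs)) - 1L)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_predictions_csv
#' @export
read_predictions_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  .stop_if(names(df)[1L] != "Id", "prediction CSV must start with an Id column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$Id
  m
}

#' Write per-class decision thresholds as CSV
#'
#' One row per class with columns `class_index` (0-based) and `threshold`.
#'
#' @param thresholds Numeric vector of per-class thresholds.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_thresholds_csv <- function(thresholds, path) {
  utils::write.csv(
    data.frame(class_index = seq_along(thresholds) - 1L,
               threshold = thresholds),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write challenge-format submission CSV
#'
#' Emits `Id,Predicted` rows where `Predicted` holds the space-separated
#' 0-based indices of the predicted classes.
#'
#' @param probs `N x C` probability matrix with sample ids as row names.
#' @param thresholds Scalar or per-class decision thresholds.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_submission_csv <- function(probs, thresholds, path) {
  pred <- apply_thresholds(probs, thresholds)
  predicted <- apply(pred, 1L, function(row)
    paste(which(row == 1L) - 1L, collapse = " "))
  utils::write.csv(data.frame(Id = rownames(probs), Predicted = predicted),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write experiment configurations as YAML
#'
#' Serializes model/head/schedule settings (ACP and head dimensions,
#' learning-rate schedule, E-loss and hard-sampler knobs) so experiments
#' can be configured from a file.
#'
#' @param config Named list of settings.
#' @param path YAML path.
#' @return `write_experiment_config` invisibly returns `path`;
#'   `read_experiment_config` returns the named list.
#' @export
write_experiment_config <- function(config, path) {
  .stop_if(!is.list(config), "`config` must be a list")
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  yaml::read_yaml(path)
}
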