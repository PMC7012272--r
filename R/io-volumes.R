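# NIfTI input, block-schedule parsing, and the labeled-sample container.

#' Movement class labels
#'
#' The five movement classes of the motor task (left hand, right hand,
#' left foot, right foot, tongue) plus the fixation label used for
#' baseline blocks.
#'
#' @format Character vectors.
#' @name labels
NULL

#' @rdname labels
#' @export
MOVEMENT_CLASSES <- c("LH", "RH", "LF", "RF", "T")

#' @rdname labels
#' @export
BLOCK_LABELS <- c("FIXATION", MOVEMENT_CLASSES)

new_error <- function(msg, class) {
  structure(class = c(class, "triplanar_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Load a 4D NIfTI volume
#'
#' Reads a `.nii` / `.nii.gz` file (header scaling applied by the reader)
#' and wraps it as a `volume4d` object: the raw 4D array, the spatial
#' affine, and a subject identifier.
#'
#' @param path Path to a NIfTI file with exactly four dimensions.
#' @param subject_id Identifier attached to all samples later extracted
#'   from this volume; defaults to the file name without extension.
#' @return A `volume4d`: list with elements `data` (4D array), `affine`
#'   (4 x 4 matrix), `subject_id`.
#' @export
load_volume4d <- function(path, subject_id = NULL) {
  if (!file.exists(path)) {
    stop(new_error(paste0("file not found: ", path), "triplanar_missing_file"))
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stop(new_error(paste0("unreadable NIfTI file: ", path,
                                          " (", conditionMessage(e), ")"),
                                   "triplanar_bad_header"))
                  })
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) {
    stop(new_error(paste0("expected a 4D volume, got ", length(dim(arr)),
                          " dimensions in ", path),
                   "triplanar_not_4d"))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  volume4d(arr, affine = structure(RNifti::xform(img), code = NULL),
           subject_id = subject_id)
}

#' Construct a volume4d in memory
#'
#' @param data A 4D numeric array `(dimX, dimY, dimZ, T)` of finite values.
#' @param affine Optional 4 x 4 spatial transform (defaults to identity).
#' @param subject_id Subject identifier string.
#' @return A `volume4d` object.
#' @export
volume4d <- function(data, affine = diag(4), subject_id = "subject") {
  if (!(is.array(data) && length(dim(data)) == 4L)) {
    stop(new_error("volume4d data must be a 4D array", "triplanar_not_4d"))
  }
  if (any(dim(data) < 1L)) stop("all four dimensions must be >= 1")
  if (!all(is.finite(data))) {
    stop(new_error("volume4d data contains non-finite values",
                   "triplanar_nonfinite"))
  }
  structure(list(data = data, affine = affine,
                 subject_id = as.character(subject_id)),
            class = "volume4d")
}

#' Write a volume4d to a NIfTI file
#'
#' @param vol A `volume4d`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume4d <- function(vol, path) {
  stopifnot(inherits(vol, "volume4d"))
  RNifti::writeNifti(RNifti::asNifti(vol$data), path)
  invisible(path)
}

#' Construct and validate a block schedule
#'
#' A block schedule lists the task blocks of one scan: for each block its
#' first frame (0-based), its number of frames, and its label (fixation or
#' one of the five movement classes). Frames are half-open intervals
#' `[start_frame, start_frame + n_frames)`; blocks must not overlap and
#' must lie within `[0, T)` when `T` is supplied.
#'
#' @param blocks A data frame with columns `start_frame`, `n_frames`,
#'   `label`.
#' @param T Total frame count of the parent volume (optional bound check).
#' @return A `block_schedule`: the validated data frame, ordered by
#'   `start_frame`.
#' @export
block_schedule <- function(blocks, T = NULL) {
  req <- c("start_frame", "n_frames", "label")
  if (!all(req %in% names(blocks))) {
    stop(new_error(paste0("schedule must have columns ",
                          paste(req, collapse = ", ")),
                   "triplanar_bad_schedule"))
  }
  blocks <- as.data.frame(blocks)[req]
  blocks$start_frame <- as.integer(blocks$start_frame)
  blocks$n_frames <- as.integer(blocks$n_frames)
  blocks$label <- as.character(blocks$label)
  bad <- setdiff(blocks$label, BLOCK_LABELS)
  if (length(bad)) {
    stop(new_error(paste0("unknown block label(s): ",
                          paste(unique(bad), collapse = ", ")),
                   "triplanar_bad_label"))
  }
  if (any(blocks$n_frames < 1L) || any(blocks$start_frame < 0L)) {
    stop(new_error("blocks need start_frame >= 0 and n_frames >= 1",
                   "triplanar_bad_schedule"))
  }
  blocks <- blocks[order(blocks$start_frame), , drop = FALSE]
  rownames(blocks) <- NULL
  ends <- blocks$start_frame + blocks$n_frames
  if (nrow(blocks) > 1L &&
      any(blocks$start_frame[-1L] < ends[-nrow(blocks)])) {
    stop(new_error("blocks overlap", "triplanar_block_overlap"))
  }
  if (!is.null(T) && any(ends > T)) {
    stop(new_error(paste0("block extends past the last frame (T = ", T, ")"),
                   "triplanar_block_overrun"))
  }
  structure(blocks, class = c("block_schedule", "data.frame"))
}

#' Read a block schedule from a tab-separated file
#'
#' The file format is a TSV with a header line and columns
#' `start_frame`, `n_frames`, `label`; times are in frames (0-based,
#' half-open), not seconds. The motor-task layout is 13 rows: 3 fixation
#' blocks intermixed with 10 movement blocks (2 per class).
#'
#' @param path Path to the TSV file.
#' @param T Total frame count of the parent volume (optional bound check).
#' @return A `block_schedule`.
#' @export
load_block_schedule <- function(path, T = NULL) {
  if (!file.exists(path)) {
    stop(new_error(paste0("file not found: ", path), "triplanar_missing_file"))
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  block_schedule(df, T = T)
}

#' Write a block schedule to a tab-separated file
#'
#' @param schedule A `block_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_block_schedule <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Labeled 3D sample
#'
#' One movement block collapsed to a single 3D volume, together with its
#' movement label and the identifier of the subject it came from.
#'
#' @param volume A 3D numeric array.
#' @param label One of `MOVEMENT_CLASSES`.
#' @param subject_id Subject identifier string.
#' @return A `sample3d` object.
#' @export
sample3d <- function(volume, label, subject_id) {
  check_3d(volume)
  label <- as.character(label)
  if (!label %in% MOVEMENT_CLASSES) {
    stop(new_error(paste0("unknown movement label: ", label),
                   "triplanar_bad_label"))
  }
  structure(list(volume = volume, label = label,
                 subject_id = as.character(subject_id)),
            class = "sample3d")
}

#' Bundle samples into a single container
#'
#' Stacks a list of `sample3d` objects (all sharing one shape) into one
#' container holding a 4D volume array plus parallel label and subject-id
#' vectors. The container is what the training harness consumes.
#'
#' @param samples A list of `sample3d` objects.
#' @return A `sample_set`: list with `volumes` (4D array, samples on the
#'   4th axis), `labels`, `subject_ids`, `dims`.
#' @export
sample_set <- function(samples) {
  if (length(samples) == 0L) {
    return(structure(list(volumes = array(numeric(0), c(0L, 0L, 0L, 0L)),
                          labels = character(0), subject_ids = character(0),
                          dims = c(0L, 0L, 0L)),
                     class = "sample_set"))
  }
  dims <- dim(samples[[1L]]$volume)
  same <- vapply(samples, function(s) identical(dim(s$volume), dims), logical(1))
  if (!all(same)) {
    stop(new_error("all samples must share one shape", "triplanar_mixed_shapes"))
  }
  vols <- array(0, c(dims, length(samples)))
  for (i in seq_along(samples)) vols[, , , i] <- samples[[i]]$volume
  structure(list(volumes = vols,
                 labels = vapply(samples, `[[`, character(1), "label"),
                 subject_ids = vapply(samples, `[[`, character(1), "subject_id"),
                 dims = dims),
            class = "sample_set")
}

#' Number of samples in a sample_set
#' @param set A `sample_set`.
#' @return Integer count.
#' @export
n_samples <- function(set) length(set$labels)

#' Subset a sample_set by index
#' @param set A `sample_set`.
#' @param idx Integer indices of the samples to keep.
#' @return A `sample_set`.
#' @export
subset_samples <- function(set, idx) {
  structure(list(volumes = set$volumes[, , , idx, drop = FALSE],
                 labels = set$labels[idx],
                 subject_ids = set$subject_ids[idx],
                 dims = set$dims),
            class = "sample_set")
}

#' Save / load labeled samples
#'
#' Persists a sample container (or a list of `sample3d`) to a single file
#' holding the volume array, the labels and the subject ids; the round
#' trip is lossless. The file is a serialized R object, one file per
#' dataset.
#'
#' @param samples A `sample_set` or list of `sample3d` objects.
#' @param path Destination file.
#' @return `save_samples` returns `path` invisibly; `load_samples` returns
#'   a `sample_set`.
#' @export
save_samples <- function(samples, path) {
  if (!inherits(samples, "sample_set")) samples <- sample_set(samples)
  saveRDS(samples, path)
  invisible(path)
}

#' @rdname save_samples
#' @export
load_samples <- function(path) {
  if (!file.exists(path)) {
    stop(new_error(paste0("file not found: ", path), "triplanar_missing_file"))
  }
  obj <- readRDS(path)
  if (!inherits(obj, "sample_set")) {
    stop(new_error("file does not contain a sample_set", "triplanar_bad_container"))
  }
  obj
}

#' Write a metrics report table
#'
#' Writes per-fold metrics as CSV with columns
#' `fold, model, accuracy, precision, f1`.
#'
#' @param reports A list of `metrics_report` objects (see [evaluate()]).
#' @param model Model name recorded in the `model` column.
#' @param path Output CSV path.
#' @return The data frame written, invisibly.
#' @export
write_metrics_csv <- function(reports, model, path) {
  df <- data.frame(fold = seq_along(reports) - 1L,
                   model = model,
                   accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
                   precision = vapply(reports, `[[`, numeric(1), "precision"),
                   f1 = vapply(reports, `[[`, numeric(1), "f1"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
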