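# Deterministic transforms from a 3D volume to each model family's input
# representation. Axes are addressed by array position (1, 2, 3); anatomical
# names (coronal/sagittal/axial) are used only in the documentation because
# their mapping onto array axes varies across conventions.

#' Slice a 3D volume into a multichannel 2D image along one axis
#'
#' Slicing a volume of extent `(d1, d2, d3)` along axis `a` yields `d_a`
#' planar slices; stacking those slices as channels gives a single 2D image
#' of shape `(H, W, C = d_a)` where `H` and `W` are the two remaining
#' extents in order. The transform is a pure axis permutation: no value is
#' changed or lost, and [stack_to_volume()] inverts it exactly.
#'
#' @param sample A 3D numeric array.
#' @param axis Which array axis (1, 2 or 3) becomes the channel axis.
#' @return A `planar_stack`: a 3D array `(H, W, C)` with attribute `axis`.
#' @seealso [to_triplanar()], [stack_to_volume()]
#' @export
to_planar_stack <- function(sample, axis = 3L) {
  check_3d(sample)
  axis <- as.integer(axis)
  stopifnot(axis %in% 1:3)
  perm <- c(setdiff(1:3, axis), axis)
  out <- aperm(sample, perm)
  structure(out, axis = axis, class = c("planar_stack", class(out)))
}

#' Reassemble a volume from a planar stack
#'
#' Inverts [to_planar_stack()]: channel `c` of the stack is placed back as
#' the volume's slice at position `c` along the stack's `axis`.
#'
#' @param stack A `planar_stack` (or any 3D array with an `axis` attribute).
#' @param axis Channel axis in the original volume; defaults to the stack's
#'   `axis` attribute.
#' @return The reconstructed 3D array.
#' @export
stack_to_volume <- function(stack, axis = attr(stack, "axis")) {
  check_3d(stack)
  stopifnot(!is.null(axis), axis %in% 1:3)
  perm <- c(setdiff(1:3, axis), axis)
  out <- aperm(unclass_stack(stack), order(perm))
  attr(out, "axis") <- NULL
  out
}

unclass_stack <- function(x) {
  attr(x, "axis") <- NULL
  class(x) <- NULL
  x
}

#' Tri-planar decomposition of a 3D volume
#'
#' Produces the three multichannel 2D images used by the tri-planar
#' multichannel model: slicing a `(d1, d2, d3)` volume along each of its
#' three axes gives images of shape `(d2, d3)` with `d1` channels,
#' `(d1, d3)` with `d2` channels, and `(d1, d2)` with `d3` channels. All
#' three stacks contain every voxel exactly once, so each reconstructs the
#' source volume via [stack_to_volume()].
#'
#' @param sample A 3D numeric array.
#' @return A list of class `triplanar_input` with elements `x`, `y`, `z`
#'   (the stacks with channel axis 1, 2, 3 respectively).
#' @examples
#' v <- array(rnorm(8), c(2, 2, 2))
#' tp <- to_triplanar(v)
#' identical(stack_to_volume(tp$x), v)
#' @export
to_triplanar <- function(sample) {
  check_3d(sample)
  structure(list(x = to_planar_stack(sample, 1L),
                 y = to_planar_stack(sample, 2L),
                 z = to_planar_stack(sample, 3L)),
            class = "triplanar_input")
}

#' Axial multichannel image (single-plane model input)
#'
#' The single-plane 2D model uses only the stack sliced along the third
#' array axis: a `(d1, d2)` image with `d3` channels.
#'
#' @inheritParams to_triplanar
#' @return A `planar_stack` of shape `(d1, d2, d3)` with `axis = 3`.
#' @export
to_axial_stack <- function(sample) to_planar_stack(sample, 3L)

#' Mean-value 2D projection
#'
#' Collapses the third array axis by averaging: `out[i, j] = mean_k
#' sample[i, j, k]`. Unlike the slicing transforms this is a projection and
#' is not invertible.
#'
#' @inheritParams to_triplanar
#' @return A 2D numeric matrix of shape `(d1, d2)`.
#' @export
to_mean_value_2d <- function(sample) {
  check_3d(sample)
  rowMeans(sample, dims = 2L)
}

#' Vector-sequence representation for the 1D model
#'
#' Slices the volume along the third axis into `d3` planar images of shape
#' `(d1, d2)` and concatenates them, in slice order, along the second axis.
#' The result is a sequence of length `L = d2 * d3` with `F = d1` features
#' per step; step `s` (0-based) holds the fibre at `(y = s mod d2,
#' z = s div d2)`, i.e. the second axis varies fastest within each slice.
#' A 91 x 109 x 91 volume maps to a 9,919-step, 91-feature sequence.
#'
#' @inheritParams to_triplanar
#' @return A numeric matrix `(L, F)`.
#' @export
to_sequence_1d <- function(sample) {
  check_3d(sample)
  d <- dim(sample)
  t(matrix(sample, d[1L], d[2L] * d[3L]))
}

#' Flatten a volume to a feature vector
#'
#' Used by the PCA+SVM baseline. The order is R's native column-major vec
#' order (first axis fastest); it is fixed and identical for every sample,
#' which is all the downstream linear model requires. A 91 x 109 x 91
#' volume yields 902,629 features.
#'
#' @inheritParams to_triplanar
#' @return A numeric vector of length `d1 * d2 * d3`.
#' @export
flatten_for_svm <- function(sample) {
  check_3d(sample)
  as.vector(sample)
}

check_3d <- function(x) {
  if (!(is.array(x) && length(dim(x)) == 3L)) {
    stop("expected a 3D array, got ",
         if (is.array(x)) paste0(length(dim(x)), "D array") else class(x)[1L],
         call. = FALSE)
  }
  invisible(x)
}
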