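#' Core volumetric data types
#'
#' A `vox_volume` is a 3D grid of real intensities with physical voxel spacing;
#' a `vox_labelmap` is a 3D grid of integer class labels in `0:(num_classes-1)`;
#' a `vox_probmap` is a per-voxel class-probability stack of dimension
#' `C x H x W x S`. Grids are indexed `(x, y, z) = (H, W, S)` in voxel units —
#' one convention everywhere.
#'
#' @param voxels numeric 3D array of intensities (all finite).
#' @param spacing numeric length-3 vector, mm per voxel along each axis (> 0).
#' @param id free-text identifier.
#' @return `volume()` returns a `vox_volume`; `labelmap()` a `vox_labelmap`;
#'   `probmap()` a `vox_probmap`.
#' @examples
#' v <- volume(array(rnorm(8), c(2, 2, 2)), spacing = c(1, 1, 1), id = "toy")
#' lm <- labelmap(array(0L, c(2, 2, 2)), num_classes = 2)
#' @export
volume <- function(voxels, spacing = c(1, 1, 1), id = "volume") {
  vox_assert(is.array(voxels) && length(dim(voxels)) == 3L,
             "voxels must be a 3D array", "voxseg_error_not_3d")
  vox_assert(all(is.finite(voxels)),
             "volume intensities must all be finite", "voxseg_error_nonfinite")
  spacing <- as.numeric(spacing)
  vox_assert(length(spacing) == 3L && all(is.finite(spacing)) && all(spacing > 0),
             "spacing must be three positive values", "voxseg_error_bad_spacing")
  structure(list(voxels = voxels, spacing = spacing, id = as.character(id)[1]),
            class = "vox_volume")
}

#' @rdname volume
#' @param labels integer-valued 3D array of class labels.
#' @param num_classes number of classes `C >= 2`; labels must lie in
#'   `0:(num_classes-1)`. Defaults to `max(labels) + 1` (at least 2).
#' @export
labelmap <- function(labels, num_classes = NULL) {
  vox_assert(is.array(labels) && length(dim(labels)) == 3L,
             "labels must be a 3D array", "voxseg_error_not_3d")
  vox_assert(all(is.finite(labels)) && all(labels == round(labels)),
             "labels must be integer-valued", "voxseg_error_noninteger_label")
  if (is.null(num_classes)) num_classes <- max(2L, as.integer(max(labels)) + 1L)
  num_classes <- as.integer(num_classes)
  vox_assert(num_classes >= 2L, "num_classes must be >= 2",
             "voxseg_error_bad_classes")
  vox_assert(min(labels) >= 0 && max(labels) <= num_classes - 1L,
             sprintf("labels must lie in 0..%d", num_classes - 1L),
             "voxseg_error_invalid_label")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, num_classes = num_classes),
            class = "vox_labelmap")
}

#' @rdname volume
#' @param probs numeric 4D array `C x H x W x S`; entries in `[0, 1]`,
#'   per-voxel class sums equal to 1 within `1e-6`.
#' @export
probmap <- function(probs) {
  vox_assert(is.array(probs) && length(dim(probs)) == 4L,
             "probs must be a 4D array (C x H x W x S)", "voxseg_error_not_4d")
  vox_assert(all(probs >= -1e-12 & probs <= 1 + 1e-12),
             "probabilities must lie in [0, 1]", "voxseg_error_bad_prob")
  sums <- colSums(matrix(probs, nrow = dim(probs)[1]))
  vox_assert(all(abs(sums - 1) <= 1e-6),
             "per-voxel class probabilities must sum to 1",
             "voxseg_error_unnormalized")
  structure(list(probs = probs), class = "vox_probmap")
}

#' Pair a volume with labels
#'
#' @param volume a [volume()].
#' @param labels a [labelmap()] of the same spatial shape.
#' @param source `"true_label"` for expert truth, `"pseudo_label"` for
#'   machine-generated pseudo-labels.
#' @return a `vox_pair`.
#' @export
labeled_pair <- function(volume, labels, source = c("true_label", "pseudo_label")) {
  source <- match.arg(source)
  vox_assert(inherits(volume, "vox_volume") && inherits(labels, "vox_labelmap"),
             "need a vox_volume and a vox_labelmap", "voxseg_error_bad_type")
  vox_assert(identical(dim(volume$voxels), dim(labels$labels)),
             "volume and labels shapes must agree", "voxseg_error_shape_mismatch")
  structure(list(volume = volume, labels = labels, source = source),
            class = "vox_pair")
}

#' Labeled/unlabeled dataset split for self-training
#'
#' @param labeled list of `vox_pair` with `source = "true_label"`.
#' @param unlabeled list of [volume()].
#' @param round_index completed self-training rounds (>= 0).
#' @return a `vox_split`.
#' @export
dataset_split <- function(labeled, unlabeled = list(), round_index = 0L) {
  vox_assert(all(vapply(labeled, inherits, TRUE, "vox_pair")),
             "labeled must be a list of vox_pair", "voxseg_error_bad_type")
  vox_assert(all(vapply(labeled, function(p) p$source == "true_label", TRUE)),
             "all labeled pairs must carry true labels", "voxseg_error_bad_source")
  vox_assert(all(vapply(unlabeled, inherits, TRUE, "vox_volume")),
             "unlabeled must be a list of vox_volume", "voxseg_error_bad_type")
  ids_l <- vapply(labeled, function(p) p$volume$id, "")
  ids_u <- vapply(unlabeled, function(v) v$id, "")
  vox_assert(!anyDuplicated(c(ids_l, ids_u)),
             "a volume id appears in both labeled and unlabeled sets",
             "voxseg_error_id_collision")
  structure(list(labeled = labeled, unlabeled = unlabeled,
                 round_index = as.integer(round_index)),
            class = "vox_split")
}

#' @export
print.vox_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<vox_volume '%s'> %d x %d x %d voxels, spacing %s mm\n",
              x$id, d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' @export
print.vox_labelmap <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<vox_labelmap> %d x %d x %d voxels, %d classes\n",
              d[1], d[2], d[3], x$num_classes))
  invisible(x)
}

#' @export
print.vox_split <- function(x, ...) {
  cat(sprintf("<vox_split> %d labeled, %d unlabeled, round %d\n",
              length(x$labeled), length(x$unlabeled), x$round_index))
  invisible(x)
}

# per-voxel argmax labeling of a probability stack
argmax_labels <- function(pm) {
  probs <- if (inherits(pm, "vox_probmap")) pm$probs else pm
  d <- dim(probs)
  flat <- matrix(probs, nrow = d[1])
  lab <- max.col(t(flat), ties.method = "first") - 1L
  labelmap(array(lab, d[2:4]), num_classes = d[1])
}
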