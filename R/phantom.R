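#' Knee-like 3D phantom configuration
#'
#' Phantoms emulate the geometry the segmentation method targets: a bright
#' convex "bone" body (a randomized ellipsoid) wrapped by a thin curved
#' "cartilage" shell over a darker background, with additive Gaussian noise
#' and an optional smooth multiplicative intensity-bias field. Labels are
#' exact (noise-free): 0 = background, 1 = bone, 2 = cartilage shell.
#'
#' @param shape spatial dimensions `(H, W, S)`, each divisible by 16.
#' @param num_classes 3 (bone + shell, default) or 2 (bone only).
#' @param bone_radius_range ellipsoid semi-axis range as a fraction of the
#'   grid size.
#' @param shell_thickness cartilage shell thickness in voxels (>= 1).
#' @param class_means per-class mean intensity (length `num_classes`,
#'   pairwise distinct).
#' @param noise_sigma additive Gaussian noise sd (>= 0).
#' @param bias_field add a smooth low-frequency multiplicative field.
#' @param spacing voxel spacing recorded on generated volumes (mm).
#' @param seed RNG seed; the phantom is fully determined by it.
#' @return a `vox_phantomcfg`.
#' @export
phantom_config <- function(shape = c(32, 32, 32), num_classes = 3L,
                           bone_radius_range = c(0.18, 0.30),
                           shell_thickness = 2L,
                           class_means = c(0.25, 0.85, 0.55),
                           noise_sigma = 0.08, bias_field = FALSE,
                           spacing = c(1, 1, 1), seed = 1L) {
  num_classes <- as.integer(num_classes)
  vox_assert(num_classes %in% c(2L, 3L), "num_classes must be 2 or 3",
             "voxseg_error_bad_config")
  class_means <- as.numeric(class_means)[seq_len(num_classes)]
  vox_assert(!anyDuplicated(class_means),
             "class_means must be pairwise distinct", "voxseg_error_bad_config")
  vox_assert(shell_thickness >= 1, "shell_thickness must be >= 1",
             "voxseg_error_bad_config")
  vox_assert(noise_sigma >= 0, "noise_sigma must be >= 0",
             "voxseg_error_bad_config")
  vox_assert(length(shape) == 3 && all(shape >= 16),
             "shape must be three sizes >= 16", "voxseg_error_bad_config")
  structure(list(shape = as.integer(shape), num_classes = num_classes,
                 bone_radius_range = as.numeric(bone_radius_range),
                 shell_thickness = as.integer(shell_thickness),
                 class_means = class_means, noise_sigma = noise_sigma,
                 bias_field = isTRUE(bias_field),
                 spacing = as.numeric(spacing), seed = as.integer(seed)),
            class = "vox_phantomcfg")
}

smooth_bias_field <- function(shape, amplitude = 0.15) {
  # three random low-frequency cosines, one per axis, multiplied together
  gx <- seq(0, 1, length.out = shape[1])
  gy <- seq(0, 1, length.out = shape[2])
  gz <- seq(0, 1, length.out = shape[3])
  f <- runif(3, 0.5, 1.5); ph <- runif(3, 0, 2 * pi)
  bx <- cos(2 * pi * f[1] * gx + ph[1])
  by <- cos(2 * pi * f[2] * gy + ph[2])
  bz <- cos(2 * pi * f[3] * gz + ph[3])
  1 + amplitude * outer(outer(bx, by), bz)
}

#' Generate one phantom
#'
#' @param cfg a [phantom_config()].
#' @param id identifier for the generated volume.
#' @return `list(volume = vox_volume, labels = vox_labelmap)`.
#' @export
generate_phantom <- function(cfg = phantom_config(), id = "phantom") {
  set.seed(cfg$seed)
  d <- cfg$shape; t <- cfg$shell_thickness
  radii <- runif(3, cfg$bone_radius_range[1], cfg$bone_radius_range[2]) * d
  margin <- radii + t + 1
  # the center must have room on both sides: margin <= d - 1 - margin
  vox_assert(all(2 * margin <= d - 1),
             "cartilage shell would exceed the grid for this configuration",
             "voxseg_error_shell_overflow")
  center <- vapply(1:3, function(a) runif(1, margin[a], d[a] - 1 - margin[a]),
                   numeric(1))
  x <- (0:(d[1] - 1) - center[1]) / radii[1]
  y <- (0:(d[2] - 1) - center[2]) / radii[2]
  z <- (0:(d[3] - 1) - center[3]) / radii[3]
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  bone <- r2 <= 1
  labels <- array(0L, d)
  labels[bone] <- 1L
  if (cfg$num_classes == 3L) {
    shell <- dilate_ball(bone, t) & !bone
    labels[shell] <- 2L
  }
  vox <- array(cfg$class_means[labels + 1L], d)
  if (cfg$bias_field) vox <- vox * smooth_bias_field(d)
  if (cfg$noise_sigma > 0) vox <- vox + rnorm(length(vox), 0, cfg$noise_sigma)
  list(volume = volume(vox, spacing = cfg$spacing, id = id),
       labels = labelmap(labels, num_classes = cfg$num_classes))
}

#' Generate a labeled/unlabeled/test dataset of phantoms
#'
#' Each phantom gets its own seed derived from the master seed, a unique id,
#' and its split. The truth labels of the unlabeled volumes are returned in a
#' separate `hidden_truth` side-car (keyed by id) for evaluation only — they
#' never enter the [dataset_split()] itself, so training cannot leak them.
#'
#' @param cfg a [phantom_config()] (its `seed` field is ignored here).
#' @param n_labeled,n_unlabeled,n_test split sizes (>= 0).
#' @param seed master seed.
#' @return `list(split = vox_split, test = list of labeled_pair,
#'   hidden_truth = named list of labelmaps)`.
#' @export
generate_dataset <- function(cfg = phantom_config(), n_labeled, n_unlabeled,
                             n_test, seed = 1L) {
  n <- n_labeled + n_unlabeled + n_test
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("%s_%03d",
                 rep(c("lab", "unl", "tst"),
                     c(n_labeled, n_unlabeled, n_test)),
                 seq_len(n))
  make <- function(k) {
    ck <- cfg; ck$seed <- seeds[k]
    generate_phantom(ck, id = ids[k])
  }
  labeled <- lapply(seq_len(n_labeled), function(k) {
    ph <- make(k); labeled_pair(ph$volume, ph$labels, "true_label")
  })
  unl_idx <- n_labeled + seq_len(n_unlabeled)
  unl <- lapply(unl_idx, make)
  unlabeled <- lapply(unl, `[[`, "volume")
  hidden <- setNames(lapply(unl, `[[`, "labels"),
                     vapply(unlabeled, `[[`, "", "id"))
  test <- lapply(n_labeled + n_unlabeled + seq_len(n_test), function(k) {
    ph <- make(k); labeled_pair(ph$volume, ph$labels, "true_label")
  })
  list(split = dataset_split(labeled, unlabeled, round_index = 0L),
       test = test, hidden_truth = hidden)
}

#' Corrupt a label map at class boundaries
#'
#' Emulates the rough pseudo-label edges the CRF refinement is meant to fix:
#' every voxel adjacent (6-neighborhood) to a different class is flipped,
#' with probability `boundary_flip_rate`, to one of the differing neighbor
#' classes (chosen uniformly). Interior voxels are untouched.
#'
#' @param lm a [labelmap()].
#' @param boundary_flip_rate flip probability in [0, 1].
#' @param seed RNG seed.
#' @return the corrupted [labelmap()].
#' @export
corrupt_labels <- function(lm, boundary_flip_rate, seed = 1L) {
  vox_assert(boundary_flip_rate >= 0 && boundary_flip_rate <= 1,
             "boundary_flip_rate must lie in [0, 1]", "voxseg_error_bad_config")
  if (boundary_flip_rate == 0) return(lm)
  set.seed(seed)
  lab <- lm$labels
  d <- dim(lab); N <- prod(d)
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nb <- matrix(-1L, 6, N)  # -1 marks out-of-grid
  for (k in 1:6) {
    sh <- shifts[[k]]
    shifted <- shift_mask(lab + 1L, sh[1], sh[2], sh[3], fill = 0L)
    nb[k, ] <- as.integer(shifted) - 1L
  }
  own <- as.integer(lab)
  band <- which(colSums(nb >= 0 & nb != rep(own, each = 6)) > 0)
  flip <- band[runif(length(band)) < boundary_flip_rate]
  for (i in flip) {
    cand <- unique(nb[, i])
    cand <- cand[cand >= 0 & cand != own[i]]
    own[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  labelmap(array(own, d), num_classes = lm$num_classes)
}
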