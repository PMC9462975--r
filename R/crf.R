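#' Fully-connected CRF configuration
#'
#' The CRF energy over a labeling f is
#' `E(f) = sum_i psi_u(f_i) + sum_{i<j} mu(f_i, f_j) * k(i, j)` with Potts
#' compatibility `mu(a, b) = 1[a != b]` and the label-independent two-kernel
#' sum `k(i,j) = omega1 * exp(-|x_i-x_j|^2 / (2 sigma_alpha^2)
#' - (y_i-y_j)^2 / (2 sigma_beta^2)) + omega2 * exp(-|x_i-x_j|^2 /
#' (2 sigma_gamma^2))`, where x are voxel positions and y the [0,1]-normalized
#' intensities. The unary potential is `psi_u = -log P` from the network's
#' softmax output.
#'
#' @param omega1,omega2 non-negative weights of the appearance and smoothness
#'   kernels.
#' @param sigma_alpha positional scale of the appearance kernel (voxels).
#' @param sigma_beta intensity scale of the appearance kernel (on [0,1]
#'   normalized intensities).
#' @param sigma_gamma positional scale of the smoothness kernel (voxels,
#'   default 1: removes small independent regions).
#' @param iterations mean-field iterations (default 5).
#' @param unary_clamp finite ceiling substituted for `-log 0`.
#' @param neighborhood_radius 0 runs the exact dense O(N^2) message pass
#'   (guarded by `dense_limit`); a positive radius r truncates messages to the
#'   cubic neighborhood of side 2r+1 so large volumes stay tractable.
#' @param dense_limit largest voxel count accepted in dense mode.
#' @return a `vox_crfcfg`.
#' @export
crf_config <- function(omega1 = 1, omega2 = 1, sigma_alpha = 3,
                       sigma_beta = 0.1, sigma_gamma = 1, iterations = 5L,
                       unary_clamp = 50, neighborhood_radius = 0L,
                       dense_limit = 4096L) {
  vox_assert(omega1 >= 0 && omega2 >= 0, "kernel weights must be >= 0",
             "voxseg_error_bad_config")
  vox_assert(sigma_alpha > 0 && sigma_beta > 0 && sigma_gamma > 0,
             "all sigma must be > 0", "voxseg_error_bad_config")
  vox_assert(iterations >= 0, "iterations must be >= 0",
             "voxseg_error_bad_config")
  structure(list(omega1 = omega1, omega2 = omega2, sigma_alpha = sigma_alpha,
                 sigma_beta = sigma_beta, sigma_gamma = sigma_gamma,
                 iterations = as.integer(iterations),
                 unary_clamp = unary_clamp,
                 neighborhood_radius = as.integer(neighborhood_radius),
                 dense_limit = as.integer(dense_limit)),
            class = "vox_crfcfg")
}

#' Unary potentials from softmax probabilities
#'
#' `psi_u = -log P` elementwise; probabilities below `exp(-clamp)` are clamped
#' so the potential never exceeds `clamp` (removes the P = 0 singularity).
#'
#' @param pm a [probmap()].
#' @param clamp finite ceiling for the potential.
#' @return a `vox_unary` (4D array of potentials, all finite and >= 0).
#' @export
unary_from_probability <- function(pm, clamp = 50) {
  vox_assert(inherits(pm, "vox_probmap"), "pm must be a vox_probmap",
             "voxseg_error_bad_type")
  u <- -log(pmax(pm$probs, exp(-clamp)))
  structure(list(potentials = u), class = "vox_unary")
}

#' Label-independent pairwise kernel between two voxels
#'
#' @param i,j length-3 voxel coordinates (0-based, `(x, y, z)`); must differ.
#' @param vol the [volume()] supplying intensities (normalized to [0,1]).
#' @param cfg a [crf_config()].
#' @return the kernel value `k(i, j) >= 0`, symmetric in its arguments.
#' @export
pairwise_kernel <- function(i, j, vol, cfg) {
  i <- as.numeric(i); j <- as.numeric(j)
  vox_assert(!all(i == j), "self-pair: i and j must be distinct voxels",
             "voxseg_error_self_pair")
  vox_assert(inherits(vol, "vox_volume"), "vol must be a vox_volume",
             "voxseg_error_bad_type")
  inten <- normalize_intensity(vol$voxels)
  yi <- inten[matrix(i + 1, 1)]; yj <- inten[matrix(j + 1, 1)]
  d2 <- sum((i - j)^2)
  cfg$omega1 * exp(-d2 / (2 * cfg$sigma_alpha^2) -
                   (yi - yj)^2 / (2 * cfg$sigma_beta^2)) +
    cfg$omega2 * exp(-d2 / (2 * cfg$sigma_gamma^2))
}

# kernel matrix over all voxel pairs of a small grid (normalized intensities)
kernel_matrix <- function(inten, sdim, cfg) {
  N <- prod(sdim)
  n0 <- 0:(N - 1)
  pos <- cbind(n0 %% sdim[1], (n0 %/% sdim[1]) %% sdim[2],
               n0 %/% (sdim[1] * sdim[2]))
  D2 <- as.matrix(stats::dist(pos))^2
  DI <- outer(as.numeric(inten), as.numeric(inten), "-")
  K <- cfg$omega1 * exp(-D2 / (2 * cfg$sigma_alpha^2) -
                        DI^2 / (2 * cfg$sigma_beta^2)) +
    cfg$omega2 * exp(-D2 / (2 * cfg$sigma_gamma^2))
  diag(K) <- 0
  K
}

#' Exact CRF energy of a labeling
#'
#' Sums the selected unary potentials and the Potts pairwise terms over all
#' unordered voxel pairs. Exact and O(N^2): intended for desk-scale instances
#' (<= ~10^3 voxels), where it serves as the inference oracle.
#'
#' @param labels a [labelmap()].
#' @param unary a `vox_unary` from [unary_from_probability()].
#' @param vol the companion [volume()].
#' @param cfg a [crf_config()].
#' @return the scalar energy `E`.
#' @export
total_energy <- function(labels, unary, vol, cfg) {
  sdim <- dim(labels$labels)
  vox_assert(identical(sdim, dim(unary$potentials)[2:4]) &&
               identical(sdim, dim(vol$voxels)),
             "labels, unary, and volume shapes must agree",
             "voxseg_error_shape_mismatch")
  N <- prod(sdim)
  vox_assert(N <= 4096, "instance too large for the exact energy sum",
             "voxseg_error_instance_too_large")
  C <- dim(unary$potentials)[1]
  umat <- matrix(unary$potentials, nrow = C)
  f <- as.integer(labels$labels)
  e_unary <- sum(umat[cbind(f + 1L, seq_len(N))])
  if (N == 1L) return(e_unary)
  K <- kernel_matrix(normalize_intensity(vol$voxels), sdim, cfg)
  diff <- outer(f, f, "!=")
  e_pair <- sum(K[upper.tri(K)] * diff[upper.tri(diff)])
  e_unary + e_pair
}

#' Mean-field refinement of a probability map
#'
#' Runs `cfg$iterations` rounds of mean-field updates on the fully-connected
#' Potts CRF: Q starts at the network's probabilities; each round, voxel i
#' receives the message `m_i(l) = sum_{j != i} k(i,j) (1 - Q_j(l))` and is
#' updated to the normalized `exp(-psi_u,i(l) - m_i(l))`. The refined label
#' map is the per-voxel argmax of the final Q. With
#' `neighborhood_radius = 0` the message pass is exact and dense (guarded by
#' `dense_limit`); a positive radius truncates it for large volumes.
#'
#' @param pm a [probmap()].
#' @param vol the companion [volume()] (same spatial shape).
#' @param cfg a [crf_config()].
#' @return `list(probs = refined probmap, labels = refined labelmap)`.
#' @export
mean_field_refine <- function(pm, vol, cfg = crf_config()) {
  vox_assert(inherits(pm, "vox_probmap") && inherits(vol, "vox_volume"),
             "need a vox_probmap and a vox_volume", "voxseg_error_bad_type")
  d <- dim(pm$probs)
  vox_assert(identical(d[2:4], dim(vol$voxels)),
             "probability map and volume shapes must agree",
             "voxseg_error_shape_mismatch")
  N <- prod(d[2:4])
  if (cfg$omega1 == 0 && cfg$omega2 == 0)
    return(list(probs = pm, labels = argmax_labels(pm)))
  if (cfg$neighborhood_radius <= 0L)
    vox_assert(N <= cfg$dense_limit,
               paste0("instance too large for dense message passing; set ",
                      "neighborhood_radius > 0 for the truncated approximation"),
               "voxseg_error_instance_too_large")
  u <- unary_from_probability(pm, cfg$unary_clamp)
  umat <- matrix(u$potentials, nrow = d[1])
  inten <- normalize_intensity(vol$voxels)
  Q <- cpp_crf_meanfield(umat, as.numeric(inten),
                         d[2], d[3], d[4],
                         cfg$omega1, cfg$omega2, cfg$sigma_alpha,
                         cfg$sigma_beta, cfg$sigma_gamma,
                         cfg$iterations, cfg$neighborhood_radius)
  qpm <- probmap(array(Q, d))
  list(probs = qpm, labels = argmax_labels(qpm))
}

#' Globally optimal labeling by exhaustive enumeration
#'
#' Enumerates every labeling of a tiny instance and returns the one with
#' minimal [total_energy()]; ties break to the lexicographically smallest
#' labeling (voxel 1 most significant). A test oracle — the instance must
#' satisfy `C^N <= 2^20`.
#'
#' @inheritParams total_energy
#' @return the minimizing [labelmap()].
#' @export
exhaustive_map <- function(unary, vol, cfg) {
  d <- dim(unary$potentials)
  C <- d[1]; sdim <- d[2:4]; N <- prod(sdim)
  vox_assert(C^N <= 2^20, "instance too large for exhaustive enumeration",
             "voxseg_error_instance_too_large")
  umat <- matrix(unary$potentials, nrow = C)
  M <- C^N
  idx <- 0:(M - 1)
  # f_1 is the most significant digit so enumeration order = lexicographic
  labmat <- matrix(0L, M, N)
  for (i in seq_len(N))
    labmat[, i] <- as.integer((idx %/% C^(N - i)) %% C)
  E <- numeric(M)
  for (i in seq_len(N)) E <- E + umat[cbind(labmat[, i] + 1L, i)]
  if (N > 1L) {
    K <- kernel_matrix(normalize_intensity(vol$voxels), sdim, cfg)
    for (i in seq_len(N - 1L))
      for (j in (i + 1L):N)
        if (K[i, j] != 0)
          E <- E + K[i, j] * (labmat[, i] != labmat[, j])
  }
  best <- which.min(E)  # first hit = lexicographically smallest tie
  labelmap(array(labmat[best, ], sdim), num_classes = C)
}

#' Soften a label map into a probability stack
#'
#' Assigns probability `confidence` to each voxel's label and spreads the
#' remainder uniformly over the other classes — the standard way to feed a
#' hard (pseudo-)labeling to the CRF as unaries.
#'
#' @param lm a [labelmap()].
#' @param confidence probability mass on the given label (in (1/C, 1)).
#' @return a [probmap()].
#' @export
labels_to_probability <- function(lm, confidence = 0.9) {
  C <- lm$num_classes
  vox_assert(confidence > 1 / C && confidence < 1,
             "confidence must lie in (1/C, 1)", "voxseg_error_bad_config")
  d <- dim(lm$labels)
  N <- prod(d)
  P <- matrix((1 - confidence) / (C - 1), C, N)
  P[cbind(as.integer(lm$labels) + 1L, seq_len(N))] <- confidence
  probmap(array(P, c(C, d)))
}
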