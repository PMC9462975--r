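# helpers to build tiny CRF instances directly
raw_unary <- function(u) structure(list(potentials = u), class = "vox_unary")

random_instance <- function(sdim, C = 2, seed = 1) {
  set.seed(seed)
  p <- array(runif(C * prod(sdim)), c(C, sdim))
  p <- sweep(p, 2:4, apply(p, 2:4, sum), "/")
  list(pm = probmap(p),
       vol = volume(array(runif(prod(sdim)), sdim), id = paste0("i", seed)))
}

test_that("unary potentials are -log P with a finite clamp", {
  p <- array(0, c(2, 2, 1, 1))
  p[1, , , ] <- c(1, exp(-1)); p[2, , , ] <- c(0, 1 - exp(-1))
  u <- unary_from_probability(probmap(p), clamp = 50)
  expect_equal(u$potentials[1, 1, 1, 1], 0)            # P = 1
  expect_equal(u$potentials[1, 2, 1, 1], 1)            # P = e^-1
  expect_equal(u$potentials[2, 1, 1, 1], 50)           # P = 0, clamped
  expect_true(all(is.finite(u$potentials)) && all(u$potentials >= 0))
})

test_that("the pairwise kernel reproduces the hand value and is symmetric", {
  cfg <- crf_config(omega1 = 1, omega2 = 1, sigma_alpha = 1, sigma_beta = 1,
                    sigma_gamma = 1)
  vol <- volume(array(0.5, c(2, 1, 1)), id = "two")
  k <- pairwise_kernel(c(0, 0, 0), c(1, 0, 0), vol, cfg)
  expect_equal(k, 2 * exp(-0.5), tolerance = 1e-6)
  expect_error(pairwise_kernel(c(0, 0, 0), c(0, 0, 0), vol, cfg),
               class = "voxseg_error_self_pair")
  expect_equal(pairwise_kernel(c(1, 0, 0), c(0, 0, 0), vol,
                               crf_config(omega1 = 0, omega2 = 0)), 0)
  set.seed(42)
  rvol <- volume(array(runif(64), c(4, 4, 4)), id = "r")
  rcfg <- crf_config(sigma_beta = 0.3)
  for (t in 1:100) {
    ij <- matrix(sample(0:3, 6, replace = TRUE), 2, byrow = TRUE)
    if (all(ij[1, ] == ij[2, ])) next
    expect_equal(pairwise_kernel(ij[1, ], ij[2, ], rvol, rcfg),
                 pairwise_kernel(ij[2, ], ij[1, ], rvol, rcfg))
  }
})

test_that("total energy decomposes into unary and Potts pairwise parts", {
  cfg <- crf_config(omega1 = 1, omega2 = 1, sigma_alpha = 1, sigma_beta = 1,
                    sigma_gamma = 1)
  # single voxel: no pairs
  u1 <- raw_unary(array(c(0.3, 0.9), c(2, 1, 1, 1)))
  v1 <- volume(array(0.5, c(1, 1, 1)), id = "one")
  expect_equal(total_energy(labelmap(array(0L, c(1, 1, 1)), 2), u1, v1, cfg),
               0.3)
  # two voxels, same label: pairwise term vanishes under Potts
  u2 <- raw_unary(array(0.25, c(2, 2, 1, 1)))
  v2 <- volume(array(0.5, c(2, 1, 1)), id = "two")
  expect_equal(total_energy(labelmap(array(0L, c(2, 1, 1)), 2), u2, v2, cfg),
               0.5)
  # two voxels, different labels, zero unaries: energy = kernel value
  u0 <- raw_unary(array(0, c(2, 2, 1, 1)))
  expect_equal(total_energy(labelmap(array(0:1, c(2, 1, 1)), 2), u0, v2, cfg),
               2 * exp(-0.5), tolerance = 1e-6)
  # omega = 0 energy equals the sum of selected unaries on random instances
  for (seed in 1:10) {
    inst <- random_instance(c(2, 2, 2), seed = seed)
    u <- unary_from_probability(inst$pm)
    lab <- argmax_lab <- labelmap(array(sample(0:1, 8, replace = TRUE),
                                        c(2, 2, 2)), 2)
    e <- total_energy(lab, u, inst$vol, crf_config(omega1 = 0, omega2 = 0))
    umat <- matrix(u$potentials, nrow = 2)
    expect_equal(e, sum(umat[cbind(as.integer(lab$labels) + 1, 1:8)]))
  }
})

test_that("mean-field refinement degenerates correctly", {
  inst <- random_instance(c(3, 3, 3), C = 3, seed = 11)
  # no pairwise coupling: argmax unchanged by any number of iterations
  for (iters in c(0L, 1L, 5L, 9L)) {
    r <- mean_field_refine(inst$pm, inst$vol,
                           crf_config(omega1 = 0, omega2 = 0,
                                      iterations = iters))
    expect_identical(r$labels$labels,
                     voxseg:::argmax_labels(inst$pm)$labels)
  }
  # label-symmetric fixed point: uniform Q stays uniform
  up <- probmap(array(1 / 3, c(3, 2, 2, 2)))
  r <- mean_field_refine(up, volume(array(runif(8), c(2, 2, 2)), id = "u"),
                         crf_config(iterations = 5))
  expect_equal(r$probs$probs, up$probs, tolerance = 1e-12)
  # Q stays normalized and shaped after refinement
  r2 <- mean_field_refine(inst$pm, inst$vol, crf_config(iterations = 5))
  expect_equal(dim(r2$probs$probs), dim(inst$pm$probs))
  sums <- colSums(matrix(r2$probs$probs, nrow = 3))
  expect_true(all(abs(sums - 1) < 1e-9))
  # guard: dense message passing refuses oversized instances
  big <- random_instance(c(32, 16, 16), seed = 3)
  expect_error(mean_field_refine(big$pm, big$vol,
                                 crf_config(neighborhood_radius = 0L)),
               class = "voxseg_error_instance_too_large")
})

test_that("mean-field refinement lowers the exact energy on most instances", {
  cfg <- crf_config(sigma_beta = 0.3, iterations = 5)
  better <- 0
  for (seed in 1:100) {
    inst <- random_instance(c(2, 2, 3), seed = seed)
    u <- unary_from_probability(inst$pm)
    mf <- mean_field_refine(inst$pm, inst$vol, cfg)
    e_mf <- total_energy(mf$labels, u, inst$vol, cfg)
    e_am <- total_energy(voxseg:::argmax_labels(inst$pm), u, inst$vol, cfg)
    if (e_mf <= e_am + 1e-12) better <- better + 1
  }
  expect_gte(better, 90)
})

test_that("exhaustive minimization dominates and honors its tie-break", {
  # decoupled voxels: exhaustive = unary argmax
  inst <- random_instance(c(2, 2, 2), seed = 5)
  u <- unary_from_probability(inst$pm)
  cfg0 <- crf_config(omega1 = 0, omega2 = 0)
  expect_identical(exhaustive_map(u, inst$vol, cfg0)$labels,
                   voxseg:::argmax_labels(inst$pm)$labels)
  # 1-voxel 3-class instance with unaries (0.5, 0.1, 0.9)
  u3 <- raw_unary(array(c(0.5, 0.1, 0.9), c(3, 1, 1, 1)))
  v1 <- volume(array(0, c(1, 1, 1)), id = "v")
  expect_equal(as.integer(exhaustive_map(u3, v1, cfg0)$labels), 1L)
  # exact ties break to the lexicographically smallest labeling
  ut <- raw_unary(array(0.5, c(2, 2, 1, 1)))
  v2 <- volume(array(0.5, c(2, 1, 1)), id = "t")
  expect_equal(as.integer(exhaustive_map(ut, v2, cfg0)$labels), c(0L, 0L))
  # global optimality against mean field and raw argmax
  cfg <- crf_config(sigma_beta = 0.3, iterations = 5)
  for (seed in 1:20) {
    inst <- random_instance(c(2, 2, 2), seed = seed + 200)
    u <- unary_from_probability(inst$pm)
    ex <- exhaustive_map(u, inst$vol, cfg)
    e_ex <- total_energy(ex, u, inst$vol, cfg)
    mf <- mean_field_refine(inst$pm, inst$vol, cfg)
    expect_lte(e_ex,
               total_energy(mf$labels, u, inst$vol, cfg) + 1e-12)
    expect_lte(e_ex,
               total_energy(voxseg:::argmax_labels(inst$pm), u, inst$vol,
                            cfg) + 1e-12)
  }
  expect_error(exhaustive_map(raw_unary(array(0.1, c(2, 8, 8, 8))),
                              volume(array(0, c(8, 8, 8)), id = "big"),
                              cfg),
               class = "voxseg_error_instance_too_large")
})

test_that("hard labels soften into valid, label-faithful probabilities", {
  lm <- labelmap(array(c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L), c(2, 2, 2)), 3)
  pm <- labels_to_probability(lm, confidence = 0.8)
  expect_equal(dim(pm$probs), c(3, 2, 2, 2))
  expect_identical(voxseg:::argmax_labels(pm)$labels, lm$labels)
  expect_equal(max(pm$probs), 0.8)
  expect_equal(min(pm$probs), 0.1)
  expect_error(labels_to_probability(lm, confidence = 0.2),
               class = "voxseg_error_bad_config")
})

test_that("truncated-neighborhood messages approximate the dense pass", {
  inst <- random_instance(c(4, 4, 4), seed = 77)
  dense <- mean_field_refine(inst$pm, inst$vol,
                             crf_config(iterations = 3))
  trunc <- mean_field_refine(inst$pm, inst$vol,
                             crf_config(iterations = 3,
                                        neighborhood_radius = 6L))
  # radius >= grid extent: truncation covers every pair, results identical
  expect_equal(trunc$probs$probs, dense$probs$probs, tolerance = 1e-12)
})
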