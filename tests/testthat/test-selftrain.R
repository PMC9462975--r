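make_vols <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    volume(array(runif(8), c(2, 2, 2)), id = sprintf("v%02d", i)))
}

test_that("partitioning is a seeded, balanced, exact cover", {
  vols <- make_vols(10)
  p <- partition_unlabeled(vols, 5, seed = 3)
  expect_true(all(lengths(p) == 2))

  p7 <- partition_unlabeled(make_vols(7), 5, seed = 3)
  expect_equal(sort(lengths(p7), decreasing = TRUE), c(2, 2, 1, 1, 1))

  set.seed(99)
  for (trial in 1:100) {
    n <- sample(1:30, 1); k <- sample(seq_len(n), 1)
    vols <- make_vols(n, seed = trial)
    parts <- partition_unlabeled(vols, k, seed = trial)
    ids <- lapply(parts, function(s) vapply(s, function(v) v$id, ""))
    expect_length(parts, k)
    expect_setequal(unlist(ids), vapply(vols, function(v) v$id, ""))
    expect_equal(sum(lengths(parts)), n)          # disjoint + covering
    expect_lte(diff(range(lengths(parts))), 1)    # balanced
  }
  expect_error(partition_unlabeled(make_vols(3), 4),
               class = "voxseg_error_bad_partition")
  expect_identical(
    vapply(partition_unlabeled(vols, 3, seed = 8)[[1]], function(v) v$id, ""),
    vapply(partition_unlabeled(vols, 3, seed = 8)[[1]], function(v) v$id, ""))
})

test_that("extending the training set is append-only and id-safe", {
  lm <- labelmap(array(0L, c(2, 2, 2)), num_classes = 2)
  cur <- lapply(make_vols(20), function(v) labeled_pair(v, lm))
  ps <- lapply(make_vols(10, seed = 2), function(v) {
    v$id <- paste0("p_", v$id)
    labeled_pair(v, lm, source = "pseudo_label")
  })
  ext <- extend_training_set(cur, ps)
  expect_length(ext, 30)
  expect_identical(ext[1:20], cur)     # truth pairs pass through unmodified
  expect_identical(extend_training_set(cur, list()), cur)
  clash <- list(labeled_pair(make_vols(1)[[1]], lm, source = "pseudo_label"))
  expect_error(extend_training_set(cur, clash),
               class = "voxseg_error_id_collision")
})

test_that("pseudo-labeling wraps forward + optional CRF refinement", {
  net <- build_network(tiny_net_cfg(base = 2, seed = 61))
  vols <- lapply(1:3, function(i)
    generate_phantom(tiny_phantom_cfg(seed = 40 + i),
                     id = sprintf("u%d", i))$volume)
  plain <- pseudo_label(net, vols, use_crf = FALSE)
  expect_length(plain, 3)
  expect_true(all(vapply(plain, function(p) p$source, "") == "pseudo_label"))
  for (i in 1:3)
    expect_identical(plain[[i]]$labels$labels,
                     predict_labels(net, vols[[i]])$labels)
  # degenerate CRF (omega = 0) must equal the bypass exactly
  degen <- pseudo_label(net, vols, use_crf = TRUE,
                        crf = crf_config(omega1 = 0, omega2 = 0))
  for (i in 1:3)
    expect_identical(degen[[i]]$labels$labels, plain[[i]]$labels$labels)
})

st_cfg <- function(rounds = 2L, use_crf = FALSE, seed = 5L) {
  # max_restarts = 0: these micro-fits are expected to be degenerate, and
  # the tests compare exact runs, not segmentation quality
  selftrain_config(
    num_subsets = 2L, rounds = rounds, use_crf = use_crf,
    crf = crf_config(neighborhood_radius = 1L, iterations = 2L),
    train = train_config(learning_rate = 1e-3, epochs = 2L),
    network = tiny_net_cfg(base = 2),
    max_restarts = 0L, seed = seed)
}

tiny_split <- function(n_lab = 2, n_unl = 4, seed = 70) {
  generate_dataset(tiny_phantom_cfg(), n_lab, n_unl, 1, seed = seed)
}

test_that("a degenerate loop (no unlabeled data) is plain supervised training", {
  ds <- tiny_split(n_unl = 0)
  cfg <- st_cfg(rounds = 0L)
  res <- run_self_training(cfg, ds$split)
  ref_net <- build_network(modifyList(cfg$network, list(seed = cfg$seed)))
  ref <- train_supervised(ref_net, ds$split$labeled,
                          modifyList(cfg$initial_train,
                                     list(seed = cfg$seed)))
  expect_identical(res$net$params, ref$net$params)
  expect_equal(nrow(res$records), 1)
})

test_that("the loop pseudo-labels every unlabeled volume and never touches
           truth labels", {
  ds <- tiny_split()
  cfg <- st_cfg(rounds = 2L, use_crf = TRUE)
  res <- run_self_training(cfg, ds$split, held_out = ds$test)
  rec <- res$records
  expect_equal(nrow(rec), 3)                  # round 0 + 2 rounds
  expect_equal(sum(rec$num_pseudo_added), length(ds$split$unlabeled))
  expect_true(all(diff(rec$round_index) == 1))
  expect_false(any(is.na(rec$heldout_dice)))
  # training set: original truth pairs first, bit-identical
  expect_identical(res$training_set[seq_along(ds$split$labeled)],
                   ds$split$labeled)
  n_pseudo <- sum(vapply(res$training_set, function(p)
    p$source == "pseudo_label", TRUE))
  expect_equal(n_pseudo, length(ds$split$unlabeled))
})

test_that("self-training runs are reproducible from the master seed and
           transparent when refinement is disabled", {
  ds <- tiny_split(seed = 71)
  r1 <- run_self_training(st_cfg(seed = 9L), ds$split)
  r2 <- run_self_training(st_cfg(seed = 9L), ds$split)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$net$params, r2$net$params)
  # use_crf off vs omega-degenerate CRF on: identical runs
  off <- run_self_training(st_cfg(use_crf = FALSE, seed = 9L), ds$split)
  cfg_on <- st_cfg(use_crf = TRUE, seed = 9L)
  cfg_on$crf <- crf_config(omega1 = 0, omega2 = 0)
  on_deg <- run_self_training(cfg_on, ds$split)
  expect_identical(off$net$params, on_deg$net$params)
  expect_identical(off$records, on_deg$records)
})
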