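#' Self-training configuration
#'
#' One self-training run trains on the labeled set, then, round by round,
#' pseudo-labels one subset of the unlabeled data (optionally CRF-refined),
#' adds the pseudo pairs to the training set, and retrains — until every
#' unlabeled volume carries a pseudo-label.
#'
#' @param num_subsets number of unlabeled subsets k (default 5).
#' @param rounds rounds to run (default k; must be <= k).
#' @param retrain_mode `"continue"` (warm-start from current weights, default)
#'   or `"from_scratch"` (re-initialize before each retraining).
#' @param use_crf refine pseudo-labels with [mean_field_refine()].
#' @param crf a [crf_config()]; the default uses a truncated neighborhood
#'   (radius 3) so full-size volumes are tractable.
#' @param train a [train_config()] used for the per-round retraining.
#' @param initial_train a [train_config()] for the initial supervised
#'   training on the labeled set (step 1); defaults to `train`. Separating
#'   the two lets the initial fit run longer (or hotter) than the per-round
#'   fine-tuning, which warm-starts from an already-trained model.
#' @param network a [network_config()].
#' @param max_restarts maximum number of seeded re-initializations of the
#'   initial supervised fit if it ends degenerate — predicting one single
#'   class everywhere although the training labels hold several. Small
#'   ReLU networks without normalization layers occasionally collapse to
#'   the majority class for an unlucky initialization; a fresh seeded init
#'   is the standard remedy. 0 disables restarts.
#' @param seed master seed; network initialization, per-phase shuffling, and
#'   restart seeds are all derived from it.
#' @return a `vox_stcfg`.
#' @export
selftrain_config <- function(num_subsets = 5L, rounds = num_subsets,
                             retrain_mode = c("continue", "from_scratch"),
                             use_crf = TRUE,
                             crf = crf_config(neighborhood_radius = 3L),
                             train = train_config(),
                             initial_train = train,
                             network = network_config(),
                             max_restarts = 2L, seed = 1L) {
  retrain_mode <- match.arg(retrain_mode)
  vox_assert(num_subsets >= 1, "num_subsets must be >= 1",
             "voxseg_error_bad_config")
  vox_assert(rounds >= 0 && rounds <= num_subsets,
             "rounds must lie in 0..num_subsets", "voxseg_error_bad_config")
  structure(list(num_subsets = as.integer(num_subsets),
                 rounds = as.integer(rounds), retrain_mode = retrain_mode,
                 use_crf = isTRUE(use_crf), crf = crf, train = train,
                 initial_train = initial_train,
                 network = network, max_restarts = as.integer(max_restarts),
                 seed = as.integer(seed)),
            class = "vox_stcfg")
}

#' Randomly partition unlabeled volumes into k disjoint subsets
#'
#' Subsets are disjoint, cover the input, and differ in size by at most one
#' (the first `n %% k` subsets take the extra volume); the assignment is
#' randomized by `seed`.
#'
#' @param unlabeled list of [volume()].
#' @param k number of subsets (1 <= k <= number of volumes).
#' @param seed RNG seed.
#' @return list of k lists of volumes.
#' @export
partition_unlabeled <- function(unlabeled, k, seed = 1L) {
  n <- length(unlabeled)
  vox_assert(n >= 1, "unlabeled list is empty", "voxseg_error_empty_set")
  vox_assert(k >= 1 && k <= n, "k must lie in 1..number of volumes",
             "voxseg_error_bad_partition")
  set.seed(seed)
  ord <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) unlabeled[ord[starts[i]:ends[i]]])
}

#' Pseudo-label a subset of unlabeled volumes
#'
#' Each volume is passed through the network; the probability map is either
#' CRF-refined ([mean_field_refine()]) or reduced to its per-voxel argmax,
#' and returned as a pair flagged `source = "pseudo_label"`.
#'
#' @param net a trained `vox_net`.
#' @param subset list of [volume()].
#' @param use_crf refine with the CRF.
#' @param crf a [crf_config()].
#' @return list of [labeled_pair()] with pseudo labels.
#' @export
pseudo_label <- function(net, subset, use_crf = TRUE,
                         crf = crf_config(neighborhood_radius = 3L)) {
  lapply(subset, function(v) {
    pm <- forward(net, v)
    lm <- if (use_crf) mean_field_refine(pm, v, crf)$labels
          else argmax_labels(pm)
    labeled_pair(v, lm, source = "pseudo_label")
  })
}

#' Extend a training set with pseudo-labeled pairs
#'
#' Concatenates; true labels are never replaced by pseudo labels, and a
#' pseudo pair sharing an id with an existing pair is an error.
#'
#' @param current list of [labeled_pair()].
#' @param pseudo list of pseudo-labeled pairs.
#' @return the concatenated list (`length(current) + length(pseudo)`).
#' @export
extend_training_set <- function(current, pseudo) {
  ids_cur <- vapply(current, function(p) p$volume$id, "")
  ids_new <- vapply(pseudo, function(p) p$volume$id, "")
  clash <- intersect(ids_cur, ids_new)
  vox_assert(length(clash) == 0,
             sprintf("pseudo pair id already in training set: %s",
                     paste(clash, collapse = ", ")),
             "voxseg_error_id_collision")
  c(current, pseudo)
}

# a fitted model is degenerate when it predicts one single class on every
# training volume although the labels hold several classes
is_degenerate_fit <- function(net, pairs) {
  label_classes <- unique(unlist(lapply(pairs, function(p)
    unique(as.integer(p$labels$labels)))))
  if (length(label_classes) < 2L) return(FALSE)
  pred_classes <- unique(unlist(lapply(pairs, function(p)
    unique(as.integer(predict_labels(net, p$volume)$labels)))))
  length(pred_classes) < 2L
}

heldout_dice <- function(net, held_out) {
  if (is.null(held_out) || length(held_out) == 0) return(NA_real_)
  mean(vapply(held_out, function(pr) {
    dice(predict_labels(net, pr$volume)$labels > 0L, pr$labels$labels > 0L)
  }, numeric(1)))
}

#' Run the self-training loop
#'
#' Step 1 trains the network on the labeled pairs alone. Then, for each round
#' r = 1..rounds: the r-th unlabeled subset is pseudo-labeled (CRF-refined if
#' configured), the pseudo pairs are appended to the training set, and the
#' network is retrained (warm-started or from scratch per `retrain_mode`).
#' After `rounds = num_subsets` rounds every unlabeled volume has received a
#' pseudo-label. The run is fully reproducible from `cfg$seed`.
#'
#' @param cfg a [selftrain_config()].
#' @param data a [dataset_split()].
#' @param held_out optional list of [labeled_pair()] evaluated after every
#'   round (mean foreground Dice).
#' @return `list(net, records, training_set)`; `records` is a data.frame with
#'   one row per round (`round_index`, `num_pseudo_added`, `mean_train_loss`,
#'   `heldout_dice`), row 0 describing the initial labeled-only training.
#' @export
run_self_training <- function(cfg, data, held_out = NULL) {
  vox_assert(inherits(cfg, "vox_stcfg"), "cfg must be a selftrain_config()",
             "voxseg_error_bad_config")
  vox_assert(length(data$labeled) > 0, "labeled set is empty",
             "voxseg_error_empty_set")
  netcfg <- cfg$network; netcfg$seed <- cfg$seed
  tcfg <- cfg$train; tcfg$seed <- cfg$seed
  icfg <- cfg$initial_train; icfg$seed <- cfg$seed
  train_set <- data$labeled
  # initial supervised fit, with seeded restarts if it ends degenerate
  for (attempt in 0:cfg$max_restarts) {
    ncfg <- netcfg; ncfg$seed <- netcfg$seed + 7919L * attempt
    itr <- icfg; itr$seed <- icfg$seed + 7919L * attempt
    fit <- train_supervised(build_network(ncfg), train_set, itr)
    net <- fit$net
    if (!is_degenerate_fit(net, train_set) || attempt == cfg$max_restarts)
      break
    message(sprintf(
      "initial fit %d collapsed to a single class; restarting from a new seed",
      attempt + 1L))
  }
  records <- data.frame(round_index = 0L, num_pseudo_added = 0L,
                        mean_train_loss = mean(fit$history),
                        heldout_dice = heldout_dice(net, held_out))
  if (cfg$rounds >= 1L) {
    vox_assert(length(data$unlabeled) >= cfg$num_subsets,
               "fewer unlabeled volumes than subsets",
               "voxseg_error_bad_partition")
    subsets <- partition_unlabeled(data$unlabeled, cfg$num_subsets,
                                   seed = cfg$seed)
    for (r in seq_len(cfg$rounds)) {
      pseudo <- pseudo_label(net, subsets[[r]], cfg$use_crf, cfg$crf)
      train_set <- extend_training_set(train_set, pseudo)
      if (cfg$retrain_mode == "from_scratch") {
        ncfg <- netcfg; ncfg$seed <- netcfg$seed + r
        net <- build_network(ncfg)
      }
      tr <- tcfg; tr$seed <- tcfg$seed + r
      fit <- train_supervised(net, train_set, tr)
      net <- fit$net
      records <- rbind(records,
                       data.frame(round_index = r,
                                  num_pseudo_added = length(pseudo),
                                  mean_train_loss = mean(fit$history),
                                  heldout_dice = heldout_dice(net, held_out)))
    }
  }
  list(net = net, records = records, training_set = train_set)
}
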