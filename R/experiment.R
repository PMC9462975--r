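#' Desk-scale semi-supervised phantom experiment
#'
#' A scaled-down analogue of a low-label-fraction knee-MRI study, run
#' entirely on generated phantoms: a small labeled set, a larger unlabeled
#' pool split into subsets, self-training with CRF-refined pseudo-labels,
#' and held-out evaluation. The labeled-only baseline is the round-0 model
#' (trained on the labeled pairs alone); the semi-supervised result is the
#' model after all self-training rounds. A third arm measures CRF edge
#' refinement directly: the truth labels of one held-out phantom are
#' corrupted at the class boundaries, softened into probabilities, and
#' mean-field refined against the intensity volume.
#'
#' The training profile is two-phase — a longer, hotter initial fit
#' (`initial_epochs` at `initial_lr`) and short per-round fine-tuning
#' (`round_epochs` at `round_lr`) warm-started from the current weights —
#' with balanced (inverse-frequency) class weights in the cross-entropy,
#' which keeps the thin foreground classes from being swallowed by the
#' background during the short training budget.
#'
#' @param seed master seed for one replicate.
#' @param n_labeled,n_unlabeled,n_test split sizes.
#' @param num_subsets unlabeled subsets (= self-training rounds).
#' @param base_channels network width.
#' @param initial_epochs,initial_lr initial supervised fit.
#' @param round_epochs,round_lr per-round fine-tuning.
#' @param use_crf refine pseudo-labels with the CRF.
#' @param crf [crf_config()] for pseudo-label refinement and the
#'   corruption arm.
#' @param corrupt_rate boundary flip rate of the corruption arm.
#' @param phantom [phantom_config()] describing the study population.
#' @return a one-row data.frame: `seed`, `baseline_dice`, `selftrain_dice`
#'   (mean held-out foreground Dice of the round-0 and final models),
#'   `corrupted_dice`, `refined_dice` (foreground Dice of the corrupted and
#'   CRF-refined labels against truth), and `n_pseudo` (pseudo-labels
#'   produced).
#' @export
phantom_experiment <- function(seed,
                               n_labeled = 4L, n_unlabeled = 16L,
                               n_test = 8L, num_subsets = 4L,
                               base_channels = 8L,
                               initial_epochs = 40L, initial_lr = 3e-3,
                               round_epochs = 10L, round_lr = 1e-3,
                               use_crf = TRUE,
                               crf = crf_config(neighborhood_radius = 2L),
                               corrupt_rate = 0.5,
                               phantom = phantom_config()) {
  ds <- generate_dataset(phantom, n_labeled, n_unlabeled, n_test, seed = seed)
  stcfg <- selftrain_config(
    num_subsets = num_subsets, rounds = num_subsets, use_crf = use_crf,
    crf = crf,
    train = train_config(learning_rate = round_lr, epochs = round_epochs,
                         class_weights = "balanced"),
    initial_train = train_config(learning_rate = initial_lr,
                                 epochs = initial_epochs,
                                 class_weights = "balanced"),
    network = network_config(num_classes = phantom$num_classes,
                             base_channels = base_channels),
    seed = seed)
  res <- run_self_training(stcfg, ds$split, held_out = ds$test)
  rec <- res$records
  # CRF edge-refinement arm on one held-out phantom
  truth <- ds$test[[1]]$labels
  vol <- ds$test[[1]]$volume
  cor <- corrupt_labels(truth, corrupt_rate, seed = seed + 10000L)
  ref <- mean_field_refine(labels_to_probability(cor, confidence = 0.8),
                           vol, crf)
  # full three-index report of the final model on the held-out set
  final <- lapply(ds$test, function(pr)
    evaluate(predict_labels(res$net, pr$volume), pr$labels,
             spacing = pr$volume$spacing))
  data.frame(seed = seed,
             baseline_dice = rec$heldout_dice[1],
             selftrain_dice = rec$heldout_dice[nrow(rec)],
             selftrain_assd = mean(vapply(final, `[[`, numeric(1), "assd"),
                                   na.rm = TRUE),
             selftrain_hd95 = mean(vapply(final, `[[`, numeric(1), "hd95"),
                                   na.rm = TRUE),
             corrupted_dice = dice(cor$labels > 0, truth$labels > 0),
             refined_dice = dice(ref$labels$labels > 0, truth$labels > 0),
             n_pseudo = sum(rec$num_pseudo_added))
}
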