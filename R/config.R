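#' Default run configuration
#'
#' The documented defaults of every pipeline stage in one nested list:
#' learning rate 1e-4, 150 epochs, batch size 1, Adam; 5 unlabeled subsets;
#' 5 CRF mean-field iterations with sigma_gamma = 1; the standard phantom.
#'
#' @return a nested list of defaults (see [load_config()]).
#' @export
default_run_config <- function() {
  list(
    network = list(in_channels = 1L, num_classes = 3L, base_channels = 32L,
                   se_reduction = 2L, se_fusion = "add", seed = 1L),
    train = list(learning_rate = 1e-4, epochs = 150L, batch_size = 1L,
                 seed = 1L),
    crf = list(omega1 = 1, omega2 = 1, sigma_alpha = 3, sigma_beta = 0.1,
               sigma_gamma = 1, iterations = 5L, unary_clamp = 50,
               neighborhood_radius = 3L, dense_limit = 4096L),
    selftrain = list(num_subsets = 5L, rounds = NULL, # NULL -> num_subsets
                     retrain_mode = "continue", use_crf = TRUE,
                     max_restarts = 2L, seed = 1L),
    phantom = list(shape = c(32L, 32L, 32L), num_classes = 3L,
                   bone_radius_range = c(0.18, 0.30), shell_thickness = 2L,
                   class_means = c(0.25, 0.85, 0.55), noise_sigma = 0.08,
                   bias_field = FALSE, spacing = c(1, 1, 1), seed = 1L),
    paths = list(input = ".", output = "."),
    log_level = "info"
  )
}

check_known_keys <- function(given, template, prefix = "") {
  if (!is.list(given)) return(invisible(TRUE))
  unknown <- setdiff(names(given), names(template))
  vox_assert(length(unknown) == 0,
             sprintf("unknown config key: %s%s", prefix, unknown[1]),
             "voxseg_error_unknown_key")
  for (nm in names(given))
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])))
      check_known_keys(given[[nm]], template[[nm]],
                       prefix = paste0(prefix, nm, "."))
  invisible(TRUE)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file whose keys mirror [default_run_config()]; unspecified
#' keys take the documented defaults, unknown keys are an error (not a
#' warning), and every section is validated through its constructor before
#' any computation starts.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a `vox_runcfg`: validated `network`, `train`, `crf`, `selftrain`
#'   (with nested configs), `phantom` objects plus `paths` and `log_level`.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_run_config()
  given <- list()
  if (!is.null(path)) {
    vox_assert(file.exists(path), sprintf("file not found: '%s'", path),
               "voxseg_error_file_not_found")
    given <- tryCatch(yaml::read_yaml(path), error = function(e)
      vox_abort(sprintf("config parse failure in '%s': %s", path,
                        conditionMessage(e)),
                "voxseg_error_parse"))
    if (is.null(given)) given <- list()  # empty file
    vox_assert(is.list(given), "config must be a key-value document",
               "voxseg_error_parse")
    check_known_keys(given, defaults)
  }
  cfg <- modifyList(defaults, given, keep.null = TRUE)
  if (is.null(cfg$selftrain$rounds))
    cfg$selftrain$rounds <- cfg$selftrain$num_subsets
  network <- do.call(network_config, cfg$network)
  train <- do.call(train_config, cfg$train)
  crf <- do.call(crf_config, cfg$crf)
  phantom <- do.call(phantom_config, cfg$phantom)
  selftrain <- selftrain_config(num_subsets = cfg$selftrain$num_subsets,
                                rounds = cfg$selftrain$rounds,
                                retrain_mode = cfg$selftrain$retrain_mode,
                                use_crf = cfg$selftrain$use_crf,
                                crf = crf, train = train, network = network,
                                max_restarts = cfg$selftrain$max_restarts,
                                seed = cfg$selftrain$seed)
  structure(list(network = network, train = train, crf = crf,
                 selftrain = selftrain, phantom = phantom,
                 paths = cfg$paths, log_level = cfg$log_level),
            class = "vox_runcfg")
}
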