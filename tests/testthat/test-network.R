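test_that("the network holds exactly four attention blocks and its parameter
           count matches the analytic layer-by-layer sum", {
  for (cfg in list(network_config(base_channels = 8, num_classes = 2),
                   network_config(base_channels = 4, num_classes = 3,
                                  se_reduction = 4),
                   network_config(base_channels = 6, num_classes = 5,
                                  in_channels = 1, se_reduction = 1))) {
    net <- build_network(cfg)
    expect_equal(scse_block_count(net), 4L)
    expect_equal(count_parameters(net),
                 analytic_param_count(cfg$in_channels, cfg$num_classes,
                                      cfg$base_channels, cfg$se_reduction))
  }
})

test_that("weight initialization is bit-identical for equal seeds", {
  a <- build_network(network_config(base_channels = 4, seed = 33))
  b <- build_network(network_config(base_channels = 4, seed = 33))
  c <- build_network(network_config(base_channels = 4, seed = 34))
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
})

test_that("forward yields normalized class probabilities and is deterministic", {
  net <- build_network(tiny_net_cfg(base = 2, seed = 2))
  vol <- volume(array(runif(32^3), c(32, 32, 32)), id = "f")
  pm <- forward(net, vol)
  expect_equal(dim(pm$probs), c(3, 32, 32, 32))
  sums <- colSums(matrix(pm$probs, nrow = 3))
  expect_true(all(abs(sums - 1) <= 1e-6))
  pm2 <- forward(net, vol)
  expect_identical(pm$probs, pm2$probs)
  bad <- volume(array(0, c(30, 32, 32)), id = "b")
  err <- tryCatch(forward(net, bad), error = identity)
  expect_s3_class(err, "voxseg_error_invalid_shape")
  expect_match(conditionMessage(err), "H")
})

test_that("attention gates obey the forced-parameter algebra", {
  set.seed(9)
  fm <- array(rnorm(4 * 8 * 8 * 8), c(4, 8, 8, 8))
  pz <- scse_params(4, reduction = 2, zero = TRUE)
  expect_equal(cse_plus_gate(fm, pz), rep(0.5, 4))
  expect_true(all(sse_gate(fm, pz) == 0.5))
  # add fusion with both gates at 0.5 returns the input exactly
  expect_equal(scse_apply(fm, pz, fusion = "add"), fm)
  # max fusion with both gates at 0.5 halves the input
  expect_equal(scse_apply(fm, pz, fusion = "max"), 0.5 * fm)
  # gates always lie strictly inside (0, 1)
  pr <- scse_params(4, seed = 101)
  g <- cse_plus_gate(fm, pr)
  expect_true(all(g > 0 & g < 1))
  sg <- sse_gate(fm, pr)
  expect_true(all(sg > 0 & sg < 1))
  expect_equal(dim(sg), c(8, 8, 8))
  # spatial gate saturates under a large bias
  pb <- scse_params(4, zero = TRUE); pb$sse$b <- 20
  expect_true(all(abs(sse_gate(fm, pb) - 1) < 1e-6))
  # zero input stays zero: gating is purely multiplicative
  expect_equal(scse_apply(array(0, c(4, 2, 2, 2)), pr), array(0, c(4, 2, 2, 2)))
  # fixed gates are homogeneous: scaling the input scales the output
  expect_equal(scse_apply(3.5 * fm, pz, fusion = "add"), 3.5 * fm)
})

test_that("a spatially constant channel pools identically through both
           cSE+ branches", {
  # with identity bottlenecks (r = 1) the gate exposes the pooled values:
  # max-pool and average-pool of a constant field both equal that constant
  C <- 3
  p <- scse_params(C, reduction = 1, zero = TRUE)
  for (br in c("cse_max", "cse_avg")) {
    p[[br]]$W1 <- diag(C); p[[br]]$W2 <- diag(C)
  }
  v <- c(0.3, 1.2, 0.7)
  fm <- array(rep(v, 2 * 2 * 2), c(C, 2, 2, 2))
  expect_equal(cse_plus_gate(fm, p), 1 / (1 + exp(-2 * v)))
})

test_that("training reduces the loss, is seed-reproducible, and honors the
           zero-epoch contract", {
  cfgn <- tiny_net_cfg(base = 4, seed = 12)
  net <- build_network(cfgn)
  ph <- generate_phantom(tiny_phantom_cfg(seed = 31), id = "t1")
  pair <- labeled_pair(ph$volume, ph$labels)

  none <- train_supervised(net, list(pair), train_config(epochs = 0))
  expect_identical(none$net$params, net$params)
  expect_length(none$history, 0)

  tc <- train_config(learning_rate = 1e-3, epochs = 8, seed = 4)
  f1 <- train_supervised(net, list(pair), tc)
  f2 <- train_supervised(net, list(pair), tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$params, f2$net$params)
  expect_lt(tail(f1$history, 1), f1$history[1])

  expect_error(train_supervised(net, list(), tc),
               class = "voxseg_error_empty_training_set")
})

test_that("mini-batch accumulation and class weighting train correctly", {
  cfgn <- tiny_net_cfg(base = 2, seed = 19)
  net <- build_network(cfgn)
  phs <- lapply(1:2, function(i)
    generate_phantom(tiny_phantom_cfg(seed = 50 + i), id = paste0("b", i)))
  pairs <- lapply(phs, function(p) labeled_pair(p$volume, p$labels))
  fb <- train_supervised(net, pairs,
                         train_config(learning_rate = 1e-3, epochs = 4,
                                      batch_size = 2, seed = 2))
  expect_length(fb$history, 4)
  expect_lt(tail(fb$history, 1), fb$history[1])
  fb2 <- train_supervised(net, pairs,
                          train_config(learning_rate = 1e-3, epochs = 4,
                                       batch_size = 2, seed = 2))
  expect_identical(fb$net$params, fb2$net$params)
  # balanced weighting keeps a valid training loop and changes the fit
  fw <- train_supervised(net, pairs,
                         train_config(learning_rate = 1e-3, epochs = 4,
                                      class_weights = "balanced", seed = 2))
  expect_true(all(is.finite(fw$history)))
  expect_false(identical(fw$net$params, fb$net$params))
  expect_error(train_supervised(net, pairs,
                                train_config(class_weights = c(1, 2),
                                             epochs = 1)),
               class = "voxseg_error_bad_config")
})

test_that("a single phantom is overfit within thirty epochs", {
  cfgn <- network_config(num_classes = 3, base_channels = 8, seed = 3)
  net <- build_network(cfgn)
  ph <- generate_phantom(phantom_config(seed = 17), id = "o1")
  pair <- labeled_pair(ph$volume, ph$labels)
  fit <- train_supervised(net, list(pair),
                          train_config(learning_rate = 3e-3, epochs = 30,
                                       seed = 6))
  expect_lt(tail(fit$history, 1), fit$history[1])
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(5)
  cfg <- network_config(num_classes = 2, base_channels = 2, seed = 44)
  net <- build_network(cfg)
  sdim <- c(16L, 16L, 16L)
  x <- matrix(runif(prod(sdim)), nrow = 1)
  lab <- sample(0:1, prod(sdim), replace = TRUE)
  loss_fn <- function(nn) {
    fw <- voxseg:::net_forward(nn, x, sdim)
    -mean(log(pmax(fw$probs[cbind(lab + 1L, seq_len(ncol(fw$probs)))], 1e-12)))
  }
  fw <- voxseg:::net_forward(net, x, sdim, keep_cache = TRUE)
  N <- ncol(fw$probs)
  pick <- cbind(lab + 1L, seq_len(N))
  dlogits <- fw$probs; dlogits[pick] <- dlogits[pick] - 1
  g <- voxseg:::net_backward(net, fw$cache, dlogits / N)
  eps <- 1e-5
  probes <- list(c("enc1.conv1", "W", 1), c("enc1.conv2", "b", 2),
                 c("dec1.conv2", "W", 3), c("dec1.up", "W", 1),
                 c("out", "W", 2))
  for (pr in probes) {
    nm <- pr[1]; leaf <- pr[2]; i <- as.integer(pr[3])
    np <- net
    np$params[[nm]][[leaf]][i] <- net$params[[nm]][[leaf]][i] + eps
    lp <- loss_fn(np)
    np$params[[nm]][[leaf]][i] <- net$params[[nm]][[leaf]][i] - eps
    lm_ <- loss_fn(np)
    num <- (lp - lm_) / (2 * eps)
    ana <- g[[nm]][[leaf]][i]
    expect_lt(abs(ana - num), 1e-6 + 1e-3 * abs(num))
  }
  # one scSE leaf (nested a level deeper)
  np <- net
  np$params[["dec1.se"]]$sse$w[1] <- net$params[["dec1.se"]]$sse$w[1] + eps
  lp <- loss_fn(np)
  np$params[["dec1.se"]]$sse$w[1] <- net$params[["dec1.se"]]$sse$w[1] - eps
  lm_ <- loss_fn(np)
  num <- (lp - lm_) / (2 * eps)
  expect_lt(abs(g[["dec1.se"]]$sse$w[1] - num), 1e-6 + 1e-3 * abs(num))
})

test_that("checkpoints round-trip through disk", {
  net <- build_network(tiny_net_cfg(base = 2, seed = 8))
  f <- tempfile(fileext = ".rds")
  save_checkpoint(net, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, net$params)
  expect_identical(back$cfg, net$cfg)
  expect_error(load_checkpoint(tempfile()),
               class = "voxseg_error_file_not_found")
})
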