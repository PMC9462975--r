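# Forward/backward passes through the attention U-Net, Adam, and the
# supervised training loop. Feature maps travel as C x N matrices over the
# voxels of an H x W x S grid (n = x + H*y + H*W*z, x fastest).

relu <- function(x) pmax(x, 0)

conv_fwd <- function(pp, x, sdim) {
  cpp_conv3_fwd(x, pp$W, pp$b, sdim[1], sdim[2], sdim[3])
}

conv_bwd <- function(pp, dy, x_in, sdim) {
  res <- cpp_conv3_bwd(x_in, pp$W, dy, sdim[1], sdim[2], sdim[3])
  list(grads = list(W = res$dW, b = res$db), dx = res$dx)
}

# reference convolution via explicit im2col lowering (slow; used as the
# independent cross-check of the BLAS path)
conv_fwd_im2col <- function(pp, x, sdim) {
  col <- cpp_im2col3(x, sdim[1], sdim[2], sdim[3], 3L, 1L)
  pp$W %*% col + pp$b
}

# 1-based output columns hit by each of the 8 offsets of a stride-2
# transposed convolution from an H x W x S input grid
upconv_indices <- function(sdim) {
  H <- sdim[1]; W <- sdim[2]; S <- sdim[3]
  n0 <- 0:(H * W * S - 1L)
  x <- n0 %% H; y <- (n0 %/% H) %% W; z <- n0 %/% (H * W)
  lapply(0:7, function(o) {
    dx <- o %% 2L; dy <- (o %/% 2L) %% 2L; dz <- o %/% 4L
    (2L * x + dx) + (2L * H) * ((2L * y + dy) + (2L * W) * (2L * z + dz)) + 1L
  })
}

upconv_slice <- function(W, o) matrix(W[, , o], dim(W)[1], dim(W)[2])

upconv_fwd <- function(pp, x, idx) {
  c_out <- dim(pp$W)[1]
  y <- matrix(0, c_out, 8L * ncol(x))
  for (o in 1:8) y[, idx[[o]]] <- upconv_slice(pp$W, o) %*% x
  y + pp$b
}

upconv_bwd <- function(pp, dy, x, idx) {
  dW <- array(0, dim(pp$W))
  dx <- matrix(0, nrow(x), ncol(x))
  for (o in 1:8) {
    dyo <- dy[, idx[[o]], drop = FALSE]
    dW[, , o] <- tcrossprod(dyo, x)
    dx <- dx + crossprod(upconv_slice(pp$W, o), dyo)
  }
  list(grads = list(W = dW, b = rowSums(dy)), dx = dx)
}

softmax_cols <- function(z) {
  C <- nrow(z)
  cmax <- z[1, ]
  if (C > 1) for (i in 2:C) cmax <- pmax(cmax, z[i, ])
  e <- exp(z - rep(cmax, each = C))
  e / rep(colSums(e), each = C)
}

# min-max normalization to [0,1]; flat volumes map to all-zero
normalize_intensity <- function(v) {
  rng <- range(v)
  if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
}

check_input_shape <- function(sdim) {
  ax <- c("H", "W", "S")
  bad <- which(sdim %% 16L != 0L)
  vox_assert(length(bad) == 0L,
             sprintf("invalid input shape: axis %s (size %d) is not divisible by 16",
                     ax[bad[1]], sdim[bad[1]]),
             "voxseg_error_invalid_shape")
}

net_forward <- function(net, x, sdim, keep_cache = FALSE) {
  p <- net$params
  cache <- list(enc = vector("list", 4), dec = vector("list", 4))
  sd <- vector("list", 5)
  sd[[1]] <- sdim
  for (l in 2:5) sd[[l]] <- sd[[l - 1]] %/% 2L
  skips <- vector("list", 4)
  for (l in 1:4) {
    x_in <- x
    a1 <- relu(conv_fwd(p[[paste0("enc", l, ".conv1")]], x, sd[[l]]))
    a2 <- relu(conv_fwd(p[[paste0("enc", l, ".conv2")]], a1, sd[[l]]))
    pl <- cpp_maxpool3_fwd(a2, sd[[l]][1], sd[[l]][2], sd[[l]][3])
    skips[[l]] <- a2
    x <- pl$out
    if (keep_cache) cache$enc[[l]] <- list(x_in = x_in, a1 = a1, a2 = a2,
                                           arg = pl$arg)
  }
  b_in <- x
  b1 <- relu(conv_fwd(p[["bott.conv1"]], x, sd[[5]]))
  x <- relu(conv_fwd(p[["bott.conv2"]], b1, sd[[5]]))
  if (keep_cache) cache$bott <- list(x_in = b_in, a1 = b1, a2 = x)
  for (l in 4:1) {
    x_below <- x
    idx <- upconv_indices(sd[[l + 1]])
    up <- upconv_fwd(p[[paste0("dec", l, ".up")]], x, idx)
    concat <- rbind(up, skips[[l]])
    se <- scse_fwd(concat, p[[paste0("dec", l, ".se")]], net$cfg$se_fusion)
    a1 <- relu(conv_fwd(p[[paste0("dec", l, ".conv1")]], se$out, sd[[l]]))
    a2 <- relu(conv_fwd(p[[paste0("dec", l, ".conv2")]], a1, sd[[l]]))
    x <- a2
    if (keep_cache)
      cache$dec[[l]] <- list(x_below = x_below, idx = idx, se = se$cache,
                             se_out = se$out, a1 = a1, a2 = a2)
    else cache$dec[[l]] <- NULL
  }
  logits <- p[["out"]]$W %*% x + p[["out"]]$b
  probs <- softmax_cols(logits)
  if (keep_cache) cache$last <- x
  list(probs = probs, cache = if (keep_cache) c(cache, list(sd = sd)) else NULL)
}

net_backward <- function(net, cache, dlogits) {
  p <- net$params
  g <- list()
  sd <- cache$sd
  g[["out"]] <- list(W = tcrossprod(dlogits, cache$last),
                     b = rowSums(dlogits))
  dx <- crossprod(p[["out"]]$W, dlogits)
  dskip <- vector("list", 4)
  for (l in 1:4) {
    cc <- cache$dec[[l]]
    d2 <- dx * (cc$a2 > 0)
    cb2 <- conv_bwd(p[[paste0("dec", l, ".conv2")]], d2, cc$a1, sd[[l]])
    g[[paste0("dec", l, ".conv2")]] <- cb2$grads
    d1 <- cb2$dx * (cc$a1 > 0)
    cb1 <- conv_bwd(p[[paste0("dec", l, ".conv1")]], d1, cc$se_out, sd[[l]])
    g[[paste0("dec", l, ".conv1")]] <- cb1$grads
    sb <- scse_bwd(cb1$dx, p[[paste0("dec", l, ".se")]], cc$se)
    g[[paste0("dec", l, ".se")]] <- sb$grads
    c_up <- net$cfg$base_channels * 2L^(l - 1L)
    d_up <- sb$dx[seq_len(c_up), , drop = FALSE]
    dskip[[l]] <- sb$dx[-seq_len(c_up), , drop = FALSE]
    ub <- upconv_bwd(p[[paste0("dec", l, ".up")]], d_up, cc$x_below, cc$idx)
    g[[paste0("dec", l, ".up")]] <- ub$grads
    dx <- ub$dx
  }
  # dx is now the gradient at the bottleneck output
  db2 <- dx * (cache$bott$a2 > 0)
  cb <- conv_bwd(p[["bott.conv2"]], db2, cache$bott$a1, sd[[5]])
  g[["bott.conv2"]] <- cb$grads
  db1 <- cb$dx * (cache$bott$a1 > 0)
  cb <- conv_bwd(p[["bott.conv1"]], db1, cache$bott$x_in, sd[[5]])
  g[["bott.conv1"]] <- cb$grads
  dx <- cb$dx
  for (l in 4:1) {
    cc <- cache$enc[[l]]
    d_pool <- cpp_maxpool3_bwd(dx, cc$arg, prod(sd[[l]]))
    d_a2 <- (d_pool + dskip[[l]]) * (cc$a2 > 0)
    cb2 <- conv_bwd(p[[paste0("enc", l, ".conv2")]], d_a2, cc$a1, sd[[l]])
    g[[paste0("enc", l, ".conv2")]] <- cb2$grads
    d_a1 <- cb2$dx * (cc$a1 > 0)
    cb1 <- conv_bwd(p[[paste0("enc", l, ".conv1")]], d_a1, cc$x_in, sd[[l]])
    g[[paste0("enc", l, ".conv1")]] <- cb1$grads
    dx <- cb1$dx
  }
  g
}

# ---- Adam ------------------------------------------------------------------

tree_zeros <- function(x) rapply(x, function(a) a * 0, how = "replace")

tree_add <- function(a, b) {
  if (is.list(a)) Map(tree_add, a, b) else a + b
}

tree_scale <- function(a, s) rapply(a, function(x) x * s, how = "replace")

adam_update <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    # gradients arrive in backward (reverse) order: align by name, not position
    out <- lapply(setNames(names(p), names(p)), function(nm)
      adam_update(p[[nm]], g[[nm]], m[[nm]], v[[nm]],
                  lr = lr, t = t, b1 = b1, b2 = b2, eps = eps))
    return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                v = lapply(out, `[[`, "v")))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

# ---- public forward / training --------------------------------------------

vol_to_input <- function(net, vol) {
  vox_assert(inherits(vol, "vox_volume"), "vol must be a vox_volume",
             "voxseg_error_bad_type")
  vox_assert(net$cfg$in_channels == 1L,
             "only single-channel volumes are supported",
             "voxseg_error_bad_config")
  sdim <- dim(vol$voxels)
  check_input_shape(sdim)
  list(x = matrix(normalize_intensity(as.numeric(vol$voxels)), nrow = 1),
       sdim = sdim)
}

#' Run the network on a volume
#'
#' Intensities are min-max normalized to [0, 1] per volume, then passed
#' through the U-Net; the output is the per-voxel softmax probability stack.
#' Inference is deterministic. Each spatial dimension must be divisible by
#' 2^4 = 16 (four stride-2 poolings).
#'
#' @param net a `vox_net`.
#' @param vol a [volume()].
#' @return `forward()`: a [probmap()] of dimension `C x H x W x S`;
#'   `predict_labels()`: the argmax [labelmap()].
#' @export
forward <- function(net, vol) {
  inp <- vol_to_input(net, vol)
  out <- net_forward(net, inp$x, inp$sdim, keep_cache = FALSE)
  probmap(array(out$probs, c(net$cfg$num_classes, inp$sdim)))
}

#' @rdname forward
#' @export
predict_labels <- function(net, vol) {
  argmax_labels(forward(net, vol))
}

#' Supervised training with Adam
#'
#' Minimizes the voxel-wise categorical cross-entropy with Adam. Pairs are
#' reshuffled every epoch from the seeded RNG stream, so two runs with the
#' same seed, data, and configuration produce identical loss histories and
#' parameters.
#'
#' @param net a `vox_net` from [build_network()].
#' @param pairs list of [labeled_pair()] (true or pseudo labels).
#' @param tcfg a [train_config()].
#' @param verbose print per-epoch loss.
#' @return `list(net = trained network, history = per-epoch mean loss)`.
#' @export
train_supervised <- function(net, pairs, tcfg = train_config(), verbose = FALSE) {
  vox_assert(length(pairs) > 0, "empty training list",
             "voxseg_error_empty_training_set")
  vox_assert(all(vapply(pairs, inherits, TRUE, "vox_pair")),
             "pairs must be labeled_pair objects", "voxseg_error_bad_type")
  inputs <- lapply(pairs, function(pr) {
    inp <- vol_to_input(net, pr$volume)
    vox_assert(identical(dim(pr$volume$voxels), dim(pr$labels$labels)),
               "volume/label shape mismatch", "voxseg_error_shape_mismatch")
    vox_assert(pr$labels$num_classes <= net$cfg$num_classes,
               "more label classes than network outputs",
               "voxseg_error_bad_classes")
    lab <- as.integer(pr$labels$labels)
    # per-voxel loss weights, normalized to mean 1 over the volume
    wv <- NULL
    if (!is.null(tcfg$class_weights)) {
      w <- if (identical(tcfg$class_weights, "balanced")) {
        cnt <- tabulate(lab + 1L, nbins = net$cfg$num_classes)
        ifelse(cnt > 0, length(lab) / (sum(cnt > 0) * pmax(cnt, 1L)), 0)
      } else {
        vox_assert(length(tcfg$class_weights) == net$cfg$num_classes,
                   "class_weights length must equal num_classes",
                   "voxseg_error_bad_config")
        tcfg$class_weights
      }
      wv <- w[lab + 1L]
      wv <- wv / mean(wv)
    }
    c(inp, list(lab = lab, wv = wv))
  })
  if (tcfg$epochs == 0L)
    return(list(net = net, history = numeric(0)))
  set.seed(tcfg$seed)
  m <- tree_zeros(net$params); v <- tree_zeros(net$params); t <- 0L
  history <- numeric(tcfg$epochs)
  n <- length(inputs)
  C <- net$cfg$num_classes
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(n)
    pos <- 1L
    while (pos <= n) {
      batch <- ord[pos:min(pos + tcfg$batch_size - 1L, n)]
      gsum <- NULL
      for (k in batch) {
        inp <- inputs[[k]]
        fw <- net_forward(net, inp$x, inp$sdim, keep_cache = TRUE)
        N <- ncol(fw$probs)
        pick <- cbind(inp$lab + 1L, seq_len(N))
        nll <- -log(pmax(fw$probs[pick], 1e-12))
        dlogits <- fw$probs
        dlogits[pick] <- dlogits[pick] - 1
        if (is.null(inp$wv)) {
          losses[k] <- mean(nll)
          dlogits <- dlogits / N
        } else {
          losses[k] <- mean(inp$wv * nll)
          dlogits <- dlogits * rep(inp$wv / N, each = nrow(dlogits))
        }
        gk <- net_backward(net, fw$cache, dlogits)
        gsum <- if (is.null(gsum)) gk else tree_add(gsum, gk)
      }
      g <- tree_scale(gsum, 1 / length(batch))
      t <- t + 1L
      upd <- adam_update(net$params, g, m, v, lr = tcfg$learning_rate, t = t)
      net$params <- upd$p; m <- upd$m; v <- upd$v
      pos <- pos + tcfg$batch_size
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d/%d  loss %.5f", ep, tcfg$epochs,
                                 history[ep]))
  }
  list(net = net, history = history)
}

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the parameters and the network configuration (seed
#' included) in one file, loadable by [load_checkpoint()] and the CLI
#' `predict` command.
#'
#' @param net a `vox_net`.
#' @param path file path.
#' @export
save_checkpoint <- function(net, path) {
  vox_assert(inherits(net, "vox_net"), "net must be a vox_net",
             "voxseg_error_bad_type")
  saveRDS(list(format = "voxseg_checkpoint", cfg = net$cfg,
               params = net$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  vox_assert(file.exists(path), sprintf("file not found: '%s'", path),
             "voxseg_error_file_not_found")
  ck <- readRDS(path)
  vox_assert(identical(ck$format, "voxseg_checkpoint"),
             "not a voxseg checkpoint", "voxseg_error_bad_checkpoint")
  structure(list(cfg = ck$cfg, params = ck$params), class = "vox_net")
}
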