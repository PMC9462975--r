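#' Network and training configuration
#'
#' The segmentation network is a 3D U-Net with four encoder (down-sampling)
#' levels, a bottleneck, and four decoder (up-sampling) levels. Each decoder
#' level concatenates the up-sampled features with the same-resolution encoder
#' skip features and passes the concatenation through one scSE-block+ attention
#' module before its two 3x3x3 convolutions, so the network holds exactly four
#' scSE-block+ modules. Channel counts start at `base_channels` and double at
#' every down-sampling.
#'
#' @param in_channels input channels (grayscale MRI: 1).
#' @param num_classes number of segmentation classes (>= 2).
#' @param base_channels channels at the first level; doubles per level.
#' @param se_reduction bottleneck reduction `r` of the channel-gate MLPs
#'   (`C -> C/r -> C`); clamped so the hidden width is at least 1.
#' @param se_fusion how the channel-gated and spatially-gated maps are fused:
#'   elementwise `"add"` (default) or elementwise `"max"`.
#' @param seed RNG seed for weight initialization.
#' @return a `vox_netcfg`.
#' @export
network_config <- function(in_channels = 1L, num_classes = 2L,
                           base_channels = 32L, se_reduction = 2L,
                           se_fusion = c("add", "max"), seed = 1L) {
  se_fusion <- match.arg(se_fusion)
  vox_assert(num_classes >= 2, "num_classes must be >= 2",
             "voxseg_error_bad_config")
  vox_assert(base_channels >= 1 && se_reduction >= 1 && in_channels >= 1,
             "channel counts and reduction must be >= 1",
             "voxseg_error_bad_config")
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 base_channels = as.integer(base_channels),
                 depth = 4L,  # four down- and four up-sampling levels
                 se_reduction = as.integer(se_reduction),
                 se_fusion = se_fusion, seed = as.integer(seed)),
            class = "vox_netcfg")
}

#' @rdname network_config
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs training epochs (default 150).
#' @param batch_size volumes per gradient step (default 1).
#' @param class_weights per-class weights of the cross-entropy loss: `NULL`
#'   (unweighted, default), `"balanced"` (inverse class frequency, computed
#'   per volume and normalized to mean 1), or a numeric vector of length
#'   `num_classes`. Weighting counters the foreground/background imbalance
#'   of volumetric segmentation, where the background can swallow the entire
#'   early optimization.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 150L, batch_size = 1L,
                         class_weights = NULL, seed = 1L) {
  vox_assert(learning_rate > 0, "learning_rate must be > 0",
             "voxseg_error_bad_config")
  vox_assert(epochs >= 0, "epochs must be >= 0", "voxseg_error_bad_config")
  vox_assert(batch_size >= 1, "batch_size must be >= 1",
             "voxseg_error_bad_config")
  vox_assert(is.null(class_weights) ||
               identical(class_weights, "balanced") ||
               (is.numeric(class_weights) && all(class_weights > 0)),
             "class_weights must be NULL, \"balanced\", or positive numbers",
             "voxseg_error_bad_config")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), optimizer = "Adam",
                 loss = "cross_entropy", class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "vox_traincfg")
}

# ---- parameter construction ------------------------------------------------

he_mat <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

conv_params <- function(c_in, c_out) {
  list(W = he_mat(c_out, 27 * c_in, 27 * c_in), b = numeric(c_out))
}

upconv_params <- function(c_in, c_out) {
  list(W = array(rnorm(c_out * c_in * 8, sd = sqrt(2 / c_in)),
                 c(c_out, c_in, 8)),
       b = numeric(c_out))
}

se_hidden <- function(C, r) max(1L, C %/% r)

#' Parameters of one scSE-block+ module
#'
#' The channel branch (cSE+) pools each channel over space through a global
#' max-pool and a global average-pool in parallel; each pooled vector passes
#' its own 1x1x1 channel-mixing bottleneck (`C -> C/r`, ReLU, `-> C`, ReLU),
#' the two branch outputs are added and squashed by a sigmoid into the
#' per-channel gate. The spatial branch (sSE) maps the C channels to one
#' number per voxel by a 1x1x1 convolution and a sigmoid.
#'
#' @param channels number of channels C of the feature map the block gates.
#' @param reduction bottleneck reduction r.
#' @param zero if `TRUE`, all weights and biases are zero (both gates then
#'   equal 0.5 everywhere — useful for algebraic checks).
#' @param seed optional RNG seed for the random initialization.
#' @return a named list of block parameters.
#' @export
scse_params <- function(channels, reduction = 2L, zero = FALSE, seed = NULL) {
  C <- as.integer(channels); Cr <- se_hidden(C, as.integer(reduction))
  if (zero) {
    branch <- function() list(W1 = matrix(0, Cr, C), b1 = numeric(Cr),
                              W2 = matrix(0, C, Cr), b2 = numeric(C))
    return(list(cse_max = branch(), cse_avg = branch(),
                sse = list(w = matrix(0, 1, C), b = 0)))
  }
  if (!is.null(seed)) set.seed(seed)
  branch <- function() list(W1 = he_mat(Cr, C, C), b1 = numeric(Cr),
                            W2 = he_mat(C, Cr, Cr), b2 = numeric(C))
  list(cse_max = branch(), cse_avg = branch(),
       sse = list(w = he_mat(1, C, C), b = 0))
}

#' Build the attention 3D U-Net
#'
#' Encoder level l (l = 1..4): two 3x3x3 convolutions + ReLU, then 2x2x2 max
#' pooling with stride 2. Bottleneck: two convolutions + ReLU. Decoder level l:
#' stride-2 transposed convolution, concatenation with the encoder skip
#' features, one scSE-block+ on the concatenation, then two convolutions +
#' ReLU. A final 1x1x1 convolution maps to `num_classes` channels followed by
#' a per-voxel softmax. Initialization is fully determined by `cfg$seed`.
#'
#' @param cfg a [network_config()].
#' @return a `vox_net` (parameters + config).
#' @export
build_network <- function(cfg) {
  vox_assert(inherits(cfg, "vox_netcfg"), "cfg must be a network_config()",
             "voxseg_error_bad_config")
  set.seed(cfg$seed)
  F <- cfg$base_channels
  ch <- F * 2^(0:4)  # level channels: F, 2F, 4F, 8F; bottleneck 16F
  p <- list()
  c_in <- cfg$in_channels
  for (l in 1:4) {
    p[[paste0("enc", l, ".conv1")]] <- conv_params(c_in, ch[l])
    p[[paste0("enc", l, ".conv2")]] <- conv_params(ch[l], ch[l])
    c_in <- ch[l]
  }
  p[["bott.conv1"]] <- conv_params(ch[4], ch[5])
  p[["bott.conv2"]] <- conv_params(ch[5], ch[5])
  for (l in 4:1) {
    below <- ch[l + 1]           # channels arriving from the level below
    p[[paste0("dec", l, ".up")]] <- upconv_params(below, ch[l])
    ccat <- 2L * ch[l]           # upsampled + skip concatenation
    p[[paste0("dec", l, ".se")]] <-
      local({
        C <- ccat; Cr <- se_hidden(C, cfg$se_reduction)
        branch <- function() list(W1 = he_mat(Cr, C, C), b1 = numeric(Cr),
                                  W2 = he_mat(C, Cr, Cr), b2 = numeric(C))
        list(cse_max = branch(), cse_avg = branch(),
             sse = list(w = he_mat(1, C, C), b = 0))
      })
    p[[paste0("dec", l, ".conv1")]] <- conv_params(ccat, ch[l])
    p[[paste0("dec", l, ".conv2")]] <- conv_params(ch[l], ch[l])
  }
  p[["out"]] <- list(W = he_mat(cfg$num_classes, ch[1], ch[1]),
                     b = numeric(cfg$num_classes))
  structure(list(cfg = cfg, params = p), class = "vox_net")
}

#' @export
print.vox_net <- function(x, ...) {
  cat(sprintf(paste0("<vox_net> 3D U-Net + scSE-block+ | base %d, %d classes,",
                     " %d scSE blocks, %s parameters\n"),
              x$cfg$base_channels, x$cfg$num_classes, scse_block_count(x),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Network introspection
#'
#' `count_parameters()` sums the sizes of every weight and bias array;
#' `scse_block_count()` counts the scSE-block+ attention modules.
#'
#' @param net a `vox_net` from [build_network()].
#' @return an integer.
#' @export
count_parameters <- function(net) {
  length(unlist(net$params, use.names = FALSE))
}

#' @rdname count_parameters
#' @export
scse_block_count <- function(net) {
  sum(grepl("^dec[0-9]+\\.se$", names(net$params)))
}

# ---- public attention-block operations -------------------------------------

#' Feature map container
#'
#' @param activations numeric 4D array `C x H x W x S` of finite activations.
#' @param level encoder/decoder depth index (bookkeeping only).
#' @return a `vox_feature`.
#' @export
feature_map <- function(activations, level = 1L) {
  vox_assert(is.array(activations) && length(dim(activations)) == 4L,
             "activations must be a 4D array (C x H x W x S)",
             "voxseg_error_not_4d")
  vox_assert(all(is.finite(activations)), "activations must be finite",
             "voxseg_error_nonfinite")
  structure(list(activations = activations, level = as.integer(level)),
            class = "vox_feature")
}

fm_to_mat <- function(fm) {
  a <- if (inherits(fm, "vox_feature")) fm$activations else fm
  d <- dim(a)
  list(mat = matrix(a, nrow = d[1]), sdim = d[2:4])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

cse_branch_fwd <- function(z, br) {
  h_pre <- as.vector(br$W1 %*% z) + br$b1
  h <- pmax(h_pre, 0)
  o_pre <- as.vector(br$W2 %*% h) + br$b2
  list(h_pre = h_pre, h = h, o_pre = o_pre, o = pmax(o_pre, 0))
}

#' Channel and spatial attention gates of the scSE-block+
#'
#' `cse_plus_gate()` computes the per-channel gate: global max-pool and global
#' average-pool over space in parallel, one bottleneck MLP per branch, the two
#' branch outputs added and passed through a sigmoid. `sse_gate()` computes
#' the per-voxel gate: a 1x1x1 convolution from C channels to 1, then a
#' sigmoid. `scse_apply()` multiplies the feature map by both gates and fuses
#' the two gated maps by elementwise addition (default) or maximum.
#'
#' @param fm a [feature_map()] or a plain `C x H x W x S` array.
#' @param params block parameters from [scse_params()].
#' @return `cse_plus_gate()`: a length-C vector in (0,1); `sse_gate()`: an
#'   `H x W x S` array in (0,1); `scse_apply()`: a gated array of the input's
#'   shape.
#' @examples
#' fm <- array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4))
#' p <- scse_params(2, zero = TRUE)
#' cse_plus_gate(fm, p)          # 0.5 0.5
#' range(sse_gate(fm, p))        # 0.5 0.5
#' all.equal(scse_apply(fm, p), fm)  # add-fusion identity at zero parameters
#' @export
cse_plus_gate <- function(fm, params) {
  m <- fm_to_mat(fm)
  z_max <- cpp_row_max(m$mat)$max
  z_avg <- rowMeans(m$mat)
  bmax <- cse_branch_fwd(z_max, params$cse_max)
  bavg <- cse_branch_fwd(z_avg, params$cse_avg)
  sigmoid(bmax$o + bavg$o)
}

#' @rdname cse_plus_gate
#' @export
sse_gate <- function(fm, params) {
  m <- fm_to_mat(fm)
  g <- sigmoid(as.vector(params$sse$w %*% m$mat) + params$sse$b)
  array(g, m$sdim)
}

#' @rdname cse_plus_gate
#' @param fusion `"add"` or `"max"`.
#' @export
scse_apply <- function(fm, params, fusion = c("add", "max")) {
  fusion <- match.arg(fusion)
  m <- fm_to_mat(fm)
  out <- scse_fwd(m$mat, params, fusion)$out
  res <- array(out, c(nrow(m$mat), m$sdim))
  if (inherits(fm, "vox_feature")) feature_map(res, fm$level) else res
}

# matrix-form forward used both publicly and inside the network
scse_fwd <- function(x, params, fusion) {
  rm <- cpp_row_max(x)
  z_max <- rm$max; z_avg <- rowMeans(x)
  bmax <- cse_branch_fwd(z_max, params$cse_max)
  bavg <- cse_branch_fwd(z_avg, params$cse_avg)
  cgate <- sigmoid(bmax$o + bavg$o)                  # length C
  g_pre <- as.vector(params$sse$w %*% x) + params$sse$b
  g <- sigmoid(g_pre)                                # length N
  cse_out <- x * cgate                               # recycles down columns
  sse_out <- x * rep(g, each = nrow(x))
  out <- if (fusion == "add") cse_out + sse_out else pmax(cse_out, sse_out)
  list(out = out,
       cache = list(x = x, which_max = rm$which, z_max = z_max, z_avg = z_avg,
                    bmax = bmax, bavg = bavg, cgate = cgate, g = g,
                    cse_out = cse_out, sse_out = sse_out, fusion = fusion))
}

cse_branch_bwd <- function(do, z, br, cache) {
  do_pre <- do * (cache$o_pre > 0)
  dW2 <- tcrossprod(do_pre, cache$h)
  dh <- as.vector(crossprod(br$W2, do_pre))
  dh_pre <- dh * (cache$h_pre > 0)
  dW1 <- tcrossprod(dh_pre, z)
  dz <- as.vector(crossprod(br$W1, dh_pre))
  list(grads = list(W1 = dW1, b1 = dh_pre, W2 = dW2, b2 = do_pre), dz = dz)
}

scse_bwd <- function(dout, params, cache) {
  x <- cache$x; C <- nrow(x); N <- ncol(x)
  if (cache$fusion == "add") {
    dcse <- dout; dsse <- dout
  } else {
    mask <- cache$cse_out >= cache$sse_out
    dcse <- dout * mask; dsse <- dout * !mask
  }
  dx <- dcse * cache$cgate + dsse * rep(cache$g, each = C)
  dcgate <- rowSums(dcse * x)
  dgvec <- colSums(dsse * x)
  # sigmoid of the summed branch outputs
  ds <- dcgate * cache$cgate * (1 - cache$cgate)
  bm <- cse_branch_bwd(ds, cache$z_max, params$cse_max, cache$bmax)
  ba <- cse_branch_bwd(ds, cache$z_avg, params$cse_avg, cache$bavg)
  # route pooled gradients back into the map: max -> argmax voxel, avg -> all
  idx <- cbind(seq_len(C), cache$which_max)
  dx[idx] <- dx[idx] + bm$dz
  dx <- dx + ba$dz / N
  # spatial gate
  dg_pre <- dgvec * cache$g * (1 - cache$g)
  dw <- matrix(as.vector(x %*% dg_pre), 1, C)
  dx <- dx + tcrossprod(as.vector(params$sse$w), dg_pre)
  list(dx = dx,
       grads = list(cse_max = bm$grads, cse_avg = ba$grads,
                    sse = list(w = dw, b = sum(dg_pre))))
}
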