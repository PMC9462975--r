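# Programmatic fixtures shared across test files.

# random non-empty binary mask: a random ball plus salt voxels
random_mask <- function(dim = c(12, 12, 12), seed = 1) {
  set.seed(seed)
  center <- runif(3, 3, dim - 3)
  radius <- runif(1, 1.5, min(dim) / 3)
  x <- (seq_len(dim[1]) - 1 - center[1])^2
  y <- (seq_len(dim[2]) - 1 - center[2])^2
  z <- (seq_len(dim[3]) - 1 - center[3])^2
  m <- outer(outer(x, y, "+"), z, "+") <= radius^2
  salt <- array(runif(prod(dim)) < 0.02, dim)
  out <- m | salt
  if (!any(out)) out[ceiling(dim[1] / 2), ceiling(dim[2] / 2),
                     ceiling(dim[3] / 2)] <- TRUE
  out
}

# all-pairs brute-force surface metrics used as the independent oracle:
# full distance matrix in R, sorted percentiles, no shared distance code
oracle_surface_metrics <- function(G, S, spacing = c(1, 1, 1)) {
  pts <- function(m) {
    p <- which(m, arr.ind = TRUE) - 1
    border <- function(q) {
      d <- dim(m)
      any6 <- vapply(seq_len(nrow(q)), function(i) {
        v <- q[i, ]
        for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
          w <- v + sh
          if (any(w < 0) || any(w >= d)) return(TRUE)
          if (!m[w[1] + 1, w[2] + 1, w[3] + 1]) return(TRUE)
        }
        FALSE
      }, logical(1))
      q[any6, , drop = FALSE]
    }
    border(p)
  }
  A <- pts(G); B <- pts(S)
  As <- sweep(A, 2, spacing, "*"); Bs <- sweep(B, 2, spacing, "*")
  D <- sqrt(outer(As[, 1], Bs[, 1], "-")^2 + outer(As[, 2], Bs[, 2], "-")^2 +
              outer(As[, 3], Bs[, 3], "-")^2)
  dgs <- apply(D, 1, min); dsg <- apply(D, 2, min)
  list(assd = (sum(dgs) + sum(dsg)) / (length(dgs) + length(dsg)),
       hd = max(max(dgs), max(dsg)),
       hd95 = max(unname(quantile(dgs, 0.95, type = 7)),
                  unname(quantile(dsg, 0.95, type = 7))))
}

tiny_phantom_cfg <- function(seed = 1) {
  phantom_config(shape = c(16, 16, 16), bone_radius_range = c(0.14, 0.22),
                 noise_sigma = 0.05, seed = seed)
}

tiny_net_cfg <- function(base = 4L, seed = 1L) {
  network_config(num_classes = 3L, base_channels = base, seed = seed)
}

# analytic parameter counter, written independently of build_network:
# a closed-form sum over the architecture's layer inventory
analytic_param_count <- function(in_channels, num_classes, base, reduction) {
  conv <- function(ci, co) co * (27 * ci) + co
  up <- function(ci, co) co * ci * 8 + co
  se <- function(C) {
    Cr <- max(1, C %/% reduction)
    2 * ((Cr * C + Cr) + (C * Cr + C)) + (C + 1)
  }
  ch <- base * 2^(0:4)
  total <- 0
  ci <- in_channels
  for (l in 1:4) {
    total <- total + conv(ci, ch[l]) + conv(ch[l], ch[l])
    ci <- ch[l]
  }
  total <- total + conv(ch[4], ch[5]) + conv(ch[5], ch[5])
  for (l in 4:1) {
    total <- total + up(ch[l + 1], ch[l]) + se(2 * ch[l]) +
      conv(2 * ch[l], ch[l]) + conv(ch[l], ch[l])
  }
  total + num_classes * ch[1] + num_classes
}
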