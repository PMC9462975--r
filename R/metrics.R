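# Segmentation evaluation: boundary extraction, Dice overlap, average
# symmetric surface distance (ASSD), and (95th-percentile) Hausdorff distance.
# Distances are Euclidean between voxel centers, scaled per-axis by spacing.

as_mask <- function(x) {
  m <- if (inherits(x, "vox_labelmap")) x$labels != 0L else x != 0
  vox_assert(is.array(m) && length(dim(m)) == 3L, "mask must be a 3D grid",
             "voxseg_error_not_3d")
  m
}

shift_mask <- function(m, dx, dy, dz, fill = FALSE) {
  d <- dim(m)
  out <- array(fill, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  fx <- sx - dx; fy <- sy - dy; fz <- sz - dz
  okx <- fx >= 1 & fx <= d[1]; oky <- fy >= 1 & fy <= d[2]
  okz <- fz >= 1 & fz <= d[3]
  out[sx[okx], sy[oky], sz[okz]] <- m[fx[okx], fy[oky], fz[okz]]
  out
}

#' Extract the voxel surface of a binary mask
#'
#' The surface is every foreground voxel with at least one background (or
#' out-of-grid) voxel among its six face neighbors; the grid border counts
#' as background.
#'
#' @param mask binary 3D array (or a [labelmap()], foreground = label > 0).
#' @param spacing mm per axis carried along for distance computations.
#' @return a `vox_surface`: 0-based voxel coordinates (n x 3) plus spacing.
#' @export
extract_surface <- function(mask, spacing = c(1, 1, 1)) {
  m <- as_mask(mask)
  vox_assert(any(m), "empty segmentation: mask has no foreground voxels",
             "voxseg_error_empty_mask")
  interior <- m
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    interior <- interior & shift_mask(m, sh[1], sh[2], sh[3], fill = FALSE)
  surf <- m & !interior
  pts <- which(surf, arr.ind = TRUE) - 1L
  dimnames(pts) <- NULL
  structure(list(points = pts, spacing = as.numeric(spacing)),
            class = "vox_surface")
}

#' Dice overlap coefficient
#'
#' `2 |G intersect S| / (|G| + |S|)`, in [0, 1]; symmetric in its arguments.
#'
#' @param G,S binary 3D grids (or [labelmap()]s, foreground = label > 0) of
#'   equal shape; at least one must be non-empty.
#' @return the Dice coefficient.
#' @export
dice <- function(G, S) {
  g <- as_mask(G); s <- as_mask(S)
  vox_assert(identical(dim(g), dim(s)), "mask shapes must agree",
             "voxseg_error_shape_mismatch")
  vox_assert(any(g) || any(s), "both masks are empty",
             "voxseg_error_empty_mask")
  2 * sum(g & s) / (sum(g) + sum(s))
}

directed_surface_dists <- function(g, s, spacing) {
  A <- extract_surface(g, spacing)$points
  B <- extract_surface(s, spacing)$points
  list(gs = cpp_min_dists(A * 1.0, B * 1.0, as.numeric(spacing)),
       sg = cpp_min_dists(B * 1.0, A * 1.0, as.numeric(spacing)))
}

#' Surface distance metrics
#'
#' `assd()` pools the nearest-boundary distances over both surfaces:
#' `(sum_{g in dG} min_s |s-g| + sum_{s in dS} min_g |g-s|) / (|dG| + |dS|)`.
#' `hd()` is the classic Hausdorff distance `max(h(G,S), h(S,G))` with
#' `h(G,S) = max_g min_s |g-s|`; `hd95()` replaces each directed maximum by
#' the 95th percentile of its directed distance set (linear interpolation
#' between order statistics), robust to outlier surface points. With
#' `method = "pooled"` the percentile is taken over the union of both
#' directed sets instead.
#'
#' @inheritParams dice
#' @param spacing mm per axis (default unit: distances in voxels).
#' @param percentile percentile for [hd95()] (default 95).
#' @param method `"directed"` (percentile per directed set, then max) or
#'   `"pooled"` (percentile of the pooled set).
#' @return a non-negative distance.
#' @export
assd <- function(G, S, spacing = c(1, 1, 1)) {
  d <- directed_surface_dists(as_mask(G), as_mask(S), spacing)
  (sum(d$gs) + sum(d$sg)) / (length(d$gs) + length(d$sg))
}

#' @rdname assd
#' @export
hd <- function(G, S, spacing = c(1, 1, 1)) {
  d <- directed_surface_dists(as_mask(G), as_mask(S), spacing)
  max(max(d$gs), max(d$sg))
}

#' @rdname assd
#' @export
hd95 <- function(G, S, spacing = c(1, 1, 1), percentile = 95,
                 method = c("directed", "pooled")) {
  method <- match.arg(method)
  d <- directed_surface_dists(as_mask(G), as_mask(S), spacing)
  p <- percentile / 100
  if (method == "pooled")
    return(unname(stats::quantile(c(d$gs, d$sg), p, type = 7)))
  max(unname(stats::quantile(d$gs, p, type = 7)),
      unname(stats::quantile(d$sg, p, type = 7)))
}

#' Evaluate a predicted label map against a reference
#'
#' Computes one-vs-rest Dice, ASSD, and HD95 for every class and a
#' foreground-pooled summary (all non-background classes merged into one
#' binary mask). Classes absent from both maps are reported with status
#' `"absent"`; a class present in the reference but missing from the
#' prediction gets status `"empty_prediction"` (and `NA` metrics) rather
#' than a fake zero, and symmetrically `"empty_reference"`.
#'
#' @param pred,ref [labelmap()]s of equal shape and class count.
#' @param spacing mm per axis.
#' @return a `vox_metrics`: fields `dice`, `assd`, `hd95` (foreground-pooled,
#'   `NA` when undefined), `per_class` (data.frame with one row per
#'   non-background class), and `spacing`.
#' @export
evaluate <- function(pred, ref, spacing = c(1, 1, 1)) {
  vox_assert(inherits(pred, "vox_labelmap") && inherits(ref, "vox_labelmap"),
             "pred and ref must be labelmaps", "voxseg_error_bad_type")
  vox_assert(identical(dim(pred$labels), dim(ref$labels)),
             "label map shapes must agree", "voxseg_error_shape_mismatch")
  vox_assert(pred$num_classes == ref$num_classes,
             "class counts must agree", "voxseg_error_bad_classes")
  C <- ref$num_classes
  rows <- lapply(seq_len(C - 1L), function(cl) {
    g <- ref$labels == cl; s <- pred$labels == cl
    if (!any(g) && !any(s))
      return(data.frame(class = cl, dice = NA_real_, assd = NA_real_,
                        hd95 = NA_real_, status = "absent"))
    if (!any(s))
      return(data.frame(class = cl, dice = dice(g, s), assd = NA_real_,
                        hd95 = NA_real_, status = "empty_prediction"))
    if (!any(g))
      return(data.frame(class = cl, dice = dice(g, s), assd = NA_real_,
                        hd95 = NA_real_, status = "empty_reference"))
    data.frame(class = cl, dice = dice(g, s),
               assd = assd(g, s, spacing), hd95 = hd95(g, s, spacing),
               status = "ok")
  })
  per_class <- do.call(rbind, rows)
  gf <- ref$labels > 0L; sf <- pred$labels > 0L
  if (any(gf) && any(sf)) {
    pooled <- c(dice = dice(gf, sf), assd = assd(gf, sf, spacing),
                hd95 = hd95(gf, sf, spacing))
  } else if (any(gf) || any(sf)) {
    pooled <- c(dice = dice(gf, sf), assd = NA_real_, hd95 = NA_real_)
  } else {
    pooled <- c(dice = NA_real_, assd = NA_real_, hd95 = NA_real_)
  }
  structure(list(dice = unname(pooled["dice"]), assd = unname(pooled["assd"]),
                 hd95 = unname(pooled["hd95"]), per_class = per_class,
                 spacing = as.numeric(spacing)),
            class = "vox_metrics")
}

#' @export
print.vox_metrics <- function(x, ...) {
  unit <- if (all(x$spacing == 1)) "voxels" else "mm"
  cat(sprintf("<vox_metrics> foreground: dice %.4f | assd %.4f %s | hd95 %.4f %s\n",
              x$dice, x$assd, unit, x$hd95, unit))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

# binary dilation by a Euclidean ball of the given voxel radius
dilate_ball <- function(mask, radius) {
  m <- as_mask(mask)
  r <- ceiling(radius)
  out <- m
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dx * dx + dy * dy + dz * dz > radius^2) next
    out <- out | shift_mask(m, dx, dy, dz, fill = FALSE)
  }
  out
}
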