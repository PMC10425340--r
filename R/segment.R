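#' Segmentation parameters
#'
#' Operator settings of the 3D paranode segmentation: additional Gaussian
#' smoothing, threshold choice, volume and elongation filters, neighborhood
#' connectivity, and optional watershed splitting of touching capsules.
#'
#' The volume filters and the elongation cut are expressed in physical units
#' and were tuned on the simulator (they are operator settings, not measured
#' quantities). The elongation cut rejects roughly isotropic blobs; it is kept
#' mild (1.3) because paranode lengths spread well below the mean and a hard
#' cut would censor genuinely short paranodes group-differentially.
#'
#' @param smooth_sigma_um additional Gaussian smoothing sigma, (x, y, z) um.
#' @param threshold_method `"otsu"` (per-field Otsu) or `"quantile"`.
#' @param threshold_quantile intensity quantile used when
#'   `threshold_method = "quantile"`.
#' @param min_volume_um3,max_volume_um3 connected-component volume filter.
#' @param min_elongation minimum ratio of first to second principal extent.
#'   The default 1.0 disables the cut: in per-node cropped fields the volume
#'   filter already removes noise specks, and because a short paranode is
#'   nearly indistinguishable in shape from a round blob, any elongation cut
#'   censors the short tail of the length distribution — group-differentially
#'   whenever group lengths differ, biasing downstream comparisons. Raise it
#'   (e.g. to 1.3) for acquisitions contaminated by round debris, accepting
#'   that trade-off. When `blur_sigma_um` is supplied the lateral extents are
#'   deblurred (blur full-width subtracted in quadrature) before the ratio,
#'   so the cut acts on the structure rather than the PSF-fattened mask.
#' @param blur_sigma_um optional total blur sigma, (x, y, z) um (PSF plus
#'   `smooth_sigma_um`), used to deblur extents for the elongation filter.
#' @param connectivity voxel connectivity: 6, 18 or 26.
#' @param split_touching if `TRUE`, components longer than
#'   `split_min_extent_um` are split in two at the saddle of the anisotropic
#'   distance transform (seeded watershed).
#' @param split_min_extent_um principal-extent threshold for splitting (um).
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(smooth_sigma_um = c(0.06, 0.06, 0.12),
                                threshold_method = c("otsu", "quantile"),
                                threshold_quantile = 0.995,
                                min_volume_um3 = 0.15,
                                max_volume_um3 = 10,
                                min_elongation = 1.0,
                                blur_sigma_um = NULL,
                                connectivity = 26,
                                split_touching = FALSE,
                                split_min_extent_um = 3.0) {
  p <- list(smooth_sigma_um = vec3(smooth_sigma_um, "smooth_sigma_um"),
            threshold_method = match.arg(threshold_method),
            threshold_quantile = as.numeric(threshold_quantile),
            min_volume_um3 = as.numeric(min_volume_um3),
            max_volume_um3 = as.numeric(max_volume_um3),
            min_elongation = as.numeric(min_elongation),
            blur_sigma_um = if (!is.null(blur_sigma_um))
              vec3(blur_sigma_um, "blur_sigma_um"),
            connectivity = as.integer(connectivity),
            split_touching = isTRUE(split_touching),
            split_min_extent_um = as.numeric(split_min_extent_um))
  if (any(p$smooth_sigma_um < 0)) stop("smooth_sigma_um must be >= 0")
  if (p$min_volume_um3 >= p$max_volume_um3)
    stop("min_volume_um3 must be smaller than max_volume_um3")
  if (p$min_elongation < 1) stop("min_elongation must be >= 1")
  if (!p$connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  class(p) <- "segmentation_params"
  p
}

#' Smooth a channel and subtract its background
#'
#' Gaussian smoothing with per-axis sigma converted from micrometres to voxel
#' units, followed by subtraction of the field's lower-quartile intensity
#' (clipped at zero) as the background estimate.
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @param params a [segmentation_params()].
#' @return the preprocessed 3D intensity array (z, y, x).
#' @export
preprocess <- function(stack, channel, params = segmentation_params()) {
  stopifnot(inherits(stack, "image_stack"))
  if (!channel %in% names(stack$channels))
    stop("key error: no channel named '", channel, "'")
  v <- stack$voxel_size_um
  sig_zyx <- c(params$smooth_sigma_um[3] / v[3],
               params$smooth_sigma_um[2] / v[2],
               params$smooth_sigma_um[1] / v[1])
  arr <- .blur3d(stack$channels[[channel]], sig_zyx)
  bg <- quantile(arr, 0.25, names = FALSE)
  pmax(arr - bg, 0)
}

otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) <= 0) return(Inf)          # flat field: nothing segmentable
  EBImage::otsu(matrix(x, ncol = 1), range = rng, levels = 256L)
}

component_stats <- function(idx_lin, dims_zyx, stack) {
  ind <- arrayInd(idx_lin, dims_zyx)             # (i, j, k) = (z, y, x)
  v <- stack$voxel_size_um
  coords <- cbind(x = stack$origin_um[1] + (ind[, 3] - 1) * v[1],
                  y = stack$origin_um[2] + (ind[, 2] - 1) * v[2],
                  z = stack$origin_um[3] + (ind[, 1] - 1) * v[3])
  centroid <- colMeans(coords)
  cc <- sweep(coords, 2, centroid)
  sv <- svd(cc, nu = 0, nv = 3)
  ax <- sv$v
  # deterministic sign: largest-magnitude entry positive
  for (a in 1:3) if (ax[which.max(abs(ax[, a])), a] < 0) ax[, a] <- -ax[, a]
  proj <- cc %*% ax
  extents <- apply(proj, 2, function(p) diff(range(p)))
  ord <- order(extents, decreasing = TRUE)
  list(voxel_idx = ind,
       coords_um = coords,
       centroid_um = centroid,
       axis = ax[, ord[1]],
       axes = ax[, ord, drop = FALSE],
       extents_um = extents[ord],
       n_voxels = length(idx_lin),
       volume_um3 = length(idx_lin) * prod(v))
}

#' Segment paranodes in 3D
#'
#' Per-field segmentation of the paranode (CASPR) channel: preprocessing,
#' per-field Otsu (or quantile) threshold, connected components at the chosen
#' connectivity, volume and elongation filters, and optional distance-
#' transform watershed splitting of over-long components. Component geometry
#' (centroid, principal axis, principal extents, volume) is computed on the
#' physical-coordinate point cloud, so voxel anisotropy never enters lengths.
#'
#' @param stack an [image_stack()] containing the paranode channel.
#' @param params a [segmentation_params()].
#' @param channel paranode channel name.
#' @return a list with `mask` (integer label array, 0 = background, labels
#'   dense from 1), `components` (list of `paranode_component`), `grid` (the
#'   preprocessed intensity array used downstream), and `qc` (threshold and
#'   filter counts).
#' @export
segment_paranodes <- function(stack, params = segmentation_params(),
                              channel = "paranode") {
  grid <- preprocess(stack, channel, params)
  thr <- otsu_threshold(grid)
  if (params$threshold_method == "quantile")
    thr <- quantile(grid, params$threshold_quantile, names = FALSE)
  # signal-presence guard: on a structure-free field Otsu splits the noise
  # mid-histogram; require the threshold to clear the background by 4 robust
  # SDs, otherwise declare the field empty (flagged, not an error)
  bg_med <- median(grid)
  bg_rsd <- (quantile(grid, 0.75, names = FALSE) - bg_med) / 0.6745
  no_signal <- is.finite(thr) && thr < bg_med + 4 * bg_rsd
  qc <- list(threshold = thr, degenerate_histogram = !is.finite(thr),
             no_signal = no_signal)

  dims <- dim(grid)
  mask <- array(0L, dims)
  if (is.finite(thr) && !no_signal) mask[grid > thr] <- 1L
  lab <- .label3d(mask, params$connectivity)
  n_raw <- max(lab)
  qc$n_raw <- n_raw
  if (n_raw == 0)
    return(list(mask = lab, components = list(), grid = grid, qc = qc))

  idx_by_lab <- split(which(lab > 0L), lab[lab > 0L])
  comps <- lapply(idx_by_lab, component_stats, dims_zyx = dims, stack = stack)

  # optional watershed split of suspiciously long components
  if (params$split_touching) {
    out <- list()
    for (cp in comps) {
      if (cp$extents_um[1] > params$split_min_extent_um) {
        halves <- split_component(cp, dims, stack, params$connectivity)
        out <- c(out, halves %||% list(cp))
      } else out <- c(out, list(cp))
    }
    comps <- out
  }

  keep <- vapply(comps, function(cp) {
    ext <- cp$extents_um
    if (!is.null(params$blur_sigma_um)) {
      # deblur the lateral extents only: blur fattens thin cross-sections but
      # does not stretch the long axis (its flat-edge half-max stays put)
      fw <- vapply(2:3, function(a)
        2.355 * sqrt(sum(params$blur_sigma_um^2 * cp$axes[, a]^2)), 0)
      ext[2:3] <- sqrt(pmax(ext[2:3]^2 - fw^2, (0.25 * ext[2:3])^2))
    }
    cp$volume_um3 >= params$min_volume_um3 &&
      cp$volume_um3 <= params$max_volume_um3 &&
      (ext[1] / max(ext[2], 1e-9)) >= params$min_elongation
  }, logical(1))
  qc$n_after_volume <- sum(keep)
  comps <- comps[keep]

  # rebuild a dense label mask matching the filtered component list
  mask <- array(0L, dims)
  for (i in seq_along(comps)) {
    cp <- comps[[i]]
    mask[cbind(cp$voxel_idx)] <- i
    comps[[i]]$label <- i
    class(comps[[i]]) <- "paranode_component"
  }
  qc$n_final <- length(comps)
  list(mask = mask, components = comps, grid = grid, qc = qc)
}

# Split one over-long component in two with a seeded watershed on the
# anisotropic distance transform; seeds are the distance maxima of the two
# axial halves. Returns NULL when the split is degenerate.
split_component <- function(cp, dims_zyx, stack, connectivity) {
  sub <- array(0L, dims_zyx)
  sub[cbind(cp$voxel_idx)] <- 1L
  v <- stack$voxel_size_um
  dt <- .edt3d_sq(sub, c(v[3], v[2], v[1]))
  proj <- (cp$coords_um %*% cp$axis)[, 1]
  med <- median(proj)
  lin <- cp$voxel_idx[, 1] + dims_zyx[1] * (cp$voxel_idx[, 2] - 1) +
    dims_zyx[1] * dims_zyx[2] * (cp$voxel_idx[, 3] - 1)
  lo <- lin[proj < med]; hi <- lin[proj >= med]
  if (!length(lo) || !length(hi)) return(NULL)
  seeds <- c(lo[which.max(dt[lo])], hi[which.max(dt[hi])]) - 1L
  ws <- .watershed_seeded(sub, dt, as.integer(seeds), connectivity)
  parts <- lapply(1:2, function(s) which(ws == s))
  if (any(vapply(parts, length, 1L) < 5)) return(NULL)
  lapply(parts, component_stats, dims_zyx = dims_zyx, stack = stack)
}

#' Detect node-marker (Nav1.6) blobs
#'
#' Blob detection on the node channel: smoothing, per-field threshold,
#' connected components and a volume filter. Centroids are pairing evidence
#' only and never enter width measurement. A missing channel yields an empty
#' result with a QC note rather than an error.
#'
#' @param stack an [image_stack()].
#' @param params a [segmentation_params()]; the elongation filter is ignored.
#' @param channel node channel name.
#' @param min_volume_um3 marker blob volume filter (um^3).
#' @return list with `centroids_um` (matrix, possibly 0-row) and `qc`.
#' @export
segment_node_marker <- function(stack, params = segmentation_params(),
                                channel = "node", min_volume_um3 = 0.02) {
  if (!channel %in% names(stack$channels))
    return(list(centroids_um = matrix(numeric(0), ncol = 3,
                                      dimnames = list(NULL, c("x", "y", "z"))),
                qc = list(note = "node channel absent")))
  grid <- preprocess(stack, channel, params)
  thr <- otsu_threshold(grid)
  bg_med <- median(grid)
  bg_rsd <- (quantile(grid, 0.75, names = FALSE) - bg_med) / 0.6745
  dims <- dim(grid)
  mask <- array(0L, dims)
  if (is.finite(thr) && thr >= bg_med + 4 * bg_rsd) mask[grid > thr] <- 1L
  lab <- .label3d(mask, params$connectivity)
  cents <- list()
  if (max(lab) > 0) {
    idx_by_lab <- split(which(lab > 0L), lab[lab > 0L])
    for (ix in idx_by_lab) {
      cp <- component_stats(ix, dims, stack)
      if (cp$volume_um3 >= min_volume_um3) cents <- c(cents, list(cp$centroid_um))
    }
  }
  centroids <- if (length(cents)) do.call(rbind, cents) else
    matrix(numeric(0), ncol = 3)
  colnames(centroids) <- c("x", "y", "z")
  list(centroids_um = centroids, qc = list(threshold = thr, n_blobs = nrow(centroids)))
}

#' @export
print.paranode_component <- function(x, ...) {
  cat(sprintf("<paranode_component #%s> %d voxels, %.3f um^3, extents %s um\n",
              x$label %||% "?", x$n_voxels, x$volume_um3,
              paste(sprintf("%.2f", x$extents_um), collapse = " x ")))
  invisible(x)
}
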