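#' Axon-label classification parameters
#'
#' @param axon_threshold_method `"quantile"` (robust background threshold:
#'   median + `nsigma` robust SDs, suited to the sparse, bright axon label) or
#'   `"otsu"`.
#' @param nsigma robust-SD multiplier for the quantile method.
#' @param dilation_radius_um tolerance radius around the axis line when
#'   testing overlap with axon-positive voxels (um).
#' @param min_overlap_fraction fraction of axis-line samples that must fall on
#'   axon signal for a `"labeled"` call; a fraction exactly at the threshold
#'   counts as labeled.
#' @return an object of class `axon_label_params`.
#' @export
axon_label_params <- function(axon_threshold_method = c("quantile", "otsu"),
                              nsigma = 4,
                              dilation_radius_um = 0.2,
                              min_overlap_fraction = 0.5) {
  stopifnot(min_overlap_fraction > 0, min_overlap_fraction <= 1,
            dilation_radius_um >= 0)
  structure(list(axon_threshold_method = match.arg(axon_threshold_method),
                 nsigma = nsigma,
                 dilation_radius_um = dilation_radius_um,
                 min_overlap_fraction = min_overlap_fraction),
            class = "axon_label_params")
}

#' Classify a paranode as lying on a labeled or non-labeled axon
#'
#' The mCherry fill marks the axon core that the CASPR sleeve wraps, so
#' overlap is measured along the component's axis line rather than over its
#' volume: the axon channel is smoothed and thresholded, the axis line
#' between the component's endpoints is sampled at one-voxel steps, and each
#' sample counts as positive when an axon-positive voxel lies within
#' `dilation_radius_um`. The paranode is `"labeled"` when the positive
#' fraction reaches `min_overlap_fraction` (ties count as labeled).
#'
#' @param comp a measured `paranode_component` (with `endpoints_um`).
#' @param stack an [image_stack()] containing the axon channel.
#' @param params an [axon_label_params()].
#' @param channel axon channel name.
#' @return `"labeled"` or `"non-labeled"`; `NA_character_` (classification
#'   unavailable) when the axon channel is absent.
#' @export
assign_axon_status <- function(comp, stack, params = axon_label_params(),
                               channel = "axon") {
  if (!channel %in% names(stack$channels)) return(NA_character_)
  grid <- .blur3d(stack$channels[[channel]],
                  c(0.1 / stack$voxel_size_um[3],
                    0.05 / stack$voxel_size_um[2],
                    0.05 / stack$voxel_size_um[1]))
  if (params$axon_threshold_method == "otsu") {
    thr <- otsu_threshold(grid)
  } else {
    med <- median(grid)
    rsd <- (quantile(grid, 0.75, names = FALSE) - med) / 0.6745
    thr <- med + params$nsigma * max(rsd, 1e-9)
  }
  pos <- which(grid > thr)
  if (!length(pos)) return("non-labeled")
  dims <- dim(grid)
  ind <- arrayInd(pos, dims)
  v <- stack$voxel_size_um
  pos_um <- cbind(stack$origin_um[1] + (ind[, 3] - 1) * v[1],
                  stack$origin_um[2] + (ind[, 2] - 1) * v[2],
                  stack$origin_um[3] + (ind[, 1] - 1) * v[3])

  e <- comp$endpoints_um %||% {
    proj <- (sweep(comp$coords_um, 2, comp$centroid_um) %*% comp$axis)[, 1]
    rbind(comp$centroid_um + comp$axis * min(proj),
          comp$centroid_um + comp$axis * max(proj))
  }
  L <- sqrt(sum((e[2, ] - e[1, ])^2))
  nstep <- max(2L, as.integer(ceiling(L / min(v))))
  tpar <- seq(0, 1, length.out = nstep)
  samples <- cbind(e[1, 1] + tpar * (e[2, 1] - e[1, 1]),
                   e[1, 2] + tpar * (e[2, 2] - e[1, 2]),
                   e[1, 3] + tpar * (e[2, 3] - e[1, 3]))

  # restrict axon-positive voxels to the line's padded bounding box
  pad <- params$dilation_radius_um + 2 * max(v)
  keep <- pos_um[, 1] >= min(samples[, 1]) - pad & pos_um[, 1] <= max(samples[, 1]) + pad &
    pos_um[, 2] >= min(samples[, 2]) - pad & pos_um[, 2] <= max(samples[, 2]) + pad &
    pos_um[, 3] >= min(samples[, 3]) - pad & pos_um[, 3] <= max(samples[, 3]) + pad
  pos_um <- pos_um[keep, , drop = FALSE]
  if (!nrow(pos_um)) return("non-labeled")

  r2 <- params$dilation_radius_um^2
  hit <- vapply(seq_len(nstep), function(s) {
    d2 <- (pos_um[, 1] - samples[s, 1])^2 +
      (pos_um[, 2] - samples[s, 2])^2 +
      (pos_um[, 3] - samples[s, 3])^2
    any(d2 <= r2)
  }, logical(1))
  if (mean(hit) >= params$min_overlap_fraction) "labeled" else "non-labeled"
}
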