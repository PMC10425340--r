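#' Render one synthetic node field
#'
#' Renders the cropped confocal field around one node (the per-node z-stack
#' acquisition the pipeline consumes): the paranode channel holds two capsules
#' (cylinders with hemispherical caps, end-to-end extent = true length) along
#' the node axis separated by the true gap; the node channel an ellipsoidal
#' Gaussian blob centered in the gap; the axon channel (for labeled axons) a
#' thin cylinder running through both capsules and the gap. Channels are
#' convolved with the anisotropic Gaussian PSF, scaled by the staining-batch
#' factor, and corrupted by Poisson shot noise followed by Gaussian read noise
#' (an infinite `photon_scale` renders the noiseless expectation). The node is
#' centered in the field; unless `config$field_size_um` is set, the field is
#' sized to the structure plus a 3-sigma PSF margin.
#'
#' @param truth_rows the one or two `ground_truth` rows of a single node (a
#'   single row renders an isolated paranode, used in calibration studies).
#' @param config the [sim_config()] the rows were drawn from.
#' @param channels channels to render, subset of
#'   `c("paranode", "node", "axon")`.
#' @param seed optional integer seed for this field's noise draws; defaults to
#'   a child seed derived from `config$seed` and the node id.
#' @return an [image_stack()] with attribute `center_um`, the physical
#'   position of the node center in the field.
#' @export
render_stack <- function(truth_rows, config,
                         channels = c("paranode", "node"),
                         seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!nrow(truth_rows) %in% c(1L, 2L) || length(unique(truth_rows$node_id)) != 1)
    stop("render_stack expects the truth rows of exactly one node")
  truth_rows <- truth_rows[order(truth_rows$paranode_id), , drop = FALSE]
  node_id <- truth_rows$node_id[1]
  u <- unit3(c(truth_rows$orient_x[1], truth_rows$orient_y[1],
               truth_rows$orient_z[1]))
  r <- config$paranode_radius_um
  gap <- truth_rows$true_gap_um[1]
  lens <- truth_rows$true_length_um

  # capsule end-to-end intervals along the axis, node center at 0
  iv <- list(c(-(gap / 2 + lens[1]), -gap / 2))
  if (nrow(truth_rows) == 2) iv <- c(iv, list(c(gap / 2, gap / 2 + lens[2])))
  if (nrow(truth_rows) == 1) iv <- list(c(-lens[1] / 2, lens[1] / 2))

  margin <- 3 * max(config$psf_sigma_um) + 0.25
  span <- range(unlist(iv))
  ends <- rbind(u * span[1], u * span[2])
  half <- pmax(abs(ends[1, ]), abs(ends[2, ])) + r + margin
  fs <- config$field_size_um %||% (2 * half)
  vox <- config$voxel_size_um
  nvox <- pmax(4L, as.integer(ceiling(fs / vox)))      # (x, y, z) counts
  center <- (nvox - 1) * vox / 2
  if (!is.null(config$field_size_um)) {
    need <- pmax(abs(ends[1, ]), abs(ends[2, ])) + r + 3 * max(config$psf_sigma_um)
    if (any(need > fs / 2))
      stop(sprintf("geometry error: node %s does not fit the field with a 3-sigma PSF margin",
                   node_id))
  }

  xs <- (seq_len(nvox[1]) - 1) * vox[1]
  ys <- (seq_len(nvox[2]) - 1) * vox[2]
  zs <- (seq_len(nvox[3]) - 1) * vox[3]
  dims_zyx <- c(nvox[3], nvox[2], nvox[1])
  edge <- min(vox)                                     # anti-alias ramp width

  paint_capsule <- function(arr, a_um, b_um, radius) {
    # distances are computed only inside the capsule's padded bounding box
    lo <- pmin(a_um, b_um) - radius - 2 * edge
    hi <- pmax(a_um, b_um) + radius + 2 * edge
    ki <- which(xs >= lo[1] & xs <= hi[1])
    ji <- which(ys >= lo[2] & ys <= hi[2])
    ii <- which(zs >= lo[3] & zs <= hi[3])
    if (!length(ki) || !length(ji) || !length(ii)) return(arr)
    px <- xs[ki]; py <- ys[ji]; pz <- zs[ii]
    d <- seg_dist_grid(px, py, pz, a_um, b_um)
    val <- pmin(pmax((radius - d) / edge + 0.5, 0), 1)
    sub <- array(aperm(val, c(3, 2, 1)), c(length(ii), length(ji), length(ki)))
    arr[ii, ji, ki] <- pmax(arr[ii, ji, ki, drop = FALSE], sub)
    arr
  }

  # distance from every grid point (px x py x pz) to segment [a, b];
  # returns array dim (length(px), length(py), length(pz))
  seg_dist_grid <- function(px, py, pz, a, b) {
    ab <- b - a
    L2 <- sum(ab^2)
    gx <- px - a[1]; gy <- py - a[2]; gz <- pz - a[3]
    tx <- outer(outer(gx * ab[1], gy * ab[2], "+"), gz * ab[3], "+") / max(L2, 1e-12)
    tt <- pmin(pmax(tx, 0), 1)    # order matters: pmax/pmin keep dim from arg 1
    cx <- array(gx, dim(tt)) - tt * ab[1]
    cy <- array(rep(gy, each = length(px)), dim(tt)) - tt * ab[2]
    cz <- array(rep(gz, each = length(px) * length(py)), dim(tt)) - tt * ab[3]
    sqrt(cx^2 + cy^2 + cz^2)
  }

  blank <- function() array(0, dims_zyx)
  out <- list()

  if ("paranode" %in% channels) {
    arr <- blank()
    for (k in seq_along(iv)) {
      span_k <- iv[[k]]
      len_k <- diff(span_k)
      rr <- min(r, len_k / 2)                 # short paranodes become spheres
      a <- center + u * (span_k[1] + rr)      # core segment excludes the caps
      b <- center + u * (span_k[2] - rr)
      arr <- paint_capsule(arr, a, b, rr)
    }
    out$paranode <- arr
  }
  if ("node" %in% channels && nrow(truth_rows) == 2) {
    arr <- blank()
    sig_ax <- max(gap / 4, 0.08)
    sig_perp <- 0.12
    lo <- center - (sig_ax * 3 + sig_perp * 3)
    hi <- center + (sig_ax * 3 + sig_perp * 3)
    ki <- which(xs >= lo[1] & xs <= hi[1])
    ji <- which(ys >= lo[2] & ys <= hi[2])
    ii <- which(zs >= lo[3] & zs <= hi[3])
    gx <- xs[ki] - center[1]; gy <- ys[ji] - center[2]; gz <- zs[ii] - center[3]
    t_ax <- outer(outer(gx * u[1], gy * u[2], "+"), gz * u[3], "+")
    r2 <- outer(outer(gx^2, gy^2, "+"), gz^2, "+") - t_ax^2
    val <- 0.8 * exp(-0.5 * (t_ax^2 / sig_ax^2 + pmax(r2, 0) / sig_perp^2))
    arr[ii, ji, ki] <- aperm(val, c(3, 2, 1))
    out$node <- arr
  } else if ("node" %in% channels) {
    out$node <- blank()
  }
  if ("axon" %in% channels) {
    arr <- blank()
    if (isTRUE(truth_rows$axon_labeled[1])) {
      ext <- max(abs(span)) + r + margin
      arr <- paint_capsule(arr, center - u * ext, center + u * ext, 0.10)
    }
    out$axon <- arr
  }

  # PSF blur, intensity scaling, noise
  sigma_vox_zyx <- c(config$psf_sigma_um[3] / vox[3],
                     config$psf_sigma_um[2] / vox[2],
                     config$psf_sigma_um[1] / vox[1])
  batch_idx <- as.integer(sub("^batch", "", truth_rows$batch[1]))
  bf <- config$batch_factors[ifelse(is.na(batch_idx), 1L, batch_idx)]
  if (is.na(bf)) bf <- 1

  if (is.null(seed)) {
    seed <- child_seed(config$seed, sum(utf8ToInt(node_id)) +
                         7L * nrow(truth_rows))
  }
  set.seed(seed)
  noiseless <- !is.finite(config$photon_scale)
  scale <- if (noiseless) 1000 else config$photon_scale

  out <- lapply(out, function(arr) {
    arr <- .blur3d(arr, sigma_vox_zyx)
    lambda <- bf * (config$background_photons + scale * arr)
    if (noiseless) {
      counts <- lambda
    } else {
      counts <- array(rpois(length(lambda), lambda), dim(lambda))
    }
    if (config$read_noise_sd > 0 && !noiseless)
      counts <- counts + array(rnorm(length(counts), 0, config$read_noise_sd),
                               dim(counts))
    array(pmax(counts, 0), dims_zyx)
  })

  stk <- image_stack(out, vox)
  attr(stk, "center_um") <- center
  attr(stk, "node_id") <- node_id
  stk
}

#' Generate a full synthetic cohort on disk
#'
#' Samples the cohort geometry, renders one OME-TIFF per node, and writes the
#' ground-truth table plus a manifest linking stack files to truth rows.
#'
#' @param config a [sim_config()].
#' @param out_dir writable output directory (created if missing).
#' @param channels channels to render per field.
#' @return invisibly, a list with `truth` (ground truth with field centers
#'   filled), `manifest` (data.frame node_id/file), and the file paths
#'   `truth_csv`, `manifest_csv`.
#' @export
generate_cohort <- function(config, out_dir,
                            channels = c("paranode", "node")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("write error: cannot create ", out_dir)
  if (config$labeled_axon_fraction > 0) channels <- union(channels, "axon")
  truth <- sample_geometry(config)
  ids <- unique(truth$node_id)
  files <- character(length(ids))
  for (n in seq_along(ids)) {
    rows <- truth[truth$node_id == ids[n], ]
    stk <- render_stack(rows, config, channels = channels,
                        seed = child_seed(config$seed, 1000L + n))
    ctr <- attr(stk, "center_um")
    sel <- truth$node_id == ids[n]
    truth$center_x_um[sel] <- ctr[1]
    truth$center_y_um[sel] <- ctr[2]
    truth$center_z_um[sel] <- ctr[3]
    files[n] <- file.path(out_dir, paste0(ids[n], ".ome.tiff"))
    write_stack(stk, files[n])
  }
  manifest <- data.frame(node_id = ids, file = basename(files),
                         stringsAsFactors = FALSE)
  truth_csv <- file.path(out_dir, "ground_truth.csv")
  manifest_csv <- file.path(out_dir, "manifest.csv")
  write.csv(truth, truth_csv, row.names = FALSE, quote = FALSE)
  write.csv(manifest, manifest_csv, row.names = FALSE, quote = FALSE)
  invisible(list(truth = truth, manifest = manifest,
                 truth_csv = truth_csv, manifest_csv = manifest_csv,
                 files = files))
}
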