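#' Measure paranode length along the principal axis
#'
#' Projects the component's physical-coordinate voxels onto its principal
#' axis, builds the axial intensity profile averaged over a 2-voxel-radius
#' tube around the axis line, and places the two endpoints at the sub-voxel
#' positions where the profile falls to half its plateau value (linear
#' interpolation between profile bins, searched from the outside in). Length
#' is the distance between the endpoints — a 3D measure independent of the
#' component's orientation with respect to the voxel grid. When the profile
#' is too noisy for a half-maximum crossing the measurement falls back to the
#' projected voxel extent plus one mean voxel size and is flagged in QC.
#'
#' @param comp a `paranode_component` (from [segment_paranodes()]) with at
#'   least 5 voxels.
#' @param grid the preprocessed intensity array the component was segmented
#'   from (z, y, x).
#' @param stack the parent [image_stack()] (voxel size and origin).
#' @param blur_sigma_um optional total Gaussian blur sigma, (x, y, z) um (PSF
#'   combined with any preprocessing smoothing). When given, the endpoints
#'   are pushed outward by a curvature correction compensating the erosion of
#'   the blurred hemispherical caps — blur of a convex surface pulls the
#'   half-maximum surface inward by roughly the squared lateral blur over the
#'   cap radius; without it, lengths of capsule-shaped objects are
#'   underestimated by up to ~2 lateral sigmas.
#' @param cap_radius_um optional nominal cap radius of the structure (um).
#'   When given together with `blur_sigma_um`, the endpoint correction is
#'   calibrated by measuring a noiseless rendered phantom capsule of this
#'   radius at the component's tilt — reproducing grid sampling, binning and
#'   blur exactly — instead of the continuum blur model.
#' @return list with `length_um`, `endpoints_um` (2 x 3 matrix, rows are the
#'   two tips in (x, y, z) um), `method` (`"half-max"` or `"extent"`), and
#'   `profile` (data.frame of axial position and tube-averaged intensity).
#' @export
paranode_length <- function(comp, grid, stack, blur_sigma_um = NULL,
                            cap_radius_um = NULL, .correct = TRUE) {
  if (comp$n_voxels < 5)
    stop("measurement error: component has fewer than 5 voxels")
  if (comp$extents_um[1] <= 0)
    stop("measurement error: degenerate component geometry")
  v <- stack$voxel_size_um
  tube_r <- 2 * mean(v)
  pad <- 0.35
  u <- comp$axis

  # candidate voxels: everything in the component's padded bounding box
  lo <- apply(comp$coords_um, 2, min) - pad
  hi <- apply(comp$coords_um, 2, max) + pad
  dims <- dim(grid)
  ii <- idx_range(lo[3], hi[3], stack$origin_um[3], v[3], dims[1])
  jj <- idx_range(lo[2], hi[2], stack$origin_um[2], v[2], dims[2])
  kk <- idx_range(lo[1], hi[1], stack$origin_um[1], v[1], dims[3])
  px <- stack$origin_um[1] + (kk - 1) * v[1]
  py <- stack$origin_um[2] + (jj - 1) * v[2]
  pz <- stack$origin_um[3] + (ii - 1) * v[3]

  c0 <- comp$centroid_um
  gx <- px - c0[1]; gy <- py - c0[2]; gz <- pz - c0[3]
  # t = axial position, d2 = squared distance from the axis line
  t_ax <- outer(outer(gx * u[1], gy * u[2], "+"), gz * u[3], "+")    # (x,y,z)
  r2 <- outer(outer(gx^2, gy^2, "+"), gz^2, "+") - t_ax^2
  inside <- r2 <= tube_r^2
  tt <- t_ax[inside]
  vals <- aperm(grid[ii, jj, kk, drop = FALSE], c(3, 2, 1))[inside]

  # bin width adapts to the axial sampling density: along near-axial (z)
  # orientations voxel planes are 2.5x sparser than in-plane
  bw <- max(min(v), sqrt(sum((u * v)^2)) * 0.9)
  half_span <- comp$extents_um[1] / 2 + pad
  br <- seq(-half_span - bw, half_span + bw, by = bw)
  bin <- findInterval(tt, br)
  ok <- bin >= 1 & bin < length(br)
  prof <- tapply(vals[ok], factor(bin[ok], levels = seq_len(length(br) - 1)),
                 mean)
  centers <- (br[-1] + br[-length(br)]) / 2
  if (anyNA(prof)) {           # sparse sampling: interpolate empty bins
    known <- !is.na(prof)
    if (sum(known) >= 2)
      prof[!known] <- approx(centers[known], prof[known], centers[!known],
                             rule = 2)$y
    prof[is.na(prof)] <- 0
  }

  core <- abs(centers) <= comp$extents_um[1] / 4
  plateau <- if (any(core)) median(prof[core]) else max(prof)
  fallback <- function() {
    proj <- (sweep(comp$coords_um, 2, c0) %*% u)[, 1]
    len <- diff(range(proj)) + mean(v)
    list(length_um = len,
         endpoints_um = rbind(c0 + u * min(proj), c0 + u * max(proj)),
         method = "extent",
         profile = data.frame(t_um = centers, intensity = as.numeric(prof)))
  }
  if (!is.finite(plateau) || plateau <= 0) return(fallback())

  hm <- plateau / 2
  lo_cross <- cross_from_outside(centers, as.numeric(prof), hm, from_left = TRUE)
  hi_cross <- cross_from_outside(centers, as.numeric(prof), hm, from_left = FALSE)
  if (is.na(lo_cross) || is.na(hi_cross) || hi_cross <= lo_cross)
    return(fallback())
  delta <- if (.correct)
    cap_erosion_um(u, comp$extents_um, blur_sigma_um, tube_r,
                   cap_radius_um, stack$voxel_size_um) else 0
  lo_cross <- lo_cross - delta
  hi_cross <- hi_cross + delta
  list(length_um = hi_cross - lo_cross,
       endpoints_um = rbind(c0 + u * lo_cross, c0 + u * hi_cross),
       method = "half-max",
       profile = data.frame(t_um = centers, intensity = as.numeric(prof)))
}

# Outward endpoint shift compensating blur erosion of a convex capsule cap.
# Blur of the convex hemispherical tip pulls the half-maximum crossing of the
# tube-averaged axial profile inward of the true end. The shift is predicted
# by simulating the measurement on an ideal capsule: a capsule of radius
# r_cap is rendered on a fine grid in the component frame, blurred with the
# axial sigma and the (root-mean-square) lateral sigma implied by the
# component's orientation, tube-averaged, and the model's half-max crossing
# offset from the true tip is returned. Results are memoised on the rounded
# (sigma_ax, sigma_lat, r_cap, tube_r) key, so a cohort with a fixed PSF
# costs a handful of model evaluations.
cap_erosion_um <- function(axis, extents_um, blur_sigma_um, tube_r,
                           cap_radius_um = NULL, voxel_size_um = NULL) {
  r_cap <- max(extents_um[2] / 2, tube_r)
  if (is.null(blur_sigma_um))
    return(r_cap - sqrt(max(r_cap^2 - tube_r^2, 0)))
  if (!is.null(cap_radius_um) && !is.null(voxel_size_um))
    return(phantom_tip_erosion(abs(axis[3]), cap_radius_um,
                               vec3(blur_sigma_um, "blur_sigma_um"),
                               voxel_size_um))
  s2 <- vec3(blur_sigma_um, "blur_sigma_um")^2
  ax2 <- sum(s2 * axis^2)
  # lateral blur covariance in the component frame: project the diagonal
  # blur covariance onto the plane orthogonal to the axis
  b1 <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v1 <- unit3(b1 - sum(b1 * axis) * axis)
  v2 <- c(axis[2] * v1[3] - axis[3] * v1[2],
          axis[3] * v1[1] - axis[1] * v1[3],
          axis[1] * v1[2] - axis[2] * v1[1])
  m11 <- sum(s2 * v1^2); m22 <- sum(s2 * v2^2); m12 <- sum(s2 * v1 * v2)
  tr2 <- (m11 + m22) / 2
  dt <- sqrt(max(tr2^2 - (m11 * m22 - m12^2), 0))
  sl1 <- sqrt(max(tr2 + dt, 0)); sl2 <- sqrt(max(tr2 - dt, 0))
  -capsule_halfmax_offset(sqrt(ax2), sl1, sl2, r_cap, tube_r)
}

.offset_cache <- new.env(parent = emptyenv())

# Phantom calibration of the per-end erosion: render a noiseless capsule of
# the nominal radius at the component's tilt on the same voxel grid, with the
# total blur as its PSF, run the identical raw half-max measurement, and take
# half the length deficit. Captures blur, tube discretization and axial
# binning by construction. Memoised on the quantized tilt (xy voxel sizes are
# symmetric, so only |u_z| matters) and the blur/voxel/radius signature.
phantom_tip_erosion <- function(uz, r_nom, blur_sigma_um, voxel_size_um) {
  uz <- min(round(abs(uz) * 40) / 40, 1)
  key <- paste(c("ph", round(uz * 1000),
                 round(c(r_nom, blur_sigma_um, voxel_size_um) / 0.002)),
               collapse = "_")
  hit <- .offset_cache[[key]]
  if (!is.null(hit)) return(hit)
  cfg <- sim_config(photon_scale = Inf, read_noise_sd = 0,
                    paranode_radius_um = r_nom,
                    psf_sigma_um = blur_sigma_um,
                    voxel_size_um = voxel_size_um, seed = 1L)
  ux <- sqrt(max(1 - uz^2, 0))
  offs <- numeric(0)
  # average over reference lengths / azimuths to wash out grid-phase jitter
  for (len_ref in c(1.44, 1.5, 1.57)) {
    phi <- (len_ref - 1.5) * 4            # small azimuth rotation, tilt fixed
    u <- c(ux * cos(phi), ux * sin(phi), uz)
    row <- data.frame(node_id = "phantom", mouse_id = "ph", group = "ph",
                      batch = "batch1", axon_labeled = FALSE, paranode_id = 1,
                      true_length_um = len_ref, true_gap_um = 0.9,
                      true_total_um = len_ref,
                      orient_x = u[1], orient_y = u[2], orient_z = u[3],
                      center_x_um = NA, center_y_um = NA, center_z_um = NA)
    stk <- render_stack(row, cfg, channels = "paranode", seed = 1L)
    seg <- segment_paranodes(stk, segmentation_params(smooth_sigma_um = c(0, 0, 0)))
    if (!length(seg$components)) next
    main <- which.max(vapply(seg$components, `[[`, 0, "n_voxels"))
    m <- paranode_length(seg$components[[main]], seg$grid, stk,
                         .correct = FALSE)
    if (m$method == "half-max") offs <- c(offs, (len_ref - m$length_um) / 2)
  }
  off <- if (length(offs)) mean(offs) else 0
  .offset_cache[[key]] <- off
  off
}

capsule_halfmax_offset <- function(sigma_ax, sigma_l1, sigma_l2, r_cap, tube_r) {
  key <- paste(round(c(sigma_ax, sigma_l1, sigma_l2, r_cap, tube_r) / 0.005),
               collapse = "_")
  hit <- .offset_cache[[key]]
  if (!is.null(hit)) return(hit)
  h_ax <- 0.02; h_lat <- 0.04
  ext1 <- r_cap + 3.5 * sigma_l1 + h_lat
  ext2 <- r_cap + 3.5 * sigma_l2 + h_lat
  cyl_len <- max(1.0, 6 * sigma_ax)             # enough cylinder for a plateau
  ts <- seq(-cyl_len, r_cap + 4 * sigma_ax + 0.1, by = h_ax)
  l1 <- seq(-ext1, ext1, by = h_lat)
  l2 <- seq(-ext2, ext2, by = h_lat)
  # capsule: core segment ends at the origin (cap center), tip at t = r_cap
  d_ax <- pmax(ts, 0)                           # axial distance to segment
  r2_lat <- outer(l1^2, l2^2, "+")
  arr <- array(0, c(length(ts), length(l1), length(l2)))
  for (i in seq_along(ts)) {
    d <- sqrt(d_ax[i]^2 + r2_lat)
    arr[i, , ] <- pmin(pmax((r_cap - d) / h_lat + 0.5, 0), 1)
  }
  arr <- .blur3d(arr, c(sigma_ax / h_ax, sigma_l1 / h_lat, sigma_l2 / h_lat))
  tube <- r2_lat <= tube_r^2
  prof <- apply(arr, 1, function(sl) mean(sl[tube]))
  plateau <- median(prof[ts < -2 * sigma_ax - r_cap / 2])
  off <- NA_real_
  if (is.finite(plateau) && plateau > 0) {
    cr <- cross_from_outside(ts, prof, plateau / 2, from_left = FALSE)
    if (!is.na(cr)) off <- cr - r_cap            # crossing relative to true tip
  }
  if (!is.finite(off)) off <- 0
  .offset_cache[[key]] <- off
  off
}

idx_range <- function(lo_um, hi_um, origin, step, n) {
  lo <- max(1L, as.integer(floor((lo_um - origin) / step)) + 1L)
  hi <- min(n, as.integer(ceiling((hi_um - origin) / step)) + 1L)
  if (hi < lo) integer(0) else lo:hi
}

# first crossing of `level`, scanning inward from the profile's outside
cross_from_outside <- function(x, y, level, from_left) {
  idx <- seq_along(y)
  if (!from_left) idx <- rev(idx)
  above <- y[idx] >= level
  first_above <- which(above)[1]
  if (is.na(first_above) || first_above == 1) {
    if (is.na(first_above)) return(NA_real_)
    return(x[idx[1]])
  }
  i1 <- idx[first_above - 1]; i2 <- idx[first_above]
  y1 <- y[i1]; y2 <- y[i2]
  if (y2 == y1) return(x[i2])
  x[i1] + (level - y1) / (y2 - y1) * (x[i2] - x[i1])
}

#' 2D maximum-projection length (comparator)
#'
#' The naive measure that the 3D method supersedes: the component's voxels are
#' max-projected onto the xy-plane and the footprint's extent along its 2D
#' principal axis (plus one xy voxel) is reported. For structures tilted out
#' of the imaging plane this foreshortens the true length.
#'
#' @param comp a `paranode_component` with at least 5 voxels.
#' @param stack the parent [image_stack()].
#' @return length in um.
#' @export
project2d_length <- function(comp, stack) {
  if (comp$n_voxels < 5)
    stop("measurement error: component has fewer than 5 voxels")
  xy <- unique(comp$coords_um[, 1:2, drop = FALSE])
  ctr <- colMeans(xy)
  cc <- sweep(xy, 2, ctr)
  sv <- svd(cc, nu = 0, nv = 2)
  proj <- cc %*% sv$v[, 1]
  diff(range(proj)) + mean(stack$voxel_size_um[1:2])
}

#' Pairing parameters
#'
#' @param max_gap_um maximum facing-endpoint gap for a candidate pair (um).
#' @param max_angle_deg maximum angle between each component's axis and the
#'   inter-endpoint vector (collinearity tolerance, degrees).
#' @param require_marker if `TRUE`, a node-marker centroid must lie within
#'   0.5 um of the gap segment.
#' @param w_gap,w_angle score weights for the normalized gap and angle terms.
#' @return an object of class `pairing_params`.
#' @export
pairing_params <- function(max_gap_um = 3.0, max_angle_deg = 30,
                           require_marker = FALSE, w_gap = 1, w_angle = 1) {
  stopifnot(max_gap_um > 0, max_angle_deg > 0, max_angle_deg <= 90)
  structure(list(max_gap_um = max_gap_um, max_angle_deg = max_angle_deg,
                 require_marker = isTRUE(require_marker),
                 w_gap = w_gap, w_angle = w_angle),
            class = "pairing_params")
}

pair_candidate <- function(a, b, params) {
  ea <- a$endpoints_um; eb <- b$endpoints_um
  dmat <- outer(1:2, 1:2, Vectorize(function(i, j)
    sqrt(sum((ea[i, ] - eb[j, ])^2))))
  w <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
  inner_a <- ea[w[1], ]; inner_b <- eb[w[2], ]
  outer_a <- ea[3 - w[1], ]; outer_b <- eb[3 - w[2], ]
  gap_vec <- inner_b - inner_a
  gap <- sqrt(sum(gap_vec^2))
  if (gap < 1e-9) {
    ang_a <- ang_b <- 0
  } else {
    ang_a <- angle_deg(a$axis, gap_vec)
    ang_b <- angle_deg(b$axis, gap_vec)
  }
  feasible <- gap <= params$max_gap_um &&
    ang_a <= params$max_angle_deg && ang_b <= params$max_angle_deg
  score <- params$w_gap * gap / params$max_gap_um +
    params$w_angle * max(ang_a, ang_b) / params$max_angle_deg
  list(gap = gap, angle = max(ang_a, ang_b), feasible = feasible,
       score = score, inner = rbind(inner_a, inner_b),
       outer = rbind(outer_a, outer_b))
}

marker_supports <- function(cand, markers, tol = 0.5) {
  if (is.null(markers) || nrow(markers) == 0) return(FALSE)
  a <- cand$inner[1, ]; b <- cand$inner[2, ]
  ab <- b - a; L2 <- max(sum(ab^2), 1e-12)
  any(apply(markers, 1, function(m) {
    t <- min(1, max(0, sum((m - a) * ab) / L2))
    sqrt(sum((a + t * ab - m)^2)) <= tol
  }))
}

#' Pair paranodes into nodes of Ranvier
#'
#' Candidate pairs are component pairs whose facing endpoints are within
#' `max_gap_um` and whose axes are both within `max_angle_deg` of the
#' inter-endpoint vector. Candidates are scored by the weighted sum of
#' normalized gap and angle (lower is better) and accepted greedily in
#' ascending score, each component used at most once (ties broken by smaller
#' gap, then smaller label pair). With `require_marker`, a node-marker
#' centroid must lie within 0.5 um of the gap segment. Unpaired components
#' remain available for paranode-length statistics.
#'
#' @param comps list of `paranode_component`s carrying `endpoints_um` (i.e.
#'   after [paranode_length()]; see [measure_components()]).
#' @param markers optional node-marker centroid matrix from
#'   [segment_node_marker()].
#' @param params a [pairing_params()].
#' @return list with `nodes` (list of `ranvier_node`: paired component
#'   labels, inner/outer endpoints, `node_width_um`, `total_region_um`,
#'   `collinearity_deg`, `marker_support`) and `unpaired` (component labels).
#' @export
pair_paranodes <- function(comps, markers = NULL, params = pairing_params()) {
  n <- length(comps)
  labels <- vapply(comps, function(cp) as.integer(cp$label %||% NA_integer_), 1L)
  if (n < 2) return(list(nodes = list(), unpaired = labels))

  cands <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cand <- pair_candidate(comps[[i]], comps[[j]], params)
    if (!cand$feasible) next
    if (params$require_marker && !marker_supports(cand, markers)) next
    cand$i <- i; cand$j <- j
    cands <- c(cands, list(cand))
  }
  if (!length(cands)) return(list(nodes = list(), unpaired = labels))

  score <- vapply(cands, `[[`, 0, "score")
  gapv <- vapply(cands, `[[`, 0, "gap")
  li <- vapply(cands, function(cd) min(labels[cd$i], labels[cd$j]), 1L)
  lj <- vapply(cands, function(cd) max(labels[cd$i], labels[cd$j]), 1L)
  ord <- order(score, gapv, li, lj)

  used <- rep(FALSE, n)
  nodes <- list()
  for (ci in ord) {
    cand <- cands[[ci]]
    if (used[cand$i] || used[cand$j]) next
    used[cand$i] <- used[cand$j] <- TRUE
    nodes <- c(nodes, list(structure(list(
      label_a = labels[cand$i], label_b = labels[cand$j],
      component_a = comps[[cand$i]], component_b = comps[[cand$j]],
      inner_endpoints_um = cand$inner,
      outer_endpoints_um = cand$outer,
      node_width_um = cand$gap,
      total_region_um = sqrt(sum((cand$outer[1, ] - cand$outer[2, ])^2)),
      collinearity_deg = cand$angle,
      marker_support = marker_supports(cand, markers)
    ), class = "ranvier_node")))
  }
  list(nodes = nodes, unpaired = labels[!used])
}

#' Node width and total nodal region length
#'
#' `node_width` is the distance between the two flanking paranodes — the
#' Euclidean distance between their facing (inner) half-maximum endpoints.
#' `total_region_length` is the outer-tip-to-outer-tip span of the
#' paranode–gap–paranode region.
#'
#' @param node a `ranvier_node` from [pair_paranodes()].
#' @return length in um.
#' @export
node_width <- function(node) {
  if (!inherits(node, "ranvier_node"))
    stop("contract error: node_width requires a paired ranvier_node")
  node$node_width_um
}

#' @rdname node_width
#' @export
total_region_length <- function(node) {
  if (!inherits(node, "ranvier_node"))
    stop("contract error: total_region_length requires a paired ranvier_node")
  node$total_region_um
}

#' @export
print.ranvier_node <- function(x, ...) {
  cat(sprintf("<ranvier_node> comps %s+%s, width %.3f um, total %.3f um, %.1f deg\n",
              x$label_a, x$label_b, x$node_width_um, x$total_region_um,
              x$collinearity_deg))
  invisible(x)
}

#' Measure all components of one segmented field
#'
#' Convenience wrapper: runs [paranode_length()] (and optionally
#' [project2d_length()]) over every component, attaching `length_um`,
#' `endpoints_um` and the measurement method to each.
#'
#' @param seg result of [segment_paranodes()].
#' @param stack the parent [image_stack()].
#' @param with_2d also compute the 2D max-projection comparator length.
#' @param blur_sigma_um,cap_radius_um passed to [paranode_length()].
#' @return `seg$components` with measurement fields filled; components with
#'   fewer than 5 voxels are dropped (counted in `attr(,"n_too_small")`).
#' @export
measure_components <- function(seg, stack, with_2d = FALSE,
                               blur_sigma_um = NULL, cap_radius_um = NULL) {
  comps <- seg$components
  keep <- vapply(comps, function(cp) cp$n_voxels >= 5, logical(1))
  out <- lapply(comps[keep], function(cp) {
    m <- paranode_length(cp, seg$grid, stack, blur_sigma_um = blur_sigma_um,
                         cap_radius_um = cap_radius_um)
    cp$length_um <- m$length_um
    cp$endpoints_um <- m$endpoints_um
    cp$measure_method <- m$method
    if (with_2d) cp$length2d_um <- project2d_length(cp, stack)
    cp
  })
  attr(out, "n_too_small") <- sum(!keep)
  out
}
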