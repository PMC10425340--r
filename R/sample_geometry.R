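#' Sample ground-truth node geometry for a synthetic cohort
#'
#' Draws the hierarchical ground truth of a simulated imaging cohort: mice
#' within groups, nodes within mice, two collinear paranodes per node. Each
#' mouse receives Gaussian intercepts for paranode length and gap; group
#' effects act multiplicatively; lengths are truncated below at 0.2 um.
#' Orientations are drawn per node (both paranodes collinear with the node
#' axis) either uniformly on the sphere or within a tilt range from the
#' xy-plane. Mice are assigned to staining batches round-robin.
#'
#' @param config a [sim_config()] object.
#' @return A `data.frame` of class `ground_truth` with two paranode rows per
#'   node: `node_id`, `mouse_id`, `group`, `batch`, `axon_labeled`,
#'   `paranode_id` (1 or 2), `true_length_um`, `true_gap_um`, `true_total_um`,
#'   orientation (`orient_x/y/z`, unit vector) and the node center within its
#'   rendered field (`center_x/y/z_um`, filled at render time, `NA` before).
#' @export
sample_geometry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)

  ler <- cfg$labeled_effect_ratio
  if (length(ler) == 1) ler <- rep(ler, cfg$n_groups)

  rows <- vector("list", cfg$n_groups * cfg$n_mice_per_group)
  ridx <- 0L
  mouse_global <- 0L
  n_batches <- length(cfg$batch_factors)
  for (g in seq_len(cfg$n_groups)) {
    gname <- cfg$group_names[g]
    for (m in seq_len(cfg$n_mice_per_group)) {
      mouse_global <- mouse_global + 1L
      mouse_id <- sprintf("%s_m%02d", gname, m)
      batch <- ((mouse_global - 1L) %% n_batches) + 1L
      b_len <- rnorm(1, 0, cfg$mouse_sd_um)
      b_gap <- rnorm(1, 0, cfg$mouse_gap_sd_um)
      nn <- cfg$n_nodes_per_mouse

      labeled <- runif(nn) < cfg$labeled_axon_fraction
      u_node <- rnorm(nn, 0, cfg$node_sd_um)
      orient <- draw_orientations(nn, cfg)

      len_mult <- cfg$group_length_ratios[g] * ifelse(labeled, ler[g], 1)
      base_len <- (cfg$control_paranode_mean_um + b_len + u_node) * len_mult
      len1 <- pmax(0.2, base_len + rnorm(nn, 0, cfg$paranode_sd_um))
      len2 <- pmax(0.2, base_len + rnorm(nn, 0, cfg$paranode_sd_um))
      gap <- pmax(0.2, (cfg$gap_mean_um + b_gap) * cfg$group_gap_ratios[g] +
                    rnorm(nn, 0, cfg$gap_sd_um))

      node_id <- sprintf("%s_n%03d", mouse_id, seq_len(nn))
      ridx <- ridx + 1L
      rows[[ridx]] <- data.frame(
        node_id = rep(node_id, each = 2),
        mouse_id = mouse_id,
        group = gname,
        batch = sprintf("batch%d", batch),
        axon_labeled = rep(labeled, each = 2),
        paranode_id = rep(1:2, nn),
        true_length_um = as.vector(rbind(len1, len2)),
        true_gap_um = rep(gap, each = 2),
        true_total_um = rep(len1 + gap + len2, each = 2),
        orient_x = rep(orient[, 1], each = 2),
        orient_y = rep(orient[, 2], each = 2),
        orient_z = rep(orient[, 3], each = 2),
        center_x_um = NA_real_, center_y_um = NA_real_, center_z_um = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- do.call(rbind, rows[seq_len(ridx)])
  rownames(truth) <- NULL
  class(truth) <- c("ground_truth", "data.frame")
  truth
}

draw_orientations <- function(n, cfg) {
  if (cfg$orientation_mode == "uniform") {
    v <- matrix(rnorm(3 * n), ncol = 3)
    v / sqrt(rowSums(v^2))
  } else {
    th <- runif(n, cfg$tilt_range_deg[1], cfg$tilt_range_deg[2]) * pi / 180
    ph <- runif(n, 0, 2 * pi)
    cbind(cos(th) * cos(ph), cos(th) * sin(ph), sin(th))
  }
}

#' True centroid positions of the two paranodes of each node
#'
#' Utility used for truth matching: paranode centroids lie at
#' `center +/- orient * (gap/2 + length/2)` along the node axis.
#'
#' @param truth a `ground_truth` table with center columns filled.
#' @return matrix with one row per truth row, columns x/y/z (um).
#' @export
truth_paranode_centers <- function(truth) {
  side <- ifelse(truth$paranode_id == 1, -1, 1)
  off <- side * (truth$true_gap_um / 2 + truth$true_length_um / 2)
  cbind(
    x = truth$center_x_um + off * truth$orient_x,
    y = truth$center_y_um + off * truth$orient_y,
    z = truth$center_z_um + off * truth$orient_z
  )
}

#' Convert ground truth to morphometry records (no imaging)
#'
#' Builds a `MorphRecord`-style table directly from true geometry, used for
#' statistics-only simulation studies (model calibration, type-I error) where
#' the imaging and segmentation stages are not under test.
#'
#' @param truth a `ground_truth` table.
#' @param measure one of `"paranode_length"`, `"node_width"`, `"total_region"`.
#' @return a morphometry record `data.frame` (one row per paranode for
#'   `paranode_length`, one per node otherwise).
#' @export
truth_records <- function(truth,
                          measure = c("paranode_length", "node_width",
                                      "total_region")) {
  measure <- match.arg(measure)
  if (measure == "paranode_length") {
    out <- data.frame(
      measure = measure,
      value_um = truth$true_length_um,
      mouse_id = truth$mouse_id,
      node_id = truth$node_id,
      group = truth$group,
      batch = truth$batch,
      axon_type = ifelse(truth$axon_labeled, "labeled", "non-labeled"),
      stringsAsFactors = FALSE
    )
  } else {
    one <- truth[truth$paranode_id == 1, ]
    out <- data.frame(
      measure = measure,
      value_um = if (measure == "node_width") one$true_gap_um else one$true_total_um,
      mouse_id = one$mouse_id,
      node_id = one$node_id,
      group = one$group,
      batch = one$batch,
      axon_type = ifelse(one$axon_labeled, "labeled", "non-labeled"),
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}
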