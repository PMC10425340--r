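#' Simulator configuration
#'
#' Builds and validates the configuration of the synthetic node-of-Ranvier
#' stack simulator. Defaults describe a two-group CSDS-style imaging cohort:
#' paranode-pair geometry drawn per node with a hierarchical
#' mouse-within-group design, rendered at the confocal voxel size
#' 0.04 x 0.04 x 0.10 um with an anisotropic Gaussian PSF, Poisson shot noise
#' and Gaussian read noise, and staining-batch intensity multipliers.
#'
#' Paranode length for one paranode of a node in group g of mouse m is drawn as
#' `(control_paranode_mean_um + b_m + u_n) * ratio_g (* labeled_effect_ratio_g
#' if on a labeled axon) + e`, with `b_m ~ N(0, mouse_sd_um)`,
#' `u_n ~ N(0, node_sd_um)` shared by the node's two paranodes, and
#' `e ~ N(0, paranode_sd_um)`, truncated below at 0.2 um. The node gap is drawn
#' analogously from `gap_mean_um`, `mouse_gap_sd_um`, `gap_sd_um` and
#' `group_gap_ratios`.
#'
#' @param n_groups number of experimental groups.
#' @param n_mice_per_group mice per group.
#' @param n_nodes_per_mouse nodes imaged per mouse (one cropped field each).
#' @param group_names optional character vector of group labels; defaults to
#'   `"control"` plus `"treatment1"`, ... .
#' @param control_paranode_mean_um control-group mean paranode length (um).
#' @param paranode_sd_um within-mouse paranode SD (um).
#' @param mouse_sd_um between-mouse intercept SD for paranode length (um).
#' @param node_sd_um node-level intercept SD shared by a node's two paranodes
#'   (um); 0 disables the node random effect in the generative model.
#' @param group_length_ratios multiplicative group effects on paranode length
#'   (control = 1).
#' @param gap_mean_um,gap_sd_um node-gap (node width) distribution (um).
#' @param mouse_gap_sd_um between-mouse intercept SD for the gap (um).
#' @param group_gap_ratios multiplicative group effects on the gap.
#' @param paranode_radius_um capsule radius (um).
#' @param orientation_mode `"uniform"` (uniform on the sphere) or
#'   `"tilt-range"` (tilt from the xy-plane uniform in `tilt_range_deg`).
#' @param tilt_range_deg length-2 tilt range in degrees, used when
#'   `orientation_mode = "tilt-range"`.
#' @param voxel_size_um physical voxel size, (x, y, z) um.
#' @param psf_sigma_um Gaussian PSF sigma, (x, y, z) um.
#' @param photon_scale mean photon count at structure peak; `Inf` renders
#'   noiseless stacks.
#' @param read_noise_sd Gaussian read-noise SD (counts).
#' @param background_photons mean background photon level.
#' @param batch_factors per-staining-batch intensity multipliers; mice are
#'   assigned to batches round-robin.
#' @param labeled_axon_fraction fraction of nodes lying on labeled (mCherry+)
#'   axons; 0 disables the axon channel.
#' @param labeled_effect_ratio extra length multiplier applied only to
#'   paranodes on labeled axons; scalar or one value per group.
#' @param field_size_um fixed rendered field size (x, y, z) um, or `NULL` to
#'   size each field to its node with a 3-sigma PSF margin.
#' @param seed integer RNG seed; identical configurations (including the seed)
#'   produce bit-identical geometry and stacks.
#'
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_groups = 2,
                       n_mice_per_group = 6,
                       n_nodes_per_mouse = 50,
                       group_names = NULL,
                       control_paranode_mean_um = 1.6,
                       paranode_sd_um = 0.25,
                       mouse_sd_um = 0.05,
                       node_sd_um = 0,
                       group_length_ratios = rep(1, n_groups),
                       gap_mean_um = 0.9,
                       gap_sd_um = 0.15,
                       mouse_gap_sd_um = 0.02,
                       group_gap_ratios = rep(1, n_groups),
                       paranode_radius_um = 0.35,
                       orientation_mode = c("uniform", "tilt-range"),
                       tilt_range_deg = c(0, 90),
                       voxel_size_um = c(0.04, 0.04, 0.10),
                       psf_sigma_um = c(0.08, 0.08, 0.20),
                       photon_scale = 50,
                       read_noise_sd = 2,
                       background_photons = 2,
                       batch_factors = c(1.0, 1.15),
                       labeled_axon_fraction = 0,
                       labeled_effect_ratio = 1,
                       field_size_um = NULL,
                       seed = 1L) {
  cfg <- list(
    n_groups = as.integer(n_groups),
    n_mice_per_group = as.integer(n_mice_per_group),
    n_nodes_per_mouse = as.integer(n_nodes_per_mouse),
    group_names = group_names %||%
      c("control", if (n_groups > 1) paste0("treatment", seq_len(n_groups - 1))),
    control_paranode_mean_um = as.numeric(control_paranode_mean_um),
    paranode_sd_um = as.numeric(paranode_sd_um),
    mouse_sd_um = as.numeric(mouse_sd_um),
    node_sd_um = as.numeric(node_sd_um),
    group_length_ratios = as.numeric(group_length_ratios),
    gap_mean_um = as.numeric(gap_mean_um),
    gap_sd_um = as.numeric(gap_sd_um),
    mouse_gap_sd_um = as.numeric(mouse_gap_sd_um),
    group_gap_ratios = as.numeric(group_gap_ratios),
    paranode_radius_um = as.numeric(paranode_radius_um),
    orientation_mode = match.arg(orientation_mode),
    tilt_range_deg = as.numeric(tilt_range_deg),
    voxel_size_um = vec3(voxel_size_um, "voxel_size_um"),
    psf_sigma_um = vec3(psf_sigma_um, "psf_sigma_um"),
    photon_scale = as.numeric(photon_scale),
    read_noise_sd = as.numeric(read_noise_sd),
    background_photons = as.numeric(background_photons),
    batch_factors = as.numeric(batch_factors),
    labeled_axon_fraction = as.numeric(labeled_axon_fraction),
    labeled_effect_ratio = as.numeric(labeled_effect_ratio),
    field_size_um = if (!is.null(field_size_um)) vec3(field_size_um, "field_size_um"),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  design : %d group(s) x %d mice x %d nodes  [%s]\n",
              x$n_groups, x$n_mice_per_group, x$n_nodes_per_mouse,
              paste(x$group_names, collapse = ", ")))
  cat(sprintf("  lengths: paranode %.3g um (sd %.3g, mouse %.3g), gap %.3g um (sd %.3g)\n",
              x$control_paranode_mean_um, x$paranode_sd_um, x$mouse_sd_um,
              x$gap_mean_um, x$gap_sd_um))
  cat(sprintf("  imaging: voxel %s um, psf %s um, photons %.3g, read sd %.3g\n",
              paste(x$voxel_size_um, collapse = "x"),
              paste(x$psf_sigma_um, collapse = "x"),
              x$photon_scale, x$read_noise_sd))
  cat(sprintf("  seed   : %d\n", x$seed))
  invisible(x)
}

validate_sim_config <- function(cfg) {
  err <- function(...) stop("configuration error: ", sprintf(...), call. = FALSE)
  pos <- function(field) {
    v <- cfg[[field]]
    if (!all(is.finite(v)) || any(v <= 0))
      err("'%s' must be finite and > 0", field)
  }
  for (f in c("n_groups", "n_mice_per_group", "n_nodes_per_mouse",
              "control_paranode_mean_um", "paranode_sd_um",
              "gap_mean_um", "gap_sd_um", "paranode_radius_um",
              "voxel_size_um", "batch_factors",
              "group_length_ratios", "group_gap_ratios",
              "labeled_effect_ratio")) pos(f)
  for (f in c("mouse_sd_um", "node_sd_um", "mouse_gap_sd_um",
              "read_noise_sd", "background_photons", "psf_sigma_um")) {
    v <- cfg[[f]]
    if (!all(is.finite(v)) || any(v < 0)) err("'%s' must be finite and >= 0", f)
  }
  if (!(is.finite(cfg$photon_scale) && cfg$photon_scale > 0) &&
      !is.infinite(cfg$photon_scale))
    err("'photon_scale' must be > 0 (Inf allowed for noiseless rendering)")
  if (length(cfg$group_names) != cfg$n_groups)
    err("'group_names' must have one entry per group")
  if (length(cfg$group_length_ratios) != cfg$n_groups)
    err("'group_length_ratios' must have one entry per group")
  if (length(cfg$group_gap_ratios) != cfg$n_groups)
    err("'group_gap_ratios' must have one entry per group")
  if (!length(cfg$labeled_effect_ratio) %in% c(1L, cfg$n_groups))
    err("'labeled_effect_ratio' must be scalar or one value per group")
  if (cfg$labeled_axon_fraction < 0 || cfg$labeled_axon_fraction > 1)
    err("'labeled_axon_fraction' must lie in [0, 1]")
  if (cfg$orientation_mode == "tilt-range") {
    tr <- cfg$tilt_range_deg
    if (length(tr) != 2 || any(!is.finite(tr)) || tr[1] > tr[2] ||
        tr[1] < 0 || tr[2] > 90)
      err("'tilt_range_deg' must be an increasing pair within [0, 90]")
  }
  cfg
}

#' Read / write simulator configurations as YAML
#'
#' @param cfg a [sim_config()] object.
#' @param path file path.
#' @return `read_sim_config` returns a validated `sim_config`;
#'   `write_sim_config` returns `path` invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  lst <- unclass(cfg)
  lst$field_size_um <- lst$field_size_um %||% "auto"
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  if (identical(lst$field_size_um, "auto")) lst$field_size_um <- NULL
  do.call(sim_config, lst)
}
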