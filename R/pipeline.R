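#' Simulate, segment and measure a cohort in memory
#'
#' The full image-based pipeline over a synthetic cohort, one rendered field
#' per node: sample ground truth, render each field, segment the paranode
#' channel, measure paranode lengths (sub-voxel half-maximum endpoints), pair
#' paranodes into nodes, optionally classify axon-label status, and emit the
#' morphometry record table. Each field gets its own deterministic child seed,
#' so reruns with the same configuration are identical.
#'
#' @param config a [sim_config()].
#' @param seg_params a [segmentation_params()].
#' @param pairing a [pairing_params()].
#' @param axon_params an [axon_label_params()], or `NULL` to skip
#'   classification; classification also requires
#'   `config$labeled_axon_fraction > 0` (otherwise no axon channel exists).
#' @param with_node_channel also render/use the node-marker channel.
#' @param with_2d also record the 2D max-projection comparator length.
#' @param progress print a dot every 50 fields.
#' @return list with `records` (morphometry records: one `paranode_length`
#'   row per measured component — including its matched true length when
#'   within 0.5 um of a true paranode centroid — plus one `node_width` and one
#'   `total_region` row per paired node), `truth` (centers filled), and `qc`
#'   (per-field component counts and thresholds).
#' @export
simulate_measure_cohort <- function(config,
                                    seg_params = segmentation_params(),
                                    pairing = pairing_params(),
                                    axon_params = NULL,
                                    with_node_channel = FALSE,
                                    with_2d = FALSE,
                                    progress = FALSE) {
  truth <- sample_geometry(config)
  if (is.null(seg_params$blur_sigma_um))
    seg_params$blur_sigma_um <-
      sqrt(config$psf_sigma_um^2 + seg_params$smooth_sigma_um^2)
  channels <- "paranode"
  if (with_node_channel) channels <- c(channels, "node")
  use_axon <- !is.null(axon_params) && config$labeled_axon_fraction > 0
  if (use_axon) channels <- c(channels, "axon")

  ids <- unique(truth$node_id)
  rec_rows <- vector("list", length(ids))
  qc_rows <- vector("list", length(ids))
  for (n in seq_along(ids)) {
    rows <- truth[truth$node_id == ids[n], ]
    stk <- render_stack(rows, config, channels = channels,
                        seed = child_seed(config$seed, 1000L + n))
    ctr <- attr(stk, "center_um")
    sel <- truth$node_id == ids[n]
    truth$center_x_um[sel] <- ctr[1]
    truth$center_y_um[sel] <- ctr[2]
    truth$center_z_um[sel] <- ctr[3]
    rows$center_x_um <- ctr[1]; rows$center_y_um <- ctr[2]; rows$center_z_um <- ctr[3]

    seg <- segment_paranodes(stk, seg_params)
    comps <- measure_components(
      seg, stk, with_2d = with_2d,
      blur_sigma_um = sqrt(config$psf_sigma_um^2 + seg_params$smooth_sigma_um^2),
      cap_radius_um = config$paranode_radius_um)
    markers <- NULL
    if (with_node_channel)
      markers <- segment_node_marker(stk, seg_params)$centroids_um
    pr <- pair_paranodes(comps, markers, pairing)

    axst <- rep(NA_character_, length(comps))
    if (use_axon && length(comps))
      axst <- vapply(comps, assign_axon_status, "", stack = stk,
                     params = axon_params)

    meta <- rows[1, c("mouse_id", "group", "batch")]
    tc <- truth_paranode_centers(rows)
    prow <- NULL
    if (length(comps)) {
      matched <- vapply(comps, function(cp) {
        d <- sqrt(colSums((t(tc) - cp$centroid_um)^2))
        w <- which.min(d)
        if (d[w] <= 0.5) w else NA_integer_
      }, 1L)
      prow <- data.frame(
        measure = "paranode_length",
        value_um = vapply(comps, `[[`, 0, "length_um"),
        mouse_id = meta$mouse_id, node_id = ids[n],
        group = meta$group, batch = meta$batch,
        axon_type = if (use_axon)
          ifelse(is.na(axst), NA, ifelse(axst == "labeled", "labeled", "non-labeled"))
          else ifelse(rows$axon_labeled[1], "labeled", "non-labeled"),
        label = vapply(comps, `[[`, 0L, "label"),
        length2d_um = if (with_2d) vapply(comps, `[[`, 0, "length2d_um") else NA_real_,
        method = vapply(comps, `[[`, "", "measure_method"),
        true_value_um = ifelse(is.na(matched), NA_real_,
                               rows$true_length_um[matched]),
        true_paranode_id = ifelse(is.na(matched), NA_integer_,
                                  rows$paranode_id[matched]),
        stringsAsFactors = FALSE
      )
    }
    nrow_list <- lapply(pr$nodes, function(nd) data.frame(
      measure = c("node_width", "total_region"),
      value_um = c(nd$node_width_um, nd$total_region_um),
      mouse_id = meta$mouse_id, node_id = ids[n],
      group = meta$group, batch = meta$batch,
      axon_type = prow$axon_type[1] %||% NA_character_,
      label = NA_integer_, length2d_um = NA_real_, method = "pairing",
      true_value_um = c(rows$true_gap_um[1], rows$true_total_um[1]),
      true_paranode_id = NA_integer_,
      stringsAsFactors = FALSE))
    rec_rows[[n]] <- do.call(rbind, c(list(prow), nrow_list))
    qc_rows[[n]] <- data.frame(node_id = ids[n], threshold = seg$qc$threshold,
                               n_components = length(comps),
                               n_paired = 2L * length(pr$nodes),
                               stringsAsFactors = FALSE)
    if (progress && n %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  records <- do.call(rbind, rec_rows)
  rownames(records) <- NULL
  list(records = records, truth = truth, qc = do.call(rbind, qc_rows))
}

#' Run configuration for the end-to-end pipeline
#'
#' @param sim a [sim_config()].
#' @param seg a [segmentation_params()].
#' @param pairing a [pairing_params()].
#' @param axon an [axon_label_params()] or `NULL`.
#' @param design `"csds"` (group model via [fit_mixed()]) or `"dreadd"`
#'   (virus-group x axon-type model via [fit_interaction()]).
#' @param measures measures to fit.
#' @param out_dir output directory.
#' @param seed run seed, propagated into `sim`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), seg = segmentation_params(),
                       pairing = pairing_params(), axon = NULL,
                       design = c("csds", "dreadd"),
                       measures = c("paranode_length", "node_width",
                                    "total_region"),
                       out_dir = tempfile("ranvier3d_run_"), seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, seg = seg, pairing = pairing, axon = axon,
                 design = match.arg(design), measures = measures,
                 out_dir = out_dir),
            class = "run_config")
}

#' Execute the full pipeline and write all stage outputs
#'
#' simulate -> segment -> measure -> (label) -> stats, with per-stage outputs
#' under `config$out_dir`: ground truth CSV, morphometry CSV, fit JSON and a
#' run manifest (configuration echo, content hashes, row counts). Identical
#' configurations produce byte-identical morphometry CSVs and manifest
#' hashes.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `records`, `truth`, `fits` and
#'   `manifest_path`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- tryCatch(
    simulate_measure_cohort(config$sim, config$seg, config$pairing,
                            axon_params = config$axon),
    error = function(e) stop("stage simulate/segment/measure failed: ",
                             conditionMessage(e), call. = FALSE))

  morph_csv <- file.path(config$out_dir, "morphometry.csv")
  write_morphometry(res$records, morph_csv)
  truth_csv <- file.path(config$out_dir, "ground_truth.csv")
  write.csv(res$truth, truth_csv, row.names = FALSE, quote = FALSE)

  fits <- list()
  fit_json <- file.path(config$out_dir, "fit.json")
  for (ms in config$measures) {
    f <- tryCatch({
      if (config$design == "dreadd" && ms == "paranode_length")
        fit_interaction(res$records, ms)
      else fit_mixed(res$records, ms)
    }, error = function(e) {
      warning("stage stats (", ms, "): ", conditionMessage(e))
      NULL
    })
    if (is.null(f)) next
    fits[[ms]] <- f
    if (inherits(f, "ranvier_fit")) {
      ct <- pairwise_contrasts(f)
      fits[[ms]] <- list(fit = f, contrasts = ct)
    }
  }
  export <- lapply(fits, function(f) {
    if (inherits(f, "ranvier_interaction_fit")) {
      list(type = "interaction",
           interaction = as.data.frame(f$interaction),
           emmeans = summary(f$emmeans),
           within_axon_contrasts = f$within_axon_contrasts)
    } else {
      list(type = "group",
           emmeans = summary(f$fit$emmeans),
           variance_components = as.list(f$fit$variance_components),
           contrasts = f$contrasts)
    }
  })
  jsonlite::write_json(export, fit_json, auto_unbox = TRUE, digits = NA,
                       force = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ranvier3d")),
    seed = config$sim$seed,
    design = config$design,
    n_truth_rows = nrow(res$truth),
    n_records = nrow(res$records),
    config_hash = fnv1a(yaml::as.yaml(unclass(config$sim))),
    morphometry_hash = fnv1a(paste(readLines(morph_csv), collapse = "\n")),
    files = c(morphometry = basename(morph_csv), truth = basename(truth_csv),
              fit = basename(fit_json))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(list(records = res$records, truth = res$truth, fits = fits,
                 manifest_path = manifest_path, qc = res$qc))
}

# content hash for manifest determinism checks
fnv1a <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf, useBytes = TRUE)
  unname(tools::md5sum(tf))
}

#' Validate ground-truth recovery of a measured cohort
#'
#' Joins measured structures to the simulator's ground truth (paranode rows by
#' their matched true centroid within 0.5 um, node rows by node id) and
#' reports per-measure bias and RMSE, detection recall and precision, and the
#' recovered vs true percent difference for each group pair.
#'
#' @param result output of [simulate_measure_cohort()] (or a list with
#'   `records` and `truth`).
#' @return an object of class `recovery_report` (a list of data.frames);
#'   `zero_matches` is `TRUE` when nothing joined.
#' @export
validate_recovery <- function(result) {
  records <- result$records
  truth <- result$truth
  pl <- records[records$measure == "paranode_length", , drop = FALSE]
  matched <- pl[!is.na(pl$true_value_um), , drop = FALSE]

  per_measure <- do.call(rbind, lapply(
    c("paranode_length", "node_width", "total_region"), function(ms) {
      d <- records[records$measure == ms & !is.na(records$true_value_um), ,
                   drop = FALSE]
      if (!nrow(d)) return(data.frame(measure = ms, n = 0L, bias_um = NA,
                                      rmse_um = NA))
      err <- d$value_um - d$true_value_um
      data.frame(measure = ms, n = nrow(d), bias_um = mean(err),
                 rmse_um = sqrt(mean(err^2)))
    }))

  n_true <- nrow(truth)
  recall <- nrow(unique(matched[c("node_id", "true_paranode_id")])) / n_true
  precision <- if (nrow(pl)) nrow(matched) / nrow(pl) else NA_real_

  groups <- unique(truth$group)
  pd <- list()
  if (length(groups) >= 2) {
    for (a in 1) for (b in 2:length(groups)) {
      g1 <- groups[1]; g2 <- groups[b]
      tm <- tapply(truth$true_length_um, truth$group, mean)
      mm <- tapply(pl$value_um, pl$group, mean)
      pd[[length(pd) + 1]] <- data.frame(
        reference = g1, comparison = g2,
        true_pct = 100 * (tm[g2] - tm[g1]) / tm[g1],
        measured_pct = 100 * (mm[g2] - mm[g1]) / mm[g1])
    }
  }
  structure(list(per_measure = per_measure,
                 recall = recall, precision = precision,
                 percent_difference = do.call(rbind, pd),
                 zero_matches = nrow(matched) == 0),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$per_measure, row.names = FALSE)
  cat(sprintf("recall %.3f, precision %.3f\n", x$recall, x$precision))
  if (!is.null(x$percent_difference)) print(x$percent_difference, row.names = FALSE)
  invisible(x)
}
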