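# Shared fixtures: tiny simulator configs, hand-built truth rows and
# synthetic components, and the exhaustive pairing oracle.

tiny_cfg <- function(...) {
  sim_config(n_mice_per_group = 2, n_nodes_per_mouse = 3, seed = 101, ...)
}

# one-row (single paranode) or two-row (full node) truth table
capsule_truth <- function(len = 1.5, orient = c(1, 0, 0), gap = 0.9,
                          len2 = NULL, node_id = "n1", batch = "batch1",
                          labeled = FALSE) {
  orient <- orient / sqrt(sum(orient^2))
  n <- if (is.null(len2)) 1L else 2L
  lens <- if (n == 1L) len else c(len, len2)
  data.frame(node_id = node_id, mouse_id = "m1", group = "g", batch = batch,
             axon_labeled = labeled, paranode_id = seq_len(n),
             true_length_um = lens, true_gap_um = gap,
             true_total_um = sum(lens) + if (n == 2L) gap else 0,
             orient_x = orient[1], orient_y = orient[2], orient_z = orient[3],
             center_x_um = NA_real_, center_y_um = NA_real_,
             center_z_um = NA_real_, stringsAsFactors = FALSE)
}

# synthetic measured component (no imaging), for pairing logic tests
synth_comp <- function(label, center, axis, len) {
  axis <- axis / sqrt(sum(axis^2))
  list(label = as.integer(label), axis = axis,
       endpoints_um = rbind(center - axis * len / 2, center + axis * len / 2),
       centroid_um = center, n_voxels = 100L,
       extents_um = c(len, 0.7, 0.7), length_um = len)
}

# random pairing field: some collinear pairs plus isolated distractors
random_pair_field <- function(k, seed) {
  set.seed(seed)
  comps <- list()
  n_nodes <- sample(0:(k %/% 2), 1)
  lab <- 0L
  add <- function(center, axis, len) {
    lab <<- lab + 1L
    comps[[length(comps) + 1]] <<- synth_comp(lab, center, axis, len)
  }
  for (i in seq_len(n_nodes)) {
    c0 <- runif(3, 2, 6); ax <- rnorm(3)
    gap <- runif(1, 0.4, 2.0); l1 <- runif(1, 1, 2); l2 <- runif(1, 1, 2)
    ax <- ax / sqrt(sum(ax^2))
    add(c0 - ax * (gap + l1) / 2, ax, l1)
    add(c0 + ax * (gap + l2) / 2, ax, l2)
  }
  while (length(comps) < k) {
    ax <- rnorm(3)
    add(runif(3, 0, 8), ax / sqrt(sum(ax^2)), runif(1, 1, 2))
  }
  comps
}

# exhaustive matching oracle: maximize pair count, then minimize total score
exhaustive_pairs <- function(comps, params) {
  n <- length(comps)
  cand <- list()
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cd <- ranvier3d:::pair_candidate(comps[[i]], comps[[j]], params)
    if (cd$feasible) cand <- c(cand, list(list(i = i, j = j, score = cd$score)))
  }
  best <- list(count = -1, score = Inf, sel = list())
  rec <- function(idx, used, count, score, sel) {
    if (idx > length(cand)) {
      if (count > best$count ||
          (count == best$count && score < best$score - 1e-12))
        best <<- list(count = count, score = score, sel = sel)
      return()
    }
    cd <- cand[[idx]]
    if (!(cd$i %in% used) && !(cd$j %in% used))
      rec(idx + 1, c(used, cd$i, cd$j), count + 1, score + cd$score,
          c(sel, idx))
    rec(idx + 1, used, count, score, sel)
  }
  rec(1, integer(0), 0, 0, list())
  sort(vapply(best$sel, function(s) paste(cand[[s]]$i, cand[[s]]$j), ""))
}

pair_labels <- function(pairing) {
  sort(vapply(pairing$nodes, function(nd)
    paste(min(nd$label_a, nd$label_b), max(nd$label_a, nd$label_b)), ""))
}

default_blur <- function(cfg, seg = segmentation_params())
  sqrt(cfg$psf_sigma_um^2 + seg$smooth_sigma_um^2)

# render + segment + measure a single-node field, returning components
measure_field <- function(rows, cfg, seed = 1L, with_2d = FALSE,
                          seg_params = segmentation_params()) {
  stk <- render_stack(rows, cfg, channels = "paranode", seed = seed)
  seg <- segment_paranodes(stk, seg_params)
  list(stack = stk, seg = seg,
       comps = measure_components(seg, stk, with_2d = with_2d,
                                  blur_sigma_um = default_blur(cfg, seg_params),
                                  cap_radius_um = cfg$paranode_radius_um))
}
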