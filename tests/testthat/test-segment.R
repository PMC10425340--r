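test_that("preprocessing removes flat background and conserves blurred mass", {
  stk <- image_stack(list(paranode = array(5, c(10, 12, 14))),
                     c(0.04, 0.04, 0.10))
  expect_true(all(preprocess(stk, "paranode") == 0))
  expect_error(preprocess(stk, "nav16"), "key error")

  # single bright voxel: anisotropic blur is wider in z in micrometre terms
  arr <- array(0, c(41, 41, 41)); arr[21, 21, 21] <- 1000
  stk2 <- image_stack(list(paranode = arr), c(0.04, 0.04, 0.10))
  p <- segmentation_params(smooth_sigma_um = c(0.1, 0.1, 0.2))
  sm <- preprocess(stk2, "paranode", p)
  expect_equal(sum(sm), 1000, tolerance = 0.001 * 1000)
  w <- which(sm == max(sm), arr.ind = TRUE)[1, ]
  prof_z <- sm[, w[2], w[3]]; prof_x <- sm[w[1], w[2], ]
  sd_z <- sqrt(sum(prof_z * ((seq_along(prof_z) - w[1]) * 0.10)^2) / sum(prof_z))
  sd_x <- sqrt(sum(prof_x * ((seq_along(prof_x) - w[3]) * 0.04)^2) / sum(prof_x))
  expect_equal(sd_z, 0.2, tolerance = 0.02)
  expect_equal(sd_x, 0.1, tolerance = 0.02)
})

test_that("two rendered capsules are segmented with high voxel overlap", {
  cfg <- sim_config(seed = 1)
  tr <- capsule_truth(len = 1.7, orient = c(0.7, 0.5, 0.51), gap = 1.0,
                      len2 = 1.4)
  stk <- render_stack(tr, cfg, channels = "paranode", seed = 12)
  seg <- segment_paranodes(stk)
  expect_length(seg$components, 2)

  # ground-truth capsule masks from the analytic geometry
  ctr <- attr(stk, "center_um")
  u <- c(tr$orient_x[1], tr$orient_y[1], tr$orient_z[1])
  d <- dim(stk$channels$paranode)
  idx <- arrayInd(seq_len(prod(d)), d)
  pts <- voxel_to_um(stk, idx)
  seg_dist <- function(a, b) {
    ab <- b - a; L2 <- sum(ab^2)
    tt <- pmin(pmax(((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
                       (pts[, 3] - a[3]) * ab[3]) / L2, 0), 1)
    sqrt((pts[, 1] - a[1] - tt * ab[1])^2 + (pts[, 2] - a[2] - tt * ab[2])^2 +
           (pts[, 3] - a[3] - tt * ab[3])^2)
  }
  r <- cfg$paranode_radius_um
  for (k in 1:2) {
    span <- if (k == 1) c(-(1.0 / 2 + 1.7), -1.0 / 2) else c(1.0 / 2, 1.0 / 2 + 1.4)
    a <- ctr + u * (span[1] + r); b <- ctr + u * (span[2] - r)
    true_mask <- seg_dist(a, b) <= r
    jac <- vapply(1:2, function(l) {
      got <- as.vector(seg$mask) == l
      sum(got & true_mask) / sum(got | true_mask)
    }, 0)
    expect_gte(max(jac), 0.7)
  }
})

test_that("a pure-noise field yields no components", {
  cfg <- sim_config(seed = 1)
  set.seed(42)
  arr <- array(rpois(30 * 60 * 60, 2) + rnorm(30 * 60 * 60, 0, 2),
               c(30, 60, 60))
  stk <- image_stack(list(paranode = pmax(arr, 0)), cfg$voxel_size_um)
  seg <- segment_paranodes(stk)
  expect_length(seg$components, 0)
})

test_that("label mask and component list stay in bijection", {
  cfg <- sim_config(seed = 2)
  tr <- capsule_truth(len = 1.6, orient = c(0.9, 0.3, 0.31), len2 = 1.5)
  stk <- render_stack(tr, cfg, channels = "paranode", seed = 21)
  seg <- segment_paranodes(stk)
  labs <- sort(unique(as.vector(seg$mask)))
  expect_identical(labs, c(0L, seq_along(seg$components)))
  expect_equal(sum(seg$mask > 0),
               sum(vapply(seg$components, `[[`, 0L, "n_voxels")))
  for (cp in seg$components)
    expect_equal(cp$volume_um3, cp$n_voxels * prod(cfg$voxel_size_um))
})

test_that("touching capsules are split at the distance-transform saddle", {
  cfg <- sim_config(photon_scale = Inf, read_noise_sd = 0, seed = 1)
  # nearly fused end-to-end pair: gap far below the blur scale
  tr <- capsule_truth(len = 1.7, orient = c(1, 0, 0), gap = 0.05, len2 = 1.7)
  stk <- render_stack(tr, cfg, channels = "paranode", seed = 30)
  fused <- segment_paranodes(stk, segmentation_params(split_touching = FALSE))
  expect_length(fused$components, 1)
  split <- segment_paranodes(stk, segmentation_params(split_touching = TRUE,
                                                      split_min_extent_um = 3.0))
  expect_length(split$components, 2)
  # the split plane sits near the true midpoint: component centroids on
  # opposite sides, each ~ (gap + len)/2 from center
  ctr <- attr(stk, "center_um")
  off <- vapply(split$components, function(cp)
    (cp$centroid_um - ctr)[1], 0)
  expect_true(prod(off) < 0)
  expect_lt(max(abs(abs(off) - (0.05 / 2 + 1.7 / 2))), 0.35)
})

test_that("node-marker blobs are detected at the gap center", {
  cfg <- sim_config(photon_scale = Inf, read_noise_sd = 0, seed = 1)
  tr <- capsule_truth(len = 1.5, orient = c(0.6, 0.64, 0.48), gap = 1.0,
                      len2 = 1.5)
  stk <- render_stack(tr, cfg, channels = c("paranode", "node"), seed = 40)
  mk <- segment_node_marker(stk)
  expect_equal(nrow(mk$centroids_um), 1)
  expect_lt(sqrt(sum((mk$centroids_um[1, ] - attr(stk, "center_um"))^2)), 0.2)

  # absent channel: empty result with QC note, not an error
  stk2 <- image_stack(list(paranode = stk$channels$paranode),
                      stk$voxel_size_um)
  mk2 <- segment_node_marker(stk2)
  expect_equal(nrow(mk2$centroids_um), 0)
  expect_match(mk2$qc$note, "absent")
})
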