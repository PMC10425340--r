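noiseless_cfg <- function() sim_config(photon_scale = Inf, read_noise_sd = 0,
                                       seed = 1)

test_that("paranode length is recovered in 3D regardless of orientation", {
  cfg <- noiseless_cfg()
  f_flat <- measure_field(capsule_truth(1.5, c(1, 0, 0)), cfg, seed = 2)
  expect_length(f_flat$comps, 1)
  expect_lt(abs(f_flat$comps[[1]]$length_um - 1.5), 0.1)
  expect_identical(f_flat$comps[[1]]$measure_method, "half-max")

  th <- 60 * pi / 180
  f_tilt <- measure_field(capsule_truth(1.5, c(cos(th), 0, sin(th))), cfg,
                          seed = 2)
  expect_lt(abs(f_tilt$comps[[1]]$length_um - 1.5), 0.1)
  expect_lt(abs(f_tilt$comps[[1]]$length_um - f_flat$comps[[1]]$length_um), 0.1)
})

test_that("degenerate components are measurement errors", {
  stk <- image_stack(list(paranode = array(1, c(4, 4, 4))), c(0.04, 0.04, 0.1))
  tiny <- list(label = 1L, n_voxels = 4L, extents_um = c(0.1, 0.05, 0),
               coords_um = matrix(runif(12), 4, 3), centroid_um = c(0, 0, 0),
               axis = c(1, 0, 0))
  expect_error(paranode_length(tiny, stk$channels$paranode, stk),
               "measurement error")
})

test_that("2D max-projection foreshortens tilted capsules as cos(theta)", {
  cfg <- noiseless_cfg()
  r <- cfg$paranode_radius_um
  # in the imaging plane: 2D equals 3D
  f0 <- measure_field(capsule_truth(1.5, c(0.8, 0.6, 0)), cfg, seed = 3,
                      with_2d = TRUE)
  expect_lt(abs(f0$comps[[1]]$length2d_um - f0$comps[[1]]$length_um), 0.08)
  # tilted 60 deg: projected extent of a capsule is (L - 2r) cos(theta) + 2r
  th <- 60 * pi / 180
  f60 <- measure_field(capsule_truth(1.5, c(cos(th), 0, sin(th))), cfg,
                       seed = 3, with_2d = TRUE)
  stadium <- (1.5 - 2 * r) * cos(th) + 2 * r
  expect_lt(abs(f60$comps[[1]]$length2d_um - stadium), 0.1)
  expect_lt(f60$comps[[1]]$length2d_um, 1.5 * cos(th) + 2 * r + 0.1)
  # along z: the footprint is the cap disc, not the length
  fz <- measure_field(capsule_truth(1.5, c(0.05, 0, 0.9987)), cfg, seed = 3,
                      with_2d = TRUE)
  expect_lt(fz$comps[[1]]$length2d_um, 1.0)
  expect_gt(fz$comps[[1]]$length2d_um, 0.55)
})

test_that("collinear capsule pairs become one node with the true width", {
  cfg <- noiseless_cfg()
  tr <- capsule_truth(1.5, c(0.72, 0.4, 0.57), gap = 0.8, len2 = 1.5)
  f <- measure_field(tr, cfg, seed = 5)
  pr <- pair_paranodes(f$comps)
  expect_length(pr$nodes, 1)
  expect_length(pr$unpaired, 0)
  nd <- pr$nodes[[1]]
  expect_lt(abs(node_width(nd) - 0.8), 0.1)
  expect_lt(abs(total_region_length(nd) - (1.5 + 0.8 + 1.5)), 0.15)
  expect_gte(total_region_length(nd), node_width(nd))
})

test_that("pairing picks the collinear partner and leaves distractors", {
  a <- synth_comp(1, c(2.0, 2, 2), c(1, 0, 0), 1.5)
  b <- synth_comp(2, c(4.3, 2, 2), c(1, 0, 0), 1.5)   # facing gap 0.8
  c3 <- synth_comp(3, c(9.0, 2, 2), c(1, 0, 0), 1.5)  # 4 um away from b
  pr <- pair_paranodes(list(a, b, c3))
  expect_equal(pair_labels(pr), "1 2")
  expect_identical(pr$unpaired, 3L)
  expect_identical(pair_labels(pr),
                   exhaustive_pairs(list(a, b, c3), pairing_params()))

  # laterally offset parallel capsules fail the collinearity test
  d <- synth_comp(1, c(2, 2, 2), c(1, 0, 0), 1.5)
  e <- synth_comp(2, c(2, 3.5, 2), c(1, 0, 0), 1.5)
  pr2 <- pair_paranodes(list(d, e))
  expect_length(pr2$nodes, 0)
  expect_identical(sort(pr2$unpaired), c(1L, 2L))
})

test_that("node width is the inner-endpoint distance, zero allowed", {
  a <- synth_comp(1, c(1.25, 0, 0), c(1, 0, 0), 1.5)   # inner tip at 2.0
  b <- synth_comp(2, c(3.65, 0, 0), c(1, 0, 0), 1.5)   # inner tip at 2.9
  pr <- pair_paranodes(list(a, b))
  expect_equal(node_width(pr$nodes[[1]]), 0.9, tolerance = 1e-9)
  expect_error(node_width(a), "contract error")
  expect_error(total_region_length(list()), "contract error")

  # coincident inner endpoints: width 0, still a valid pair
  z1 <- synth_comp(1, c(1.25, 0, 0), c(1, 0, 0), 1.5)
  z2 <- synth_comp(2, c(2.75, 0, 0), c(1, 0, 0), 1.5)
  pr0 <- pair_paranodes(list(z1, z2))
  expect_equal(node_width(pr0$nodes[[1]]), 0)
})

test_that("a bent node obeys the triangle inequality within 1%", {
  th <- 10 * pi / 180
  u2 <- c(cos(th), sin(th), 0)
  a <- synth_comp(1, c(-0.45 - 0.75, 0, 0), c(1, 0, 0), 1.5)  # inner tip -0.45
  b <- synth_comp(2, c(0.45, 0, 0) + u2 * 0.75, u2, 1.5)      # bent arm
  pr <- pair_paranodes(list(a, b))
  expect_length(pr$nodes, 1)
  nd <- pr$nodes[[1]]
  parts <- 1.5 + node_width(nd) + 1.5
  expect_lte(total_region_length(nd), parts * 1.0001)
  expect_gt(total_region_length(nd), parts * 0.99)
})

test_that("marker support gates pairing when required", {
  a <- synth_comp(1, c(2.0, 2, 2), c(1, 0, 0), 1.5)
  b <- synth_comp(2, c(4.3, 2, 2), c(1, 0, 0), 1.5)
  on_gap <- matrix(c(3.15, 2, 2), 1)
  far <- matrix(c(3.15, 4.5, 2), 1)
  p <- pairing_params(require_marker = TRUE)
  expect_length(pair_paranodes(list(a, b), on_gap, p)$nodes, 1)
  expect_length(pair_paranodes(list(a, b), far, p)$nodes, 0)
})

test_that("pairing conserves components over simulated fields", {
  cfg <- sim_config(n_groups = 1, n_mice_per_group = 2, n_nodes_per_mouse = 6,
                    seed = 19)
  tr <- sample_geometry(cfg)
  for (id in unique(tr$node_id)[1:6]) {
    f <- measure_field(tr[tr$node_id == id, ], cfg, seed = 50 + match(id, tr$node_id))
    pr <- pair_paranodes(f$comps)
    expect_equal(2 * length(pr$nodes) + length(pr$unpaired), length(f$comps))
  }
})
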