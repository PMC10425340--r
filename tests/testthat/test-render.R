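test_that("noiseless render recovers capsule extents at half-maximum", {
  cfg <- sim_config(photon_scale = Inf, read_noise_sd = 0, seed = 1)
  tr <- capsule_truth(len = 1.5, orient = c(1, 0, 0))
  stk <- render_stack(tr, cfg, channels = "paranode", seed = 2)
  arr <- stk$channels$paranode
  bg <- median(arr)
  mask <- arr > bg + (max(arr) - bg) / 2
  idx <- which(mask, arr.ind = TRUE)            # (z, y, x)
  v <- stk$voxel_size_um
  x_extent <- diff(range(idx[, 3])) * v[1]
  y_extent <- diff(range(idx[, 2])) * v[2]
  # the half-max mask is the capsule eroded by blur of its convex surface:
  # extents sit just inside the true ones, never outside, and the erosion is
  # bounded by ~sigma_lat_max^2-scale shifts per end
  expect_lte(x_extent, 1.5 + 2 * v[1])
  expect_gte(x_extent, 1.5 - 0.25)
  expect_lte(y_extent, 0.7 + 2 * v[2])
  expect_gte(y_extent, 0.7 - 0.2)
  # the measurement path (with phantom tip correction) recovers the full
  # end-to-end extent
  seg <- segment_paranodes(stk)
  m <- measure_components(seg, stk, blur_sigma_um = default_blur(cfg),
                          cap_radius_um = cfg$paranode_radius_um)
  expect_lt(abs(m[[1]]$length_um - 1.5), 0.1)
})

test_that("staining-batch factors scale mean foreground intensity", {
  cfg <- sim_config(batch_factors = c(1, 2), background_photons = 0, seed = 1)
  tr1 <- capsule_truth(len = 1.6, orient = c(1, 0, 0), len2 = 1.6,
                       batch = "batch1")
  tr2 <- tr1; tr2$batch <- "batch2"
  s1 <- render_stack(tr1, cfg, channels = "paranode", seed = 9)
  s2 <- render_stack(tr2, cfg, channels = "paranode", seed = 9)
  fg <- s1$channels$paranode > 0.25 * max(s1$channels$paranode)
  ratio <- mean(s2$channels$paranode[fg]) / mean(s1$channels$paranode[fg])
  expect_lt(abs(ratio - 2.0), 0.1)
})

test_that("non-labeled axon channel contains no structure above noise", {
  cfg <- sim_config(seed = 1)
  tr <- capsule_truth(len = 1.5, orient = c(1, 0, 0), len2 = 1.5,
                      labeled = FALSE)
  stk <- render_stack(tr, cfg, channels = c("paranode", "axon"), seed = 3)
  sm <- ranvier3d:::.blur3d(stk$channels$axon, c(1, 2, 2))
  z <- (sm - mean(sm)) / sd(sm)
  # smoothed pure-noise field: no coherent bright object
  expect_lt(mean(z > 3), 0.005)
  # whereas the paranode channel holds obvious structure
  smp <- ranvier3d:::.blur3d(stk$channels$paranode, c(1, 2, 2))
  zp <- (smp - mean(smp)) / sd(smp)
  expect_gt(max(zp), 5)
})

test_that("a structure that cannot fit the requested field is a geometry error", {
  cfg <- sim_config(field_size_um = c(2, 2, 2), seed = 1)
  tr <- capsule_truth(len = 1.8, orient = c(1, 0, 0), len2 = 1.8,
                      node_id = "nodeX")
  expect_error(render_stack(tr, cfg, channels = "paranode"),
               "geometry error.*nodeX")
})

test_that("rendering is deterministic under a fixed seed", {
  cfg <- tiny_cfg()
  tr <- capsule_truth(len = 1.4, orient = c(0.6, 0.5, 0.62), len2 = 1.7)
  a <- render_stack(tr, cfg, channels = c("paranode", "node"), seed = 4)
  b <- render_stack(tr, cfg, channels = c("paranode", "node"), seed = 4)
  expect_identical(a$channels, b$channels)
})

test_that("rendered capsule midpoints sit at the true axial separation", {
  cfg <- sim_config(photon_scale = Inf, read_noise_sd = 0, seed = 1)
  tr <- capsule_truth(len = 1.2, orient = c(0.8, 0.36, 0.48), gap = 1.0,
                      len2 = 1.8)
  stk <- render_stack(tr, cfg, channels = "paranode", seed = 6)
  seg <- segment_paranodes(stk)
  expect_length(seg$components, 2)
  cents <- t(vapply(seg$components, `[[`, numeric(3), "centroid_um"))
  sep <- sqrt(sum((cents[1, ] - cents[2, ])^2))
  expected <- 1.2 / 2 + 1.0 + 1.8 / 2           # midpoint-to-midpoint
  expect_lt(abs(sep - expected), 0.08)
})
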