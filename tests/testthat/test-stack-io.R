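make_stack <- function(seed = 1, nc = 2, d = c(6, 10, 12)) {
  set.seed(seed)
  ch <- lapply(seq_len(nc), function(i) array(runif(prod(d)) * 120, d))
  names(ch) <- c("paranode", "node", "axon")[seq_len(nc)]
  image_stack(ch, c(0.04, 0.04, 0.10))
}

test_that("OME-TIFF round trip preserves voxel size, names and intensities", {
  stk <- make_stack()
  f <- tempfile(fileext = ".ome.tiff")
  write_stack(stk, f)
  rt <- read_stack(f)
  expect_equal(rt$voxel_size_um, c(0.04, 0.04, 0.10), tolerance = 1e-6)
  expect_identical(names(rt$channels), c("paranode", "node"))
  expect_equal(rt$channels$paranode, stk$channels$paranode, tolerance = 1e-6)
  # a second cycle stays within container precision (~2^-32 relative)
  f2 <- tempfile(fileext = ".ome.tiff")
  write_stack(rt, f2)
  rt2 <- read_stack(f2)
  expect_equal(rt2$channels, rt$channels, tolerance = 1e-8)
})

test_that("plain TIFF without metadata needs a voxel-size override", {
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(1:3, function(i) matrix(runif(20), 4, 5)), f,
                  bits.per.sample = 32L, reduce = FALSE)
  expect_error(read_stack(f), "metadata error")
  stk <- read_stack(f, voxel_size_override = c(0.1, 0.1, 0.3))
  expect_equal(dim(stk$channels$ch0), c(3, 4, 5))
  expect_equal(stk$voxel_size_um, c(0.1, 0.1, 0.3))
})

test_that("physical crops cover the requested box at voxel resolution", {
  d <- c(60, 200, 220)
  stk <- image_stack(list(paranode = array(0, d)), c(0.04, 0.04, 0.10))
  cr <- crop_um(stk, center_um = c(4.4, 4, 3), size_um = c(6, 6, 4))
  expect_equal(dim(cr$channels$paranode), c(40, 150, 150))
  # a crop past the stack edge is clipped with a warning
  expect_warning(cl <- crop_um(stk, c(0, 0, 0), c(2, 2, 2)), "clipped")
  expect_true(all(dim(cl$channels$paranode) <= c(11, 26, 26)))
  expect_error(crop_um(stk, c(100, 100, 100), c(1, 1, 1)), "bounds error")
})

test_that("crop offsets keep physical coordinates absolute", {
  d <- c(30, 50, 50)
  arr <- array(0, d); arr[15, 25, 30] <- 7
  stk <- image_stack(list(paranode = arr), c(0.04, 0.04, 0.10))
  p_um <- voxel_to_um(stk, cbind(15, 25, 30))
  cr <- crop_um(stk, center_um = as.numeric(p_um), size_um = c(1, 1, 1))
  idx <- which(cr$channels$paranode == 7, arr.ind = TRUE)
  expect_equal(nrow(idx), 1)
  expect_equal(as.numeric(voxel_to_um(cr, idx)), as.numeric(p_um),
               tolerance = 1e-9)
  # index -> um -> index identity
  back <- um_to_voxel(stk, p_um)
  expect_equal(as.integer(back), c(15L, 25L, 30L))
})

test_that("morphometry tables round-trip through CSV", {
  rec <- data.frame(measure = "paranode_length",
                    value_um = round(runif(600, 1, 2), 6),
                    mouse_id = rep(sprintf("m%02d", 1:12), each = 50),
                    node_id = sprintf("n%03d", 1:600), group = "control",
                    batch = "batch1", axon_type = "n/a",
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".csv")
  write_morphometry(rec, f)
  rt <- read_morphometry(f)
  expect_equal(rt, rec)

  empty <- rec[0, ]
  write_morphometry(empty, f)
  expect_equal(nrow(read_morphometry(f)), 0)

  bad <- rec; bad$value_um[3] <- NaN
  expect_error(write_morphometry(bad, f), "non-finite")
  expect_error(read_morphometry(textConnection("a,b\n1,2")) ,"format error")
})
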