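test_that("empty and trivial masks label correctly", {
  m <- matrix(FALSE, 5, 7)
  lab <- binary_mask_to_labelmap(m)
  expect_true(all(lab == 0L))
  expect_equal(n_instances(lab), 0L)
  expect_error(binary_mask_to_labelmap(matrix(logical(0), 0, 0)), "non-empty")
  expect_error(binary_mask_to_labelmap(m, connectivity = 6), "4 or 8")
})

test_that("ids are assigned in raster-scan order", {
  m <- matrix(FALSE, 6, 9)
  m[2:4, 7:8] <- TRUE      # right blob
  m[2:4, 2:3] <- TRUE      # left blob, same top row
  lab <- binary_mask_to_labelmap(m, 8)
  expect_equal(n_instances(lab), 2L)
  expect_equal(lab[2, 2], 1L)   # left-most blob first in raster order
  expect_equal(lab[2, 7], 2L)
  expect_identical(lab, binary_mask_to_labelmap(m, 8))  # deterministic
})

test_that("connectivity 4 vs 8 differ on diagonal bridges", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(n_instances(binary_mask_to_labelmap(m, 8)), 1L)
  expect_equal(n_instances(binary_mask_to_labelmap(m, 4)), 2L)
})

test_that("component labelling agrees with a flood-fill oracle and EBImage", {
  set.seed(42)
  for (i in 1:12) {
    m <- matrix(runif(40 * 50) < 0.35, 40, 50)
    for (conn in c(4, 8)) {
      lab <- binary_mask_to_labelmap(m, conn)
      oracle <- flood_fill_labels(m, conn)
      expect_equal(n_instances(lab), max(oracle))
      # oracle assigns raster-order ids too, so the maps must be identical
      expect_identical(normalize_labels(oracle), lab)
    }
    # EBImage bwlabel is an independent 4-connected implementation
    eb <- matrix(as.integer(EBImage::bwlabel(m)), 40, 50)
    expect_equal(n_instances(binary_mask_to_labelmap(m, 4)), max(eb))
  }
})

test_that("instance extraction matches direct pixel counting", {
  gt <- matrix(0L, 10, 10)
  gt[4:6, 4:6] <- 1L
  inst <- extract_instances(gt)
  expect_equal(inst$area, 9L)
  expect_false(inst$touches_border)
  expect_equal(inst$centroid_row, 4)   # 0-based centre of rows 4:6
  expect_equal(inst$centroid_col, 4)

  gt2 <- matrix(0L, 5, 5); gt2[1:5, 1:5] <- 1L
  expect_true(extract_instances(gt2)$touches_border)

  set.seed(7)
  for (i in 1:8) {
    lab <- random_rect_map(30, 40, 6)
    inst <- extract_instances(lab)
    for (id in inst$id) {
      expect_equal(inst$area[id], sum(lab == id))
    }
    expect_equal(sum(inst$area), sum(lab > 0L))   # conservation
  }
})

test_that("bounding boxes equal brute-force min/max scans", {
  lab <- matrix(0L, 10, 12)
  lab[5, 7] <- 1L
  b <- labelmap_to_boxes(lab)
  expect_equal(unlist(b[1, c("min_x", "min_y", "max_x", "max_y")]),
               c(min_x = 6, min_y = 4, max_x = 6, max_y = 4))  # 0-based

  lab2 <- matrix(0L, 12, 12)
  lab2[3:8, 4:10] <- 1L; lab2[3:5, 4:6] <- 1L   # L-ish shape rows 3-8 cols 4-10
  lab2[6:8, 8:10] <- 0L
  lab2 <- normalize_labels(lab2)
  b2 <- labelmap_to_boxes(lab2)
  expect_equal(b2$min_y, 2); expect_equal(b2$max_y, 7)
  expect_equal(b2$min_x, 3); expect_equal(b2$max_x, 9)

  set.seed(11)
  for (i in 1:6) {
    lab <- random_rect_map(25, 35, 5)
    b <- labelmap_to_boxes(lab)
    for (id in b$id) {
      px <- which(lab == id, arr.ind = TRUE)
      expect_equal(b$min_y[id], min(px[, 1]) - 1L)
      expect_equal(b$max_y[id], max(px[, 1]) - 1L)
      expect_equal(b$min_x[id], min(px[, 2]) - 1L)
      expect_equal(b$max_x[id], max(px[, 2]) - 1L)
    }
  }
})

test_that("normalization renumbers with gaps and is idempotent", {
  lab <- matrix(0L, 6, 6)
  lab[2, 2] <- 9L; lab[4, 4] <- 5L
  nl <- normalize_labels(lab)
  expect_equal(sort(unique(nl[nl > 0L])), c(1L, 2L))
  expect_equal(nl[2, 2], 1L)           # raster-first pixel gets id 1
  expect_equal(nl[4, 4], 2L)
  expect_identical(normalize_labels(nl), nl)
  expect_error(validate_labelmap(lab, normalized = TRUE), "gap-free")
  expect_error(validate_labelmap(matrix(-1L, 2, 2)), "non-negative")
})

test_that("label maps round-trip through disk", {
  set.seed(3)
  lab <- random_rect_map(40, 40, 8)
  f <- tempfile(fileext = ".tif")
  save_labelmap(lab, f)
  expect_identical(load_labelmap(f), lab)

  z <- matrix(0L, 5, 5)
  fz <- tempfile(fileext = ".tif")
  save_labelmap(z, fz)
  expect_identical(load_labelmap(fz), z)

  big <- matrix(seq_len(300 * 300), 300, 300)   # 90000 ids > 65535
  expect_error(save_labelmap(big, tempfile(fileext = ".tif")), "65535")
})

test_that("annotation loading honours alpha and luminance rules", {
  # RGBA: alpha defines foreground even where RGB is dark
  h <- 20; w <- 20
  rgba <- array(0, c(h, w, 4))
  rgba[3:6, 3:6, 4] <- 1          # blob 1 via alpha, black RGB
  rgba[12:15, 12:15, 4] <- 1      # blob 2
  rgba[8:9, 8:9, 1:3] <- 1        # bright decoy with alpha 0 -> background
  f <- tempfile(fileext = ".png")
  png::writePNG(rgba, f)
  lab <- load_annotation(f, "binary_mask")
  expect_equal(n_instances(lab), 2L)
  expect_equal(sum(lab > 0L), 32L)

  # plain grayscale: luminance > 0 is foreground
  g <- matrix(0, 10, 10); g[2:4, 2:4] <- 1; g[7:8, 7:8] <- 0.5
  f2 <- tempfile(fileext = ".png")
  png::writePNG(g, f2)
  expect_equal(n_instances(load_annotation(f2, "binary_mask")), 2L)

  # label_map kind: values are ids, normalized on load
  m <- matrix(0, 8, 8); m[2:3, 2:3] <- 5 / 65535; m[6:7, 6:7] <- 9 / 65535
  f3 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(m, f3, bits.per.sample = 16)
  lab3 <- load_annotation(f3, "label_map")
  expect_equal(sort(unique(lab3[lab3 > 0L])), c(1L, 2L))
  expect_equal(sum(lab3 == 1L), 4L)

  # multi-channel file rejected as label_map
  rgb <- array(0.5, c(5, 5, 3))
  f4 <- tempfile(fileext = ".png")
  png::writePNG(rgb, f4)
  expect_error(load_annotation(f4, "label_map"), "single-channel")
  expect_error(load_annotation(tempfile(fileext = ".png"), "binary_mask"),
               "not found")
})
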