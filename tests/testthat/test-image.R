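test_that("max projection equals the elementwise maximum", {
  m <- matrix(1:12, 3, 4)
  expect_identical(max_project(m), m)
  set.seed(2)
  st <- array(runif(3 * 4 * 5), dim = c(3, 4, 5))
  expect_equal(max_project(st), apply(st, c(1, 2), max))
  a <- matrix(0, 4, 4); a[1, 1] <- 1
  b <- matrix(0, 4, 4); b[4, 4] <- 1
  proj <- max_project(array(c(a, b), dim = c(4, 4, 2)))
  expect_equal(proj[1, 1], 1)
  expect_equal(proj[4, 4], 1)
})

test_that("contrast stretch clips the stated percentiles", {
  v <- matrix(0:999, 25, 40)
  s <- stretch_contrast(v, clip = 0.005)
  lo <- quantile(v, 0.005); hi <- quantile(v, 0.995)
  expect_true(all(s[v <= lo] == 0))
  expect_true(all(s[v >= hi] == 1))
  mid <- v > lo & v < hi
  expect_equal(s[mid], (v[mid] - lo) / (hi - lo), tolerance = 1e-12,
               ignore_attr = TRUE)
  # constant image: unchanged, flagged
  cst <- stretch_contrast(matrix(5, 10, 10))
  expect_true(attr(cst, "constant"))
  expect_equal(as.numeric(cst), rep(5, 100))
  # approximately idempotent
  s2 <- stretch_contrast(s)
  expect_lt(max(abs(s2 - s)), 0.05)
})

test_that("5x5 Sobel responds to ramps as expected", {
  expect_equal(max(sobel_5x5(matrix(3, 10, 10))$M), 0)
  ramp <- matrix(seq_len(20), 20, 20, byrow = TRUE)  # intensity grows with x
  g <- sobel_5x5(ramp)
  interior <- g$M[5:16, 5:16]
  expect_true(all(abs(g$Gy[5:16, 5:16]) < 1e-9))
  expect_equal(as.numeric(interior), rep(interior[1], length(interior)),
               tolerance = 1e-9)
  expect_true(all(axial_diff(g$D[5:16, 5:16], 0) < 1e-6))
  expect_error(sobel_5x5(matrix(0, 3, 3)), "5x5")
})

test_that("stripes yield a direction histogram at the stripe orientation", {
  img <- matrix(rep(c(0, 0, 1, 1), 16), 64, 64, byrow = TRUE)
  # stripes vary along x => stripes run along y (90 deg)
  f <- sobel_5x5(img)
  h <- cell_direction_histogram(f, matrix(1, 64, 64))
  expect_equal(sum(h$weights), 1)
  peak <- h$mids[which.max(h$weights)]
  expect_lt(axial_diff(peak, 90), 4)
  # all-background mask: empty histogram
  h0 <- cell_direction_histogram(f, matrix(0, 64, 64))
  expect_equal(sum(h0$weights), 0)
  expect_equal(attr(h0, "n_pixels"), 0L)
})

test_that("cell quantification recovers alignment ground truth", {
  # effectively parallel chords; chord ends sit on the cell boundary and
  # are removed by the mask erosion
  sl <- generate_line_image(0.8, 0.001, line_length = "chord", rng_seed = 31)
  q <- quantify_cells(sl$image, sl$mask)
  expect_equal(nrow(q), 1)
  expect_lt(q$mtsd_deg, 5)
  expect_lt(q$mtdev_deg, 5)
  expect_equal(q$eccentricity, 0.8, tolerance = 0.02)

  # uniform angles: nearly unaligned
  set.seed(8)
  su <- generate_line_image(0.6, 5000, rng_seed = 32)  # wraps to uniform
  qu <- quantify_cells(su$image, su$mask)
  expect_gt(qu$mtsd_deg, 60)

  # two identical cells in one frame give identical rows
  one <- generate_line_image(0.8, 25, img_size = 128, rng_seed = 33)
  img <- cbind(one$image, one$image)
  lab <- cbind(one$mask, 2L * one$mask)
  q2 <- quantify_cells(img, lab)
  expect_equal(nrow(q2), 2)
  expect_equal(q2$mtsd_deg[1], q2$mtsd_deg[2], tolerance = 1e-9)
  expect_equal(q2$mtdev_deg[1], q2$mtdev_deg[2], tolerance = 1e-9)
  expect_equal(q2$eccentricity[1], q2$eccentricity[2], tolerance = 1e-9)
})

test_that("tiny cells are flagged and dimension mismatches rejected", {
  img <- matrix(runif(400), 20, 20)
  lab <- matrix(0L, 20, 20)
  lab[9:11, 9:11] <- 1L
  q <- quantify_cells(img, lab)
  expect_true(q$flagged[1])
  expect_error(quantify_cells(matrix(0, 5, 5), matrix(0L, 6, 6)),
               "dimensions")
})

test_that("field mode equals cell mode for a single-cell mask", {
  sl <- generate_line_image(0.85, 28, rng_seed = 41)
  qc <- quantify_cells(sl$image, sl$mask)
  qf <- quantify_field(sl$image, mask = sl$mask)
  expect_equal(qf$mtsd_deg, qc$mtsd_deg, tolerance = 1e-9)
  expect_equal(qf$mt_main_direction_deg, qc$mt_main_direction_deg,
               tolerance = 1e-9)
  expect_equal(qf$cell_id, 0L)
})

test_that("pipeline is invariant to intensity scaling and 90-deg rotation", {
  sl <- generate_line_image(0.8, 25, rng_seed = 51)
  q1 <- quantify_cells(sl$image, sl$mask)
  q2 <- quantify_cells(sl$image * 3.7, sl$mask)
  expect_equal(q1$mtsd_deg, q2$mtsd_deg, tolerance = 1e-9)

  rot_img <- t(sl$image)[ncol(sl$image):1, ]   # 90-deg rotation
  rot_mask <- t(sl$mask)[ncol(sl$mask):1, ]
  qr <- quantify_cells(rot_img, rot_mask)
  expect_lt(axial_diff(qr$mt_main_direction_deg,
                       q1$mt_main_direction_deg + 90), 3)
  expect_equal(qr$mtsd_deg, q1$mtsd_deg, tolerance = 0.05)
})

test_that("Fourier directionality finds stripes and stays flat on noise", {
  img <- matrix(rep(c(0, 0, 0, 1, 1, 1, 1, 0), 16), 96, 96, byrow = TRUE)
  h <- fourier_directionality(img)
  peak <- h$mids[which.max(h$weights)]
  expect_lt(axial_diff(peak, 90), 6)

  set.seed(19)
  acc <- Reduce(`+`, lapply(1:10, function(i)
    fourier_directionality(matrix(runif(96 * 96), 96, 96))$weights))
  expect_lt(max(acc) / min(acc), 2)
  expect_error(fourier_directionality(matrix(0, 10, 10)), "32x32")
})

test_that("time-lapse quantification applies the pipeline per frame", {
  sl <- generate_line_image(0.8, 25, img_size = 128, rng_seed = 61)
  frames <- list(sl$image, sl$image * 2)
  q <- quantify_timelapse(frames, sl$mask)
  expect_equal(q$frame, c(1, 2))
  expect_equal(q$mtsd_deg[1], q$mtsd_deg[2], tolerance = 1e-9)
})

test_that("image and mask round-trip through TIFF and PNG", {
  sl <- generate_line_image(0.8, 25, img_size = 64, rng_seed = 71)
  img <- sl$image / max(sl$image)
  tf <- tempfile(fileext = ".tif")
  tiff::writeTIFF(img, tf, bits.per.sample = 16)
  back <- read_grayscale_image(tf)
  expect_equal(back, img, tolerance = 1e-4)

  mf <- tempfile(fileext = ".tif")
  tiff::writeTIFF(sl$mask / 255, mf, bits.per.sample = 8)
  lab <- read_label_mask(mf)
  expect_true(all(lab %in% c(0L, 1L)))
  expect_equal(lab, sl$mask)

  pf <- tempfile(fileext = ".png")
  png::writePNG(sl$mask / 255, pf)
  labp <- read_label_mask(pf)
  expect_equal(labp, sl$mask)
})
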