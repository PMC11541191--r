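test_that("Isodata finds the intermeans fixed point of two delta peaks", {
  counts <- numeric(256)
  counts[10 + 1] <- 500; counts[200 + 1] <- 500
  thr <- global_threshold_hist(counts, x_min = 0, width = 1, "isodata")
  expect_equal(thr$value, 105)
})

test_that("Isodata matches a brute-force fixed-point scan on random 8-bit histograms", {
  set.seed(7)
  for (k in 1:20) {
    counts <- numeric(256)
    # bimodal-ish random histogram
    n1 <- sample(30:90, 1); n2 <- sample(150:240, 1)
    counts[n1 + 1 + (-20:20)] <- rpois(41, 40)
    counts[n2 + 1 + (-10:10)] <- rpois(21, 25)
    fps <- intermeans_fixed_points(counts)
    expect_gt(length(fps), 0)
    thr <- global_threshold_hist(counts, 0, 1, "isodata")
    expect_true(thr$bin %in% fps)
  }
})

test_that("Otsu separates a perfectly bimodal image exactly", {
  v <- array(0, c(2, 10, 10)); v[, , 6:10] <- 255
  thr <- global_threshold(v, "otsu")
  expect_identical(thr$foreground_count, sum(v == 255))
})

test_that("Otsu agrees with an independent implementation on a random image", {
  set.seed(11)
  img <- matrix(sample(0:255, 64 * 64, replace = TRUE,
                       prob = c(rep(4, 100), rep(1, 156))), 64, 64)
  counts <- tabulate(img + 1L, 256)
  ours <- global_threshold_hist(counts, 0, 1, "otsu")$bin
  ref <- EBImage::otsu(EBImage::Image(img / 255), range = c(0, 1),
                       levels = 256) * 255
  expect_lt(abs(ours - ref), 2)
})

test_that("thresholds are equivariant and counts invariant under exact scaling", {
  set.seed(3)
  v <- gauss_blur3d(array(runif(12 * 40 * 40, 0, 1000), c(12, 40, 40)),
                    1.5, c(1, 1, 1))
  for (alg in c("isodata", "imagej_default", "otsu", "mean")) {
    t1 <- global_threshold(v, alg)
    t2 <- global_threshold(0.8 * v, alg)
    expect_equal(t2$value, 0.8 * t1$value, tolerance = 1e-9)
    expect_identical(t2$foreground_count, t1$foreground_count)
  }
})

test_that("constant images admit no threshold", {
  expect_error(global_threshold(array(7, c(2, 3, 3))), "no threshold")
})

test_that("connected labelling distinguishes 26- from 6-connectivity", {
  m <- array(FALSE, c(3, 5, 5))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE    # diagonal touch
  l26 <- label_components(m, 26)
  l6 <- label_components(m, 6)
  expect_identical(attr(l26, "n_labels"), 1L)
  expect_identical(attr(l6, "n_labels"), 2L)
  m2 <- matrix(FALSE, 5, 5); m2[1, 1] <- TRUE; m2[2, 2] <- TRUE
  expect_identical(attr(label_components(m2, 26), "n_labels"), 1L)
})

test_that("object measurement reproduces closed-form geometry", {
  expect_equal(pixels_per_um2(0.0425), 553.6332, tolerance = 1e-4)

  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  mo <- measure_objects(one, voxel_size = c(0.1, 0.1, 0.1), mode = "3d")
  expect_equal(mo$objects$volume_um3, 0.001)

  ball <- ball_mask(10)
  mb <- measure_objects(ball, voxel_size = c(0.1, 0.1, 0.1), mode = "3d")
  expect_gte(mb$objects$sphericity, 0.95)
  expect_equal(mb$objects$volume_um3, 4 / 3 * pi, tolerance = 0.01)

  # an elongated rod is far less spherical
  rod <- array(FALSE, c(9, 9, 41)); rod[4:6, 4:6, 3:39] <- TRUE
  mr <- measure_objects(rod, voxel_size = c(0.1, 0.1, 0.1), mode = "3d")
  expect_lt(mr$objects$sphericity, 0.9)
})

test_that("2D mode sums per-slice particle areas with the pixel conversion", {
  m <- array(FALSE, c(2, 10, 10))
  m[1, 2:4, 2:4] <- TRUE     # 9 px
  m[2, 6:9, 6:7] <- TRUE     # 8 px
  mo <- measure_objects(m, voxel_size = c(0.13, 0.0425, 0.0425), mode = "2d")
  expect_identical(mo$total_quantity, 17L)
  expect_equal(mo$total_area_um2, 17 / 553.6332, tolerance = 1e-4)
  expect_identical(nrow(mo$objects), 2L)
})

test_that("total quantity is additive over disjoint ROI partitions", {
  sc <- generate_scene(small_scene_spec(seed = 8))
  mask <- sc$green > 0
  d <- dim(mask)
  half <- (d[3] %/% 2)
  box <- function(x0, x1) list(z = c(0, d[1]), y = c(0, d[2]), x = c(x0, x1))
  left <- crop_roi(mask * 1, box(0, half))
  right <- crop_roi(mask * 1, box(half, d[3]))
  expect_identical(sum(left > 0) + sum(right > 0), sum(mask))
})

test_that("the surface chain recovers a bright capsule on flat background", {
  sp <- small_scene_spec(seed = 12, n_mito = 1L)
  sc <- generate_scene(sp)
  res <- imaris_like_surface(sc$green + 50, voxel_size = sp$voxel_size)
  expect_gt(nrow(res$segmentation$objects), 0)
  main <- max(res$segmentation$objects$voxel_count)
  expect_lt(abs(main - sc$true_foreground_voxels) / sc$true_foreground_voxels,
            0.15)
})

test_that("background elimination on a constant image hits the no-threshold path", {
  expect_error(imaris_like_surface(array(100, c(6, 20, 20)),
                                   voxel_size = c(0.13, 0.0425, 0.0425)),
               "no threshold")
})

test_that("sub-voxel grain size disables smoothing", {
  sc <- generate_scene(small_scene_spec(seed = 13))
  v <- sc$green + 10
  a <- imaris_like_surface(v, voxel_size = sc$spec$voxel_size,
                           grain_size = 0.001)
  # manual chain without the (skipped) smoothing step
  baseline <- gauss_blur3d(v, 0.319, sc$spec$voxel_size)
  manual <- pmax(v - baseline, 0)
  thr <- global_threshold(manual, "isodata")
  expect_equal(a$threshold$value, thr$value)
  expect_identical(sum(a$mask), thr$foreground_count)
})

test_that("ROI masking clears outside pixels and drops out-of-range slices", {
  mask <- array(1, c(6, 20, 20))
  whole <- roi_set(1:6, rep(list(list(cbind(x = c(-1, 20, 20, -1),
                                            y = c(-1, -1, 20, 20)))), 6))
  expect_equal(mask_outside_rois(mask, whole), mask, ignore_attr = TRUE)

  tiny <- roi_set(2:4, rep(list(list(cbind(x = c(4.5, 9.5, 9.5, 4.5),
                                           y = c(4.5, 4.5, 9.5, 9.5)))), 3))
  out <- mask_outside_rois(mask, tiny)
  expect_identical(dim(out), c(3L, 20L, 20L))
  expect_identical(attr(out, "slice_offset"), 1L)
  expect_equal(sum(out), 3 * 25)   # 5x5 pixel centres inside per slice
  expect_error(mask_outside_rois(mask, list()), "empty ROI set")
})

test_that("objects outside the cell ROI are removed, inside counts unchanged", {
  mask <- array(FALSE, c(4, 30, 30))
  mask[2, 10:12, 10:12] <- TRUE          # inside object (9 px)
  mask[2, 25:28, 25:28] <- TRUE          # neighbour-cell object
  roi <- roi_set(1:4, rep(list(list(cbind(x = c(2, 20, 20, 2),
                                          y = c(2, 2, 20, 20)))), 4))
  out <- mask_outside_rois(mask, roi)
  expect_identical(sum(out), 9L)
})
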