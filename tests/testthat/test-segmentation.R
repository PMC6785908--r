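# scar thresholding, connected components, label downsampling

make_wall_volume <- function(dim = c(20, 20, 20), voxel = 1) {
  list(vol = function(intensities) volume3d(array(intensities, dim), voxel),
       dim = dim)
}

test_that("FWHM rule thresholds at half of the seeded reference maximum", {
  d <- c(20, 20, 8)
  arr <- array(10, d)
  wall <- array(TRUE, d)
  arr[5:10, 5:10, 3:6] <- 200  # enhancing blob containing the seed
  vol <- volume3d(arr, 1)
  params <- segmentation_params(seeds = c(7, 7, 4))
  scar <- fwhm_scar(vol, wall, params)
  expect_equal(attr(scar, "threshold"), 100)
  expect_identical(unname(which(scar)), unname(which(arr == 200)))
})

test_that("FWHM recovers a seeded Gaussian-mixture scar within 5%", {
  set.seed(7)
  d <- c(30, 30, 30)
  wall <- array(TRUE, d)
  arr <- array(rnorm(prod(d), 30, 5), d)
  scar_true <- array(FALSE, d)
  scar_true[8:22, 8:22, 8:22] <- TRUE
  arr[scar_true] <- rnorm(sum(scar_true), 150, 10)
  vol <- volume3d(arr, 1)
  scar <- fwhm_scar(vol, wall, segmentation_params(seeds = c(15, 15, 15)))
  expect_lt(abs(sum(scar) - sum(scar_true)) / sum(scar_true), 0.05)
})

test_that("only seeded components survive the connected-component filter", {
  d <- c(20, 20, 8)
  arr <- array(10, d)
  arr[3:6, 3:6, 3:6] <- 200
  arr[12:15, 12:15, 3:6] <- 200
  vol <- volume3d(arr, 1)
  wall <- array(TRUE, d)
  scar <- fwhm_scar(vol, wall,
                    segmentation_params(seeds = c(4, 4, 4), connectivity = 6))
  expect_true(all(which(scar) == which(arr == 200 &
                                         slice.index(arr, 1) <= 6)))
})

test_that("diagonal blobs join under 26- but not 6-connectivity", {
  m <- array(0L, c(3, 3, 3))
  m[1, 1, 1] <- 1L
  m[2, 2, 2] <- 1L
  c26 <- lvcoreg:::cpp_connected_components(m, 26L)
  c6 <- lvcoreg:::cpp_connected_components(m, 6L)
  expect_equal(max(c26), 1)
  expect_equal(max(c6), 2)
  # seeded filter keeps only the seeded blob under 6-connectivity
  kept <- connected_component_filter(m == 1L, c(1, 1, 1), 6)
  expect_equal(sum(kept), 1)
  kept26 <- connected_component_filter(m == 1L, c(1, 1, 1), 26)
  expect_equal(sum(kept26), 2)
})

test_that("seeds outside the mask are ignored with a warning", {
  m <- array(FALSE, c(4, 4, 4))
  m[1:2, 1:2, 1:2] <- TRUE
  expect_warning(expect_warning(
    out <- connected_component_filter(m, c(4, 4, 4), 26), "outside"),
    "no seeds")
  expect_equal(sum(out), 0)
})

test_that("ex-vivo threshold follows the mean-minus-SD formula", {
  d <- c(10, 10, 4)
  arr <- array(50, d)
  wall <- array(TRUE, d)
  roi_vox <- as.matrix(expand.grid(1:5, 1:2, 1))
  arr[roi_vox] <- c(90, 110, 90, 110, 90, 110, 90, 110, 90, 110)  # mean 100
  vol <- volume3d(arr, 1)
  sd_roi <- sd(arr[roi_vox])
  scar <- exvivo_scar(vol, wall, region_of_interest(roi_vox, "scar_roi"),
                      region_of_interest(as.matrix(expand.grid(6:10, 9:10, 4)),
                                         "remote_roi"),
                      segmentation_params(sd_multiplier = 1,
                                          seeds = roi_vox[2, , drop = FALSE]))
  expect_equal(attr(scar, "threshold"), 100 - sd_roi)
  scar0 <- exvivo_scar(vol, wall, region_of_interest(roi_vox, "scar_roi"),
                       region_of_interest(as.matrix(expand.grid(6:10, 9:10, 4)),
                                          "remote_roi"),
                       segmentation_params(sd_multiplier = 0,
                                           seeds = roi_vox[2, , drop = FALSE]))
  expect_equal(attr(scar0, "threshold"), 100)
  # degenerate single-valued ROI
  expect_error(
    exvivo_scar(vol, wall,
                region_of_interest(matrix(c(1, 8, 2, 1, 8, 2), 2, byrow = TRUE)[1, , drop = FALSE],
                                   "scar_roi"),
                region_of_interest(roi_vox, "remote_roi"),
                segmentation_params()),
    "degenerate ROI")
})

test_that("thresholding is monotone: a higher threshold never adds voxels", {
  pr <- coarse_pair()
  vol <- pr$ex$volume
  wall <- wall_mask(pr$ex$labels)
  rois <- lvcoreg:::auto_exvivo_rois(pr$ex$labels, coarse_spec())
  masks <- lapply(c(0.5, 1, 1.5), function(k) {
    suppressWarnings(
      exvivo_scar(vol, wall, rois$scar, rois$remote,
                  segmentation_params(sd_multiplier = k)))
  })
  # sd_multiplier 0.5 has the highest threshold: mask nested within the others
  expect_true(all(!masks[[1]] | masks[[2]]))
  expect_true(all(!masks[[2]] | masks[[3]]))
  # scar masks are always subsets of the wall
  for (m in masks) expect_true(all(!m | wall))
})

test_that("ex-vivo segmentation recovers the generated scar on the coarse pair", {
  pr <- coarse_pair()
  segres <- lvcoreg:::segment_pair(pr$inv, pr$ex, coarse_spec(),
                                   segmentation_params())
  # the boundary-dimming shell is ~3x thicker relative to the scar at this
  # coarse resolution than at the native 0.4 mm grid (where the bound is
  # 10%, asserted with the acceptance fixtures)
  gt <- sum(scar_mask(pr$ex$labels))
  got <- sum(scar_mask(segres$labels_ex))
  expect_lt(abs(got - gt) / gt, 0.25)
  gt_in <- sum(scar_mask(pr$inv$labels))
  got_in <- sum(scar_mask(segres$labels_in))
  expect_lt(abs(got_in - gt_in) / gt_in, 0.05)
})

test_that("downsampling preserves uniform blocks and applies tie priority", {
  lab <- array(1L, c(4, 4, 4))
  lm <- label_map(lab, 1)
  ds <- downsample_labels(lm, 2)
  expect_true(all(ds$data == 1L))
  expect_equal(ds$voxel, 2)
  # 2x2x2 block with 4 scar and 4 myocardium -> scar by priority
  lab2 <- array(1L, c(2, 2, 2))
  lab2[1:2, 1:2, 1] <- 3L
  ds2 <- downsample_labels(label_map(lab2, 1), 2)
  expect_equal(as.integer(ds2$data), 3L)
})

test_that("non-integer downsampling ratios bin by world-space boxes", {
  lab <- array(2L, c(9, 9, 9))
  lab[1:3, , ] <- 1L
  lm <- label_map(lab, 1)
  ds <- downsample_labels(lm, 1.5)
  expect_equal(dim(ds$data), c(6L, 6L, 6L))
  expect_true(all(ds$data %in% c(1L, 2L)))
  # volume approximately preserved per label
  expect_lt(abs(sum(ds$data == 1L) * 1.5^3 - sum(lab == 1L)) / sum(lab == 1L),
            0.2)
})

test_that("downsampled phantom wall volume stays within 3% of the fine grid", {
  pr <- coarse_pair()
  ds <- downsample_labels(pr$ex$labels, coarse_spec()$invivo_voxel)
  vf <- compartment_volumes(pr$ex$labels)$wall_ml
  vc <- compartment_volumes(ds)$wall_ml
  expect_lt(abs(vc - vf) / vf, 0.03)
})

test_that("scar label replacement respects the wall", {
  pr <- coarse_pair()
  lm <- pr$inv$labels
  bad <- array(TRUE, dim(lm$data))
  expect_error(set_scar_label(lm, bad), "subset of the wall")
  new <- set_scar_label(lm, scar_mask(lm))
  expect_identical(new$data, lm$data)
})
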