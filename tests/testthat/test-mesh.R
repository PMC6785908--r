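# surface extraction, projection morphometry, nodal DICE, LV dimensions

test_that("sphere-shell surfaces and thickness match the closed form", {
  lm <- sphere_shell(20, 30, 1)
  endo <- extract_surface(lm, "endo")
  epi <- extract_surface(lm, "epi")
  expect_lt(abs(surface_area(endo) - 4 * pi * 400) / (4 * pi * 400), 0.05)
  rec <- pair_nearest_epi(endo, epi)
  th <- wall_thickness(rec)
  expect_lt(abs(mean(th) - 10), 0.5)
  expect_true(all(th >= 0))
  # paired nodes are radially aligned: the segment midpoint direction agrees
  # with the endo-node direction within one edge length
  dirs_e <- endo$vertices / sqrt(rowSums(endo$vertices^2))
  epi_p <- epi$vertices[rec$epi_node, ]
  dirs_p <- epi_p / sqrt(rowSums(epi_p^2))
  ang <- acos(pmin(1, rowSums(dirs_e * dirs_p)))
  expect_lt(mean(ang), 0.1)
})

test_that("thickness on the analytic shell converges under grid refinement", {
  th1 <- wall_thickness(local({
    lm <- sphere_shell(20, 30, 1)
    pair_nearest_epi(extract_surface(lm, "endo"), extract_surface(lm, "epi"))
  }))
  th05 <- wall_thickness(local({
    lm <- sphere_shell(20, 30, 0.5)
    pair_nearest_epi(extract_surface(lm, "endo"), extract_surface(lm, "epi"))
  }))
  expect_lt(abs(mean(th1) - mean(th05)), 0.25)
})

test_that("degenerate surface requests are rejected", {
  lm <- sphere_shell(20, 30, 1)
  nocav <- lm
  nocav$data[nocav$data == 2L] <- 0L
  nocav <- label_map(nocav$data, lm$voxel, lm$origin, lm$mv_plane)
  expect_error(extract_surface(nocav, "endo"), "empty endo")
  noplane <- label_map(lm$data, lm$voxel, lm$origin, NULL)
  expect_error(extract_surface(noplane, "endo"), "MV plane")
})

test_that("identical endo and epi meshes give zero-length projections", {
  lm <- sphere_shell(20, 30, 1)
  endo <- extract_surface(lm, "endo")
  rec <- pair_nearest_epi(endo, endo)
  expect_true(all(rec$length_mm == 0))
  expect_identical(rec$epi_node, rec$endo_node)
  st <- nodal_scar_and_transmurality(rec, endo, endo, scar_mask(lm),
                                     lvcoreg:::grid_geom(lm))
  expect_true(all(st$transmurality == 0))
  expect_true(all(!st$scar_flag))
})

test_that("transmurality reads the scar depth fraction from the labels", {
  # scar occupying the inner half of the shell within one octant
  lm <- sphere_shell(20, 30, 1)
  d <- dim(lm$data)
  xs <- seq(lm$origin[1], by = lm$voxel, length.out = d[1])
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(xs, each = d[1]), times = d[3]), d)
  Z <- array(rep(xs, each = d[1] * d[2]), d)
  r <- sqrt(X^2 + Y^2 + Z^2)
  sel <- lm$data == 1L & r <= 25 & X > 5 & Y > 5 & Z < -5
  lab <- lm$data
  lab[sel] <- 3L
  lm2 <- label_map(lab, lm$voxel, lm$origin, lm$mv_plane)
  mor <- lv_morphometry(lm2)
  at <- mor$endo$attributes
  v <- mor$endo$vertices
  deep <- v[, 1] > 9 & v[, 2] > 9 & v[, 3] < -9  # octant interior
  expect_gt(sum(deep), 20)
  expect_true(all(at$scar_flag[deep]))
  expect_lt(abs(mean(at$transmurality[deep]) - 0.5), 0.08)
  far <- v[, 1] < -5 | v[, 2] < -5 | v[, 3] > 5
  expect_true(all(at$transmurality[far] == 0))
  expect_true(all(!at$scar_flag[far]))
  # flags imply positive transmurality (endpoint samples included)
  expect_true(all(at$transmurality[at$scar_flag] > 0))
})

test_that("nodal scar DICE follows the overlap formula and is symmetric", {
  verts <- cbind(seq_len(10), 0, 0)
  tris <- cbind(1:8, 2:9, 3:10)
  mk <- function(flags) surface_mesh(verts, tris, list(scar_flag = flags))
  a <- mk(c(rep(TRUE, 8), FALSE, FALSE))
  b <- mk(c(rep(TRUE, 6), FALSE, FALSE, TRUE, TRUE))
  # pairing is node-to-node on identical coordinates: 6 common scar pairs
  expect_equal(nodal_dice_scar(a, b), 2 * 6 / (8 + 8))
  expect_equal(nodal_dice_scar(a, b), nodal_dice_scar(b, a))
  expect_equal(nodal_dice_scar(a, a), 1)
  disj <- mk(c(rep(FALSE, 8), TRUE, TRUE))
  expect_equal(nodal_dice_scar(mk(c(rep(TRUE, 8), FALSE, FALSE)), disj), 0)
  none <- mk(rep(FALSE, 10))
  expect_warning(d0 <- nodal_dice_scar(none, none), "no scar")
  expect_equal(d0, 1)
  expect_error(nodal_dice_scar(surface_mesh(verts, tris), a), "scar_flag")
})

test_that("LV dimensions recover the analytic axes", {
  spec <- phantom_spec()
  inv <- make_invivo_phantom(spec)
  dims <- measure_lv_dimensions(inv$labels)
  expect_lt(abs(dims["long_axis_mm"] - spec$endo_semiaxes[[1]]),
            inv$labels$voxel)
  # short-axis diameter at 25% depth of the truncated ellipsoid
  z <- -0.25 * spec$endo_semiaxes[[1]]
  expected <- 2 * spec$endo_semiaxes[[2]] *
    sqrt(1 - (z / spec$endo_semiaxes[[1]])^2)
  expect_lt(abs(dims["short_axis_1_mm"] - expected), 2 * inv$labels$voxel)
  # axial symmetry of the phantom: the two principal diameters agree
  expect_lt(abs(dims["short_axis_1_mm"] / dims["short_axis_2_mm"] - 1), 0.02)
  noplane <- label_map(inv$labels$data, inv$labels$voxel, inv$labels$origin,
                       NULL)
  expect_error(measure_lv_dimensions(noplane), "MV plane")
})

test_that("the endocardial mesh lies inside the epicardial mesh", {
  pr <- coarse_pair()
  mor <- lv_morphometry(pr$inv$labels)
  # every endo node is closer to the cavity centroid than its paired epi node
  idx <- lvcoreg:::cpp_nn_index(mor$endo$vertices, mor$epi$vertices)
  cav <- which(cavity_mask(pr$inv$labels))
  d <- dim(pr$inv$labels$data)
  ijk <- cbind((cav - 1) %% d[1], ((cav - 1) %/% d[1]) %% d[2],
               (cav - 1) %/% (d[1] * d[2]))
  ctr <- colMeans(sweep(ijk * pr$inv$labels$voxel, 2, pr$inv$labels$origin, "+"))
  re <- sqrt(rowSums(sweep(mor$endo$vertices, 2, ctr)^2))
  rp <- sqrt(rowSums(sweep(mor$epi$vertices[idx, ], 2, ctr)^2))
  expect_gt(mean(rp > re), 0.995)
  at <- mor$endo$attributes
  expect_true(all(at$transmurality >= 0 & at$transmurality <= 1))
  expect_true(all(at$thickness_mm >= 0))
})

test_that("node transmurality tracks the generator's ground truth", {
  pr <- coarse_pair()
  mor <- lv_morphometry(pr$inv$labels)
  gt <- ground_truth_transmurality(coarse_spec(), mor$endo$vertices)
  mae <- mean(abs(gt - mor$endo$attributes$transmurality))
  expect_lt(mae, 0.1)
})
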