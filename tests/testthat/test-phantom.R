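# phantom generator: geometry, ground-truth deformation, determinism

test_that("wall volume matches an independent shell-volume estimate", {
  spec <- phantom_spec()
  inv <- make_invivo_phantom(spec)
  vol_gen <- compartment_volumes(inv$labels)$wall_ml * 1000  # mm^3
  # independent oracle: distance to the endocardial surface measured against
  # a dense surface point cloud (no foot-point solver involved), Monte-Carlo
  # volume over the bounding box
  al <- spec$endo_semiaxes[[1]]; as_ <- spec$endo_semiaxes[[2]]
  th <- rep(seq(0, pi, length.out = 700), times = 1400)
  ph <- rep(seq(0, 2 * pi, length.out = 1400), each = 700)
  cloud <- cbind(as_ * sin(th) * cos(ph), as_ * sin(th) * sin(ph),
                 al * cos(th))
  set.seed(42)
  n <- 3e5
  box_lo <- c(-40, -40, -75); box_hi <- c(40, 40, 5)
  mc <- cbind(runif(n, box_lo[1], box_hi[1]), runif(n, box_lo[2], box_hi[2]),
              runif(n, box_lo[3], box_hi[3]))
  inside_endo <- (mc[, 1] / as_)^2 + (mc[, 2] / as_)^2 + (mc[, 3] / al)^2 <= 1
  nn <- lvcoreg:::cpp_nn_index(mc, cloud)
  d <- sqrt(rowSums((cloud[nn, ] - mc)^2))
  in_wall <- !inside_endo & d <= spec$wall_thickness & mc[, 3] <= 0
  vol_mc <- prod(box_hi - box_lo) * mean(in_wall)
  expect_lt(abs(vol_gen - vol_mc) / vol_mc, 0.02)
})

test_that("zero angular extent produces no scar and profile values are exact", {
  spec0 <- coarse_spec(scar_angular_extent = 0)
  inv0 <- make_invivo_phantom(spec0)
  expect_equal(sum(scar_mask(inv0$labels)), 0)

  spec <- phantom_spec()
  al <- spec$endo_semiaxes[[1]]; as_ <- spec$endo_semiaxes[[2]]
  endo_pt <- function(phi_deg, z) {
    r <- as_ * sqrt(1 - (z / al)^2)
    c(r * cos(phi_deg * pi / 180), r * sin(phi_deg * pi / 180), z)
  }
  # scar core (inside the first 65% of the 90-degree sector)
  expect_equal(ground_truth_transmurality(spec, endo_pt(50, -30)), 1.0)
  # scar rim (outer 35% of the sector)
  expect_equal(ground_truth_transmurality(spec, endo_pt(115, -30)), 0.5)
  # healthy sector
  expect_equal(ground_truth_transmurality(spec, endo_pt(200, -30)), 0.0)
  # above the MV truncation
  expect_error(ground_truth_transmurality(spec, c(0, 25, 10)),
               "outside MV truncation")
})

test_that("ex-vivo pair encodes the imposed cavity scaling", {
  pr <- coarse_pair()
  vin <- compartment_volumes(pr$inv$labels)
  vex <- compartment_volumes(pr$ex$labels)
  spec <- coarse_spec()
  imposed <- spec$long_axis_ratio * spec$short_axis_ratio^2
  expect_lt(abs(vex$cavity_ml / vin$cavity_ml - imposed) / imposed, 0.02)
})

test_that("identity warp reproduces the in-vivo membership on the fine grid", {
  sp1 <- coarse_spec(long_axis_ratio = 1, short_axis_ratio = 1,
                     thick_mult_healthy = 1, thick_mult_low = 1,
                     thick_mult_high = 1)
  inv1 <- make_invivo_phantom(sp1)
  ex1 <- make_exvivo_pair(sp1, inv1$labels)
  g <- list(dim = dim(ex1$labels$data), origin = ex1$labels$origin,
            voxel = ex1$labels$voxel)
  pts <- lvcoreg:::grid_centers(g$dim, g$origin, g$voxel)
  direct <- lvcoreg:::cpp_phantom_labels(pts, lvcoreg:::phantom_pars(sp1),
                                         FALSE)$label
  expect_identical(as.integer(ex1$labels$data), as.integer(direct))
  # membership-resampling volume conservation
  vin <- compartment_volumes(inv1$labels)$wall_ml
  vex <- compartment_volumes(ex1$labels)$wall_ml
  expect_lt(abs(vex - vin) / vin, 0.01)
})

test_that("decreasing the short-axis ratio strictly shrinks the cavity", {
  vols <- vapply(c(0.9, 0.8, 0.7), function(s) {
    sp <- coarse_spec(short_axis_ratio = s)
    inv <- make_invivo_phantom(sp)
    compartment_volumes(make_exvivo_pair(sp, inv$labels)$labels)$cavity_ml
  }, numeric(1))
  expect_true(all(diff(vols) < 0))
})

test_that("generation is deterministic given the seed", {
  sp <- coarse_spec(seed = 11)
  a <- make_invivo_phantom(sp)
  b <- make_invivo_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$data, b$labels$data)
  exa <- make_exvivo_pair(sp, a$labels)
  exb <- make_exvivo_pair(sp, b$labels)
  expect_identical(exa$volume$data, exb$volume$data)
})

test_that("the ground-truth warp has positive Jacobian throughout the wall", {
  pr <- coarse_pair()
  field <- pr$ex$field
  set.seed(2)
  n <- 1e5
  pts <- cbind(runif(n, -35, 35), runif(n, -35, 35), runif(n, -70, 0))
  h <- 1e-3
  f0 <- deformation_apply(field, pts)
  J <- array(NA_real_, c(n, 3, 3))
  for (d in 1:3) {
    dp <- pts
    dp[, d] <- dp[, d] + h
    J[, , d] <- (deformation_apply(field, dp) - f0) / h
  }
  dets <- J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
    J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
    J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
  expect_gt(min(dets), 0)
})

test_that("forward and inverse analytic maps are mutually consistent", {
  pr <- coarse_pair()
  set.seed(4)
  pts <- cbind(runif(2000, -30, 30), runif(2000, -30, 30),
               runif(2000, -65, -2))
  fwd <- deformation_apply(pr$ex$field, pts)
  back <- deformation_apply(pr$ex$field, fwd, inverse = TRUE)
  expect_lt(max(abs(back - pts)), 1e-5)
})

test_that("in-vivo labels warped through the ground-truth field match ex-vivo", {
  pr <- coarse_pair()
  warped <- apply_deformation_field(pr$inv$labels, pr$ex$field, pr$ex$labels)
  expect_gt(voxel_dice(wall_mask(warped), wall_mask(pr$ex$labels)), 0.95)
})

test_that("invalid specifications are rejected", {
  expect_error(make_invivo_phantom(phantom_spec(wall_thickness = 2)),
               "unresolvable wall")
  expect_error(phantom_spec(long_axis_ratio = 1.4), "ratios")
  expect_error(phantom_spec(thick_mult_low = -1), "positive")
  expect_error(phantom_spec(exvivo_voxel = 2, invivo_voxel = 1), "exceed")
  sp <- coarse_spec(thick_mult_high = 0.05)
  inv <- make_invivo_phantom(sp)
  expect_error(make_exvivo_pair(sp, inv$labels), "collapses")
})

test_that("replicate jitter perturbs geometry but preserves imposed ratios", {
  sp <- jitter_phantom_spec(phantom_spec(), seed = 5)
  expect_false(isTRUE(all.equal(sp$endo_semiaxes,
                                phantom_spec()$endo_semiaxes)))
  expect_equal(sp$long_axis_ratio, 0.83)
  expect_equal(sp$short_axis_ratio, 0.81)
  expect_true(all(abs(sp$endo_semiaxes / phantom_spec()$endo_semiaxes - 1) <= 0.1))
})
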