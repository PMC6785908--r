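# landmark fit, transform algebra, rigid/affine/FFD registration

test_that("identical landmark sets give the identity with zero residual", {
  lm <- random_landmarks(5)
  tr <- fit_rigid_landmarks(lm, lm)
  expect_equal(tr$A, diag(3), tolerance = 1e-12)
  expect_equal(tr$b, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(attr(tr, "rms"), 1e-10)
})

test_that("a known rigid transform is recovered to machine precision", {
  lm <- random_landmarks(4)
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  p <- as.matrix(lm[, c("x", "y", "z")]) %*% t(R) +
    matrix(c(1, 2, 3), 4, 3, byrow = TRUE)
  moved <- landmark_set(data.frame(name = lm$name, x = p[, 1], y = p[, 2],
                                   z = p[, 3]))
  tr <- fit_rigid_landmarks(moved, lm)
  expect_lt(max(abs(tr$A - R)), 1e-9)
  expect_lt(max(abs(tr$b - c(1, 2, 3))), 1e-9)
})

test_that("landmark fit residual stays bounded under picking noise", {
  set.seed(10)
  rms <- replicate(100, {
    lm <- landmark_set(data.frame(
      name = c("LM_bifurcation", "RCA_ostium", "LV_apex", "papillary_1",
               "papillary_2"),
      x = rnorm(5, 0, 30), y = rnorm(5, 0, 30), z = rnorm(5, 0, 30)))
    noisy <- lm
    noisy$x <- noisy$x + rnorm(5)
    noisy$y <- noisy$y + rnorm(5)
    noisy$z <- noisy$z + rnorm(5)
    attr(fit_rigid_landmarks(noisy, lm), "rms")
  })
  expect_lte(mean(rms), 2)
})

test_that("degenerate landmark input is rejected", {
  lm <- random_landmarks(5)
  expect_error(fit_rigid_landmarks(lm[1:2, ], lm), "at least 3")
  line <- landmark_set(data.frame(
    name = c("LM_bifurcation", "RCA_ostium", "LV_apex"),
    x = c(0, 1, 2), y = c(0, 2, 4), z = c(0, 3, 6)))
  expect_error(fit_rigid_landmarks(line, line), "rank deficient")
})

test_that("chain application equals the composed transform", {
  t1 <- rigid_transform(lvcoreg:::euler_rotation(c(0.1, -0.2, 0.3)), c(5, -2, 1))
  t2 <- affine_transform(diag(c(0.8, 0.9, 1.1)), c(-1, 4, 2))
  comp <- compose_transforms(t2, t1)
  set.seed(1)
  pts <- matrix(rnorm(300, 0, 40), ncol = 3)
  seq_app <- transform_points(t2, transform_points(t1, pts))
  expect_lt(max(abs(transform_points(comp, pts) - seq_app)), 1e-9)
  # FFD applies its stored affine plus the spline displacement
  lat0 <- c(-60, -60, -60)
  coef <- array(0, c(8, 8, 8, 3))
  coef[, , , 2] <- 1.5
  tf <- ffd_transform(comp$A, comp$b, lat0, 20, coef)
  got <- transform_points(tf, pts)
  expect_lt(max(abs(got - (transform_points(comp, pts) +
                             matrix(c(0, 1.5, 0), nrow(pts), 3, byrow = TRUE)))),
            1e-9)
  # round trip through inversion
  back <- transform_points(invert_transform(comp), transform_points(comp, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("bending energy vanishes for control fields sampled from an affine map", {
  n <- c(7, 6, 5)
  A <- matrix(c(1.1, 0.02, 0, -0.03, 0.95, 0.01, 0, 0.05, 1.02), 3, byrow = TRUE)
  b <- c(2, -1, 0.5)
  nodes <- lvcoreg:::grid_centers(n, c(-30, -30, -30), 10)
  disp <- nodes %*% t(A) + matrix(b, nrow(nodes), 3, byrow = TRUE) - nodes
  coef <- array(disp, c(n, 3))
  tf <- ffd_transform(diag(3), c(0, 0, 0), c(-30, -30, -30), 10, coef)
  expect_equal(bending_energy(tf), 0, tolerance = 1e-18)
  coef[4, 3, 2, 1] <- coef[4, 3, 2, 1] + 1
  expect_gt(bending_energy(ffd_transform(diag(3), c(0, 0, 0),
                                         c(-30, -30, -30), 10, coef)), 0)
})

test_that("identity resampling returns labels bit-identically", {
  lm <- coarse_invivo()$labels
  out <- apply_transform(lm, rigid_transform(), lm)
  expect_identical(out$data, lm$data)
})

test_that("a one-voxel translation shifts labels and preserves interior volume", {
  lab <- array(0L, c(7, 7, 7))
  lab[2:6, 2:6, 2:6] <- 1L
  lm <- label_map(lab, 1)
  tr <- rigid_transform(diag(3), c(1, 0, 0))  # sample source at x+1
  out <- apply_transform(lm, tr, lm)
  expect_identical(out$data[1:5, , ], lm$data[2:6, , ])
  expect_equal(sum(out$data == 1L), sum(lab == 1L))
})

test_that("rigid registration of a map to itself stays at the identity", {
  fx <- coarse_invivo()$labels
  tr <- register_rigid(fx, fx, rigid_transform(), coarse_reg_cfg())
  expect_lt(max(abs(tr$A - diag(3))), 1e-3)
  expect_lt(max(abs(tr$b)), 0.1)
  m <- attr(tr, "metric")
  expect_lte(m["final"], m["init"])
  reg <- apply_transform(fx, tr, fx)
  expect_equal(voxel_dice(wall_mask(fx), wall_mask(reg)), 1, tolerance = 1e-3)
})

test_that("a known rigid displacement is recovered within half a voxel", {
  fx <- coarse_invivo()$labels
  known <- rigid_transform(lvcoreg:::euler_rotation(c(0.05, -0.04, 0.08)),
                           c(3, -2.5, 2))
  moving <- warp_labels(fx, function(p) transform_points(known, p))
  # moving(x) = fixed(known(x)); registration recovers the inverse of `known`
  tr <- register_rigid(fx, moving, rigid_transform(), coarse_reg_cfg())
  expected <- invert_transform(known)
  g <- lvcoreg:::grid_geom(fx)
  pts <- lvcoreg:::grid_centers(g$dim, g$origin, g$voxel)
  wp <- pts[which(wall_mask(fx)), ]
  err <- sqrt(rowSums((transform_points(tr, wp) -
                         transform_points(expected, wp))^2))
  expect_lt(mean(err), 0.5 * fx$voxel)
})

test_that("affine registration recovers a known anisotropic scaling within 2%", {
  fx <- coarse_invivo()$labels
  g <- lvcoreg:::grid_geom(fx)
  ctr <- g$origin + (g$dim - 1) * g$voxel / 2
  S <- diag(c(0.8, 0.8, 0.9))
  known <- affine_transform(S, as.numeric(ctr - S %*% ctr))
  moving <- warp_labels(fx, function(p) transform_points(known, p))
  tr <- register_affine(fx, moving, rigid_transform(), coarse_reg_cfg())
  expected <- invert_transform(known)
  expect_lt(max(abs(diag(tr$A) / diag(expected$A) - 1)), 0.02)
  m <- attr(tr, "metric")
  expect_lte(m["final"], m["init"])
})

test_that("FFD registration of a map to itself leaves the lattice still", {
  fx <- coarse_invivo()$labels
  tf <- register_ffd(fx, fx, affine_transform(), coarse_reg_cfg())
  expect_lt(max(abs(tf$coef)), 0.1)
})

test_that("FFD recovers random representable warps within one fixed voxel", {
  fx <- coarse_invivo()$labels
  g <- lvcoreg:::grid_geom(fx)
  pts <- lvcoreg:::grid_centers(g$dim, g$origin, g$voxel)
  wp <- pts[which(wall_mask(fx)), ]
  errs <- vapply(1:3, function(s) {
    set.seed(s)
    lat <- lvcoreg:::ffd_lattice(fx, 20)
    coef <- array(rnorm(prod(lat$n) * 3, 0, 4), c(lat$n, 3))
    wtr <- ffd_transform(diag(3), c(0, 0, 0), lat$lat0, 20, coef)
    moving <- warp_labels(fx, function(p) transform_points(wtr, p))
    tf <- register_ffd(fx, moving, affine_transform(), coarse_reg_cfg())
    # recovered transform composed with the true warp must be the identity
    comp <- transform_points(wtr, transform_points(tf, wp))
    mean(sqrt(rowSums((comp - wp)^2)))
  }, numeric(1))
  expect_lt(mean(errs), fx$voxel)
})

test_that("a smooth sinusoidal warp is recovered to high wall overlap", {
  fx <- coarse_invivo()$labels
  warp <- function(p) p + cbind(3 * sin(2 * pi * p[, 3] / 40),
                                3 * sin(2 * pi * p[, 1] / 40),
                                3 * sin(2 * pi * p[, 2] / 40))
  moving <- warp_labels(fx, warp)
  tf <- register_ffd(fx, moving, affine_transform(), coarse_reg_cfg())
  reg <- apply_transform(moving, tf, fx)
  expect_gte(voxel_dice(wall_mask(fx), wall_mask(reg)), 0.95)
  tr <- attr(tf, "metric_trace")
  expect_lte(tr[length(tr)], tr[1])
})

test_that("disjoint bounding boxes after initialisation raise an error", {
  fx <- coarse_invivo()$labels
  far <- rigid_transform(diag(3), c(500, 500, 500))
  expect_error(register_rigid(fx, fx, far, coarse_reg_cfg()), "overlap")
})
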