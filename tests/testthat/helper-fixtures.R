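# shared fixtures, memoised across test files (built once per test run)

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# coarse phantom (2.4 / 1.2 mm voxels) for fast unit tests
coarse_spec <- function(seed = 3, ...) {
  phantom_spec(invivo_voxel = 2.4, exvivo_voxel = 1.2, margin_mm = 5,
               seed = seed, ...)
}

coarse_invivo <- function() {
  memo_fixture("coarse_invivo", function() make_invivo_phantom(coarse_spec()))
}

coarse_pair <- function() {
  memo_fixture("coarse_pair", function() {
    inv <- coarse_invivo()
    list(inv = inv, ex = make_exvivo_pair(coarse_spec(), inv$labels))
  })
}

# light registration settings matched to the coarse grid
coarse_reg_cfg <- function() {
  registration_config(levels = c(20, 10, 5), pyramid = c(2, 2, 1),
                      maxit = c(40, 40, 40), rigid_pyramid = c(2, 1),
                      rigid_maxit = 60)
}

# full-resolution default pair (1.2 / 0.4 mm) with segmentation and the
# complete registration chain; the expensive acceptance fixture
default_run <- function() {
  memo_fixture("default_run", function() {
    lvcoreg:::replicate_analysis(phantom_spec(seed = 1),
                                 segmentation_params(),
                                 registration_config(),
                                 run_registration = TRUE)
  })
}

# digital spherical shell label map (cavity r < r_endo, wall to r_epi)
sphere_shell <- function(r_endo = 20, r_epi = 30, voxel = 1,
                         plane_z = r_epi + 5) {
  ext <- r_epi + 5
  xs <- seq(-ext, ext, by = voxel)
  n <- length(xs)
  r <- sqrt(outer(outer(xs^2, xs^2, "+"), xs^2, "+"))
  lab <- array(0L, c(n, n, n))
  lab[r < r_endo] <- 2L
  lab[r >= r_endo & r <= r_epi] <- 1L
  label_map(lab, voxel, c(-ext, -ext, -ext),
            mv_plane = list(point = c(0, 0, plane_z), normal = c(0, 0, 1)))
}

# moving image = fixed labels resampled through a known point map
warp_labels <- function(fixed, map_fun) {
  g <- list(dim = dim(fixed$data), origin = fixed$origin, voxel = fixed$voxel)
  pts <- lvcoreg:::grid_centers(g$dim, g$origin, g$voxel)
  lab <- lvcoreg:::cpp_label_resample(fixed$data, fixed$origin, fixed$voxel,
                                      map_fun(pts), c(3L, 2L, 1L, 4L, 0L))
  dim(lab) <- g$dim
  label_map(lab, fixed$voxel, fixed$origin, fixed$mv_plane)
}

random_landmarks <- function(n = 4, seed = 1) {
  set.seed(seed)
  landmark_set(data.frame(
    name = c("LM_bifurcation", "RCA_ostium", "LV_apex", "papillary_1",
             "papillary_2")[seq_len(n)],
    x = rnorm(n, 0, 20), y = rnorm(n, 0, 20), z = rnorm(n, 0, 20)))
}
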