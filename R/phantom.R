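#' Parameterisation of the paired in-vivo / ex-vivo LV phantom
#'
#' The phantom models the left ventricle as a truncated thick-walled
#' ellipsoid with an antero-septal scar sector, imaged twice: in vivo
#' (loaded, 1.2 mm voxels) and ex vivo (excised and unloaded, 0.4 mm
#' voxels). The ex-vivo shape change is an analytic deformation: the
#' endocardial surface is scaled anisotropically about the cavity centroid
#' (long-axis ratio 0.83, short-axis ratio 0.81) and the local wall
#' thickness is multiplied by a region factor selected by scar
#' transmurality (healthy x1.29, 0-50% transmural x1.05, 50-100%
#' transmural x0.98), blended smoothly across region borders. Because the
#' deformation is built from cavity scaling plus normal-direction thickness
#' scaling of a convex surface, its inverse is analytic and ex-vivo labels
#' are computed by exact geometric membership of the inverse-mapped point
#' (no label interpolation).
#'
#' @param endo_semiaxes in-vivo endocardial semiaxes, mm, `c(long, short)`
#'   (the two short axes are equal).
#' @param wall_thickness uniform in-vivo wall thickness, mm.
#' @param mv_plane_offset z position (mm) of the mitral-valve truncation
#'   plane relative to the ellipsoid centre; 0 truncates at the equator so
#'   the cavity long axis equals the long semiaxis.
#' @param scar_angle_start,scar_angular_extent angular placement of the
#'   antero-septal scar sector, degrees.
#' @param scar_long_extent fraction of the long axis covered by scar.
#' @param scar_transmural_profile `list(core, rim, core_fraction)`:
#'   transmurality of the scar core and rim, and the fraction of the
#'   angular extent occupied by the core (the rim is the remaining band).
#' @param long_axis_ratio,short_axis_ratio ex-vivo/in-vivo cavity scale.
#' @param thick_mult_healthy,thick_mult_low,thick_mult_high wall-thickness
#'   multipliers for healthy, 0-50% and 50-100% transmural regions.
#' @param blend_band_mm width (mm) of the smoothstep transition of the
#'   thickness multiplier across region borders.
#' @param blend_offset_mm outward shift (mm) of the transition centre into
#'   the lower-transmurality side, so plateau multipliers hold up to the
#'   scar border.
#' @param invivo_voxel,exvivo_voxel isotropic voxel sizes, mm.
#' @param intensity per-condition intensity model: named means (and
#'   optionally `sds`) per compartment. Default SDs are 5% of the
#'   wall-scar contrast of the condition.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param psf_fwhm_mm full-width-at-half-maximum of the acquisition
#'   point-spread function emulated by Gaussian blurring of the intensity
#'   image (labels are never blurred).
#' @param papillary add two papillary-muscle bumps on the endocardium.
#' @param landmark_noise_sd SD (mm) of landmark picking error; 0 disables.
#' @param margin_mm padding of the generated grids around the anatomy.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return a validated object of class `phantom_spec`.
#' @export
phantom_spec <- function(endo_semiaxes = c(long = 60, short = 25),
                         wall_thickness = 9.95,
                         mv_plane_offset = 0,
                         scar_angle_start = 30,
                         scar_angular_extent = 90,
                         scar_long_extent = 0.4,
                         scar_transmural_profile = list(core = 1, rim = 0.5,
                                                        core_fraction = 0.65),
                         long_axis_ratio = 0.83,
                         short_axis_ratio = 0.81,
                         thick_mult_healthy = 1.29,
                         thick_mult_low = 1.05,
                         thick_mult_high = 0.98,
                         blend_band_mm = 2,
                         blend_offset_mm = 1.5,
                         invivo_voxel = 1.2,
                         exvivo_voxel = 0.4,
                         intensity = NULL,
                         noise_model = c("gaussian", "rician"),
                         psf_fwhm_mm = 0.8,
                         papillary = FALSE,
                         landmark_noise_sd = 0,
                         margin_mm = 6,
                         seed = 1L) {
  spec <- list(
    endo_semiaxes = endo_semiaxes, wall_thickness = wall_thickness,
    mv_plane_offset = mv_plane_offset, scar_angle_start = scar_angle_start,
    scar_angular_extent = scar_angular_extent,
    scar_long_extent = scar_long_extent,
    scar_transmural_profile = scar_transmural_profile,
    long_axis_ratio = long_axis_ratio, short_axis_ratio = short_axis_ratio,
    thick_mult_healthy = thick_mult_healthy, thick_mult_low = thick_mult_low,
    thick_mult_high = thick_mult_high,
    blend_band_mm = blend_band_mm, blend_offset_mm = blend_offset_mm,
    invivo_voxel = invivo_voxel, exvivo_voxel = exvivo_voxel,
    intensity = intensity %||% default_intensity_model(),
    noise_model = match.arg(noise_model), psf_fwhm_mm = psf_fwhm_mm,
    papillary = papillary, landmark_noise_sd = landmark_noise_sd,
    margin_mm = margin_mm, seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

default_intensity_model <- function() {
  list(
    invivo = list(means = c(background = 5, myocardium = 30, cavity = 100,
                            scar = 150, aorta = 100), sds = NULL),
    exvivo = list(means = c(background = 150, myocardium = 40, cavity = 150,
                            scar = 160, aorta = 150), sds = NULL)
  )
}

validate_phantom_spec <- function(spec) {
  s <- spec
  stopifnot(length(s$endo_semiaxes) == 2, all(s$endo_semiaxes > 0),
            s$wall_thickness > 0, s$invivo_voxel > 0, s$exvivo_voxel > 0)
  if (s$exvivo_voxel > s$invivo_voxel)
    stop("exvivo_voxel must not exceed invivo_voxel")
  if (!(s$long_axis_ratio > 0 && s$long_axis_ratio <= 1) ||
      !(s$short_axis_ratio > 0 && s$short_axis_ratio <= 1))
    stop("axis ratios must lie in (0, 1]")
  if (any(c(s$thick_mult_healthy, s$thick_mult_low, s$thick_mult_high) <= 0))
    stop("thickness multipliers must be positive")
  pr <- s$scar_transmural_profile
  if (any(c(pr$core, pr$rim) < 0) || any(c(pr$core, pr$rim) > 1))
    stop("transmurality values must lie in [0, 1]")
  stopifnot(pr$core_fraction >= 0, pr$core_fraction <= 1,
            s$scar_angular_extent >= 0, s$scar_long_extent >= 0,
            s$scar_long_extent <= 1, s$blend_band_mm > 0)
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> LV endo %g x %g mm, wall %.2f mm; scar %g deg x %.0f%% long axis\n",
    x$endo_semiaxes[[1]], x$endo_semiaxes[[2]], x$wall_thickness,
    x$scar_angular_extent, 100 * x$scar_long_extent))
  cat(sprintf("  ex/in ratios: long %.2f short %.2f; thickness x(%.2f, %.2f, %.2f)\n",
              x$long_axis_ratio, x$short_axis_ratio, x$thick_mult_healthy,
              x$thick_mult_low, x$thick_mult_high))
  cat(sprintf("  voxels: in-vivo %.2f mm, ex-vivo %.2f mm; seed %d\n",
              x$invivo_voxel, x$exvivo_voxel, x$seed))
  invisible(x)
}

# centroid (z) of the truncated ellipsoidal cavity; the scaling centre
cavity_centroid_z <- function(spec) {
  al <- spec$endo_semiaxes[[1]]
  u0 <- min(1, spec$mv_plane_offset / al)
  num <- (u0^2 / 2 - u0^4 / 4) - (1 / 2 - 1 / 4)
  den <- (u0 - u0^3 / 3) + 2 / 3
  al * num / den
}

# parameter pack consumed by the C++ geometry kernel
phantom_pars <- function(spec, identity_warp = FALSE) {
  al <- spec$endo_semiaxes[[1]]
  as <- spec$endo_semiaxes[[2]]
  zmv <- spec$mv_plane_offset
  long_axis <- al + zmv  # apex at z = -al, base plane at z = zmv
  zmid <- (zmv - al) / 2
  half <- spec$scar_long_extent * long_axis / 2
  pr <- spec$scar_transmural_profile
  S <- if (identity_warp) c(1, 1, 1)
       else c(spec$short_axis_ratio, spec$short_axis_ratio, spec$long_axis_ratio)
  m <- if (identity_warp) c(1, 1, 1)
       else c(spec$thick_mult_healthy, spec$thick_mult_low, spec$thick_mult_high)
  list(
    a = c(as, as, al), t = spec$wall_thickness, zmv = zmv,
    phi0 = spec$scar_angle_start * pi / 180,
    phiw = spec$scar_angular_extent * pi / 180,
    phicw = spec$scar_angular_extent * pr$core_fraction * pi / 180,
    zlo = zmid - half, zhi = zmid + half,
    tau_core = pr$core, tau_rim = pr$rim,
    band = spec$blend_band_mm, offset = spec$blend_offset_mm,
    m_h = m[1], m_l = m[2], m_hh = m[3],
    S = S, cz = cavity_centroid_z(spec)
  )
}

phantom_intensity <- function(labels, spec, condition) {
  mod <- spec$intensity[[condition]]
  means <- mod$means[names(LBL)]
  sds <- mod$sds
  if (is.null(sds)) {
    contrast <- abs(mod$means[["scar"]] - mod$means[["myocardium"]])
    sds <- setNames(rep(0.05 * contrast, length(LBL)), names(LBL))
  } else {
    sds <- sds[names(LBL)]
  }
  img <- means[labels$data + 1L]
  n <- length(img)
  sd_vox <- sds[labels$data + 1L]
  if (spec$noise_model == "gaussian") {
    img <- img + rnorm(n) * sd_vox
  } else {
    img <- sqrt((img + rnorm(n) * sd_vox)^2 + (rnorm(n) * sd_vox)^2)
  }
  dim(img) <- dim(labels$data)
  if (spec$psf_fwhm_mm > 0) {
    sig_vox <- spec$psf_fwhm_mm / (2 * sqrt(2 * log(2))) / labels$voxel
    img <- cpp_gaussian_smooth(img, sig_vox)
  }
  volume3d(img, labels$voxel, labels$origin, labels$mv_plane)
}

# analytic anatomical landmark positions (world mm, in-vivo condition)
phantom_landmark_base <- function(spec) {
  al <- spec$endo_semiaxes[[1]]
  as <- spec$endo_semiaxes[[2]]
  t <- spec$wall_thickness
  zmv <- spec$mv_plane_offset
  data.frame(
    name = c("LM_bifurcation", "RCA_ostium", "LV_apex", "papillary_1",
             "papillary_2"),
    x = c(-0.6 * as, 0.72 * as, 0, 0.48 * as, -0.40 * as),
    y = c(0.8 * as, -0.6 * as, 0, 0.32 * as, -0.48 * as),
    z = c(zmv + 2, zmv + 1, -(al + t), -25, -30),
    stringsAsFactors = FALSE
  )
}

apply_landmark_noise <- function(lm, sd) {
  if (sd > 0) {
    lm$x <- lm$x + rnorm(nrow(lm), 0, sd)
    lm$y <- lm$y + rnorm(nrow(lm), 0, sd)
    lm$z <- lm$z + rnorm(nrow(lm), 0, sd)
  }
  landmark_set(lm)
}

add_papillary <- function(lab_arr, pts_invivo, spec) {
  al <- spec$endo_semiaxes[[1]]
  as <- spec$endo_semiaxes[[2]]
  for (ang in c(200, 250) * pi / 180) {
    z0 <- -25
    r0 <- as * sqrt(1 - (z0 / al)^2)
    ctr <- c(r0 * cos(ang), r0 * sin(ang), z0)
    d2 <- (pts_invivo[, 1] - ctr[1])^2 + (pts_invivo[, 2] - ctr[2])^2 +
      (pts_invivo[, 3] - ctr[3])^2
    sel <- d2 <= 16 & lab_arr == LBL[["cavity"]]
    lab_arr[sel] <- LBL[["myocardium"]]
  }
  lab_arr
}

#' Generate the in-vivo phantom
#'
#' Builds the in-vivo LGE-like volume, its ground-truth label map and the
#' anatomical landmark set on an isotropic grid of `spec$invivo_voxel` mm.
#'
#' @param spec a [phantom_spec()].
#' @return `list(volume, labels, landmarks)`.
#' @export
make_invivo_phantom <- function(spec) {
  validate_phantom_spec(spec)
  if (spec$wall_thickness < 2 * spec$invivo_voxel) stop("unresolvable wall")
  al <- spec$endo_semiaxes[[1]]
  as <- spec$endo_semiaxes[[2]]
  t <- spec$wall_thickness
  m <- spec$margin_mm
  v <- spec$invivo_voxel
  lo <- c(-(as + t + m), -(as + t + m), -(al + t + m))
  hi <- c(as + t + m, as + t + m, spec$mv_plane_offset + m)
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / v)))
  origin <- lo + v / 2
  pts <- grid_centers(dims, origin, v)
  pars <- phantom_pars(spec)
  res <- cpp_phantom_labels(pts, pars, FALSE)
  lab <- res$label
  if (spec$papillary) lab <- add_papillary(lab, pts, spec)
  dim(lab) <- dims
  mv <- list(point = c(0, 0, spec$mv_plane_offset), normal = c(0, 0, 1))
  labels <- label_map(lab, v, origin, mv)
  vol <- with_seed(spec$seed, phantom_intensity(labels, spec, "invivo"))
  lms <- with_seed(spec$seed + 17L,
                   apply_landmark_noise(phantom_landmark_base(spec),
                                        spec$landmark_noise_sd))
  list(volume = vol, labels = labels, landmarks = lms)
}

#' Generate the paired ex-vivo phantom and the ground-truth deformation
#'
#' Applies the analytic in-vivo to ex-vivo shape change (cavity scaling
#' about the centroid plus transmurality-dependent wall-thickness scaling)
#' and renders the result on the finer ex-vivo grid by evaluating the
#' analytic inverse map at every ex-vivo voxel centre (exact membership, no
#' label interpolation). Landmarks are transported through the forward map.
#'
#' @param spec a [phantom_spec()].
#' @param invivo_labels the in-vivo label map (defines the grid on which the
#'   dense ground-truth displacement field is sampled).
#' @return `list(volume, labels, landmarks, field)` where `field` is a
#'   `deformation_field`.
#' @export
make_exvivo_pair <- function(spec, invivo_labels) {
  validate_phantom_spec(spec)
  stopifnot(inherits(invivo_labels, "lv_labelmap"))
  mmin <- min(spec$thick_mult_healthy, spec$thick_mult_low, spec$thick_mult_high)
  if (mmin * spec$wall_thickness < 2 * spec$exvivo_voxel)
    stop("thickness multiplier collapses wall below the ex-vivo resolution")
  al <- spec$endo_semiaxes[[1]]
  as <- spec$endo_semiaxes[[2]]
  t <- spec$wall_thickness
  mmax <- max(spec$thick_mult_healthy, spec$thick_mult_low, spec$thick_mult_high)
  marg <- spec$margin_mm
  v <- spec$exvivo_voxel
  cz <- cavity_centroid_z(spec)
  sl <- spec$long_axis_ratio
  ss <- spec$short_axis_ratio
  zmv_ex <- cz + sl * (spec$mv_plane_offset - cz)
  apex_ex <- cz + sl * (-al - cz)
  lo <- c(-(ss * as + mmax * t + marg), -(ss * as + mmax * t + marg),
          apex_ex - mmax * t - marg)
  hi <- c(ss * as + mmax * t + marg, ss * as + mmax * t + marg, zmv_ex + marg)
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / v)))
  origin <- lo + v / 2
  pts <- grid_centers(dims, origin, v)
  pars <- phantom_pars(spec)
  res <- cpp_phantom_labels(pts, pars, TRUE)
  lab <- res$label
  if (spec$papillary) {
    pin <- cpp_phantom_map(pts, pars, TRUE)
    lab <- add_papillary(lab, pin, spec)
  }
  dim(lab) <- dims
  mv <- list(point = c(0, 0, zmv_ex), normal = c(0, 0, 1))
  labels <- label_map(lab, v, origin, mv)
  vol <- with_seed(spec$seed + 500000L,
                   phantom_intensity(labels, spec, "exvivo"))
  base <- phantom_landmark_base(spec)
  fwd <- cpp_phantom_map(as.matrix(base[, c("x", "y", "z")]), pars, FALSE)
  base$x <- fwd[, 1]; base$y <- fwd[, 2]; base$z <- fwd[, 3]
  lms <- with_seed(spec$seed + 23L,
                   apply_landmark_noise(base, spec$landmark_noise_sd))
  field <- deformation_field(spec, invivo_labels)
  list(volume = vol, labels = labels, landmarks = lms, field = field)
}

#' Ground-truth deformation field of the phantom pair
#'
#' Dense world-space displacement (mm) sampled at every voxel centre of the
#' in-vivo grid, mapping in-vivo points to their ex-vivo positions; the
#' object also carries the analytic map so the exact forward and inverse
#' transforms can be evaluated at arbitrary points via
#' [deformation_apply()].
#'
#' @param spec a [phantom_spec()].
#' @param invivo_labels in-vivo label map providing the sampling grid.
#' @return object of class `deformation_field` with elements `disp`
#'   (4D array, last dimension xyz), `origin`, `voxel`, `pars`.
#' @export
deformation_field <- function(spec, invivo_labels) {
  g <- grid_geom(invivo_labels)
  pts <- grid_centers(g$dim, g$origin, g$voxel)
  pars <- phantom_pars(spec)
  fwd <- cpp_phantom_map(pts, pars, FALSE)
  disp <- fwd - pts
  dim(disp) <- c(g$dim, 3)
  structure(list(disp = disp, origin = g$origin, voxel = g$voxel, pars = pars),
            class = "deformation_field")
}

#' Evaluate the analytic phantom deformation at arbitrary points
#'
#' @param field a `deformation_field`.
#' @param pts N x 3 matrix of world points (mm).
#' @param inverse evaluate the analytic inverse (ex-vivo to in-vivo) map.
#' @return N x 3 matrix of mapped points.
#' @export
deformation_apply <- function(field, pts, inverse = FALSE) {
  stopifnot(inherits(field, "deformation_field"))
  cpp_phantom_map(as_point_matrix(pts), field$pars, inverse)
}

#' Resample a volume or label map through the ground-truth deformation
#'
#' Pushes each target-grid voxel centre through the analytic map (the
#' inverse map when resampling in-vivo data onto the ex-vivo grid, the
#' forward map for the opposite direction) and samples the source there
#' (labels: indicator argmax with priority ties; scalars: trilinear).
#'
#' @param source `lv_volume` or `lv_labelmap` to resample.
#' @param field a `deformation_field`.
#' @param target target grid (`lv_volume`/`lv_labelmap` or
#'   `list(dim, origin, voxel)`).
#' @param direction `"inverse"` (default; target is ex-vivo space) or
#'   `"forward"`.
#' @return resampled object on the target grid.
#' @export
apply_deformation_field <- function(source, field, target,
                                    direction = c("inverse", "forward")) {
  direction <- match.arg(direction)
  stopifnot(inherits(field, "deformation_field"))
  g <- if (is.list(target) && !inherits(target, "lv_volume")) target
       else grid_geom(target)
  pts <- grid_centers(g$dim, g$origin, g$voxel)
  y <- cpp_phantom_map(pts, field$pars, direction == "inverse")
  mv_plane <- if (inherits(target, "lv_volume")) target$mv_plane else source$mv_plane
  if (inherits(source, "lv_labelmap")) {
    lab <- cpp_label_resample(source$data, source$origin, source$voxel, y,
                              LABEL_PRIORITY)
    dim(lab) <- g$dim
    return(label_map(lab, g$voxel, g$origin, mv_plane))
  }
  vals <- cpp_trilinear(source$data, source$origin, source$voxel, y, 0)
  dim(vals) <- g$dim
  volume3d(vals, g$voxel, g$origin, mv_plane)
}

#' Ground-truth scar transmurality at endocardial points
#'
#' Looks up the phantom's transmural profile at the angular/longitudinal
#' position of the endocardial foot point of each query point. Points above
#' the mitral-valve truncation plane are rejected.
#'
#' @param spec a [phantom_spec()].
#' @param pts N x 3 matrix (or length-3 vector) of world points on or near
#'   the in-vivo endocardial surface.
#' @return numeric vector of transmurality values in `[0, 1]`.
#' @export
ground_truth_transmurality <- function(spec, pts) {
  validate_phantom_spec(spec)
  pts <- as_point_matrix(pts)
  if (any(pts[, 3] > spec$mv_plane_offset + 1e-9))
    stop("point outside MV truncation")
  cpp_phantom_tau_mult(pts, phantom_pars(spec))$tau
}

# ground-truth thickness multiplier at endocardial points (phantom oracle)
ground_truth_thickness_mult <- function(spec, pts) {
  cpp_phantom_tau_mult(as_point_matrix(pts), phantom_pars(spec))$mult
}

#' Per-replicate jitter of the phantom geometry
#'
#' Emulates inter-animal variability by scaling the semiaxes and scar
#' extents by independent uniform factors in `1 +/- 10%`. The imposed
#' ex/in ratios and thickness multipliers are untouched.
#'
#' @param spec a [phantom_spec()].
#' @param seed replicate seed (also becomes the spec's noise seed).
#' @return jittered `phantom_spec`.
#' @export
jitter_phantom_spec <- function(spec, seed) {
  with_seed(seed, {
    f <- runif(4, 0.9, 1.1)
    spec$endo_semiaxes <- spec$endo_semiaxes * f[1:2]
    spec$scar_angular_extent <- min(360, spec$scar_angular_extent * f[3])
    spec$scar_long_extent <- min(1, spec$scar_long_extent * f[4])
  })
  spec$seed <- as.integer(seed)
  validate_phantom_spec(spec)
  spec
}
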