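#' Spatial transforms
#'
#' Transforms map world coordinates of the fixed image space to the moving
#' image space (the resampling convention): to bring the moving image onto
#' the fixed grid, each fixed voxel centre is pushed through the transform
#' and the moving image is sampled there. The registration chain is
#' landmark-rigid, then image rigid, affine and finally a cubic B-spline
#' free-form deformation; an `ffd_transform` stores its initial affine and
#' applies `T(x) = A x + b + u(x)` with `u` the spline displacement.
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t length-3 translation, mm.
#' @return transform object.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("R must be a proper rotation")
  structure(list(A = R, b = as.numeric(t)),
            class = c("rigid_transform", "lv_transform"))
}

#' @rdname rigid_transform
#' @param A 3x3 invertible linear matrix.
#' @export
affine_transform <- function(A = diag(3), t = c(0, 0, 0)) {
  A <- as.matrix(A)
  stopifnot(all(dim(A) == c(3, 3)), length(t) == 3)
  if (abs(det(A)) < 1e-10) stop("affine matrix must be invertible")
  structure(list(A = A, b = as.numeric(t)),
            class = c("affine_transform", "lv_transform"))
}

#' @rdname rigid_transform
#' @param b translation of the initial affine part.
#' @param lat0 world position of lattice node (1,1,1).
#' @param spacing control-point spacing, mm.
#' @param coef 4D array `nx x ny x nz x 3` of control displacements (mm).
#' @export
ffd_transform <- function(A, b, lat0, spacing, coef) {
  stopifnot(length(dim(coef)) == 4, dim(coef)[4] == 3, all(is.finite(coef)))
  structure(list(A = as.matrix(A), b = as.numeric(b), lat0 = as.numeric(lat0),
                 spacing = spacing, coef = coef),
            class = c("ffd_transform", "lv_transform"))
}

#' @export
print.lv_transform <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  cat("A =\n"); print(round(x$A, 6))
  cat("b =", round(x$b, 6), "\n")
  if (inherits(x, "ffd_transform"))
    cat(sprintf("FFD lattice %s @ %g mm, max |u| = %.3f mm\n",
                paste(dim(x$coef)[1:3], collapse = "x"), x$spacing,
                max(abs(x$coef))))
  invisible(x)
}

#' Apply a transform to world points
#'
#' @param tr an `lv_transform`.
#' @param pts N x 3 matrix of world points.
#' @return N x 3 matrix of mapped points.
#' @export
transform_points <- function(tr, pts) {
  pts <- as_point_matrix(pts)
  if (inherits(tr, "ffd_transform"))
    return(cpp_transform_points(pts, tr$A, tr$b, tr$coef, tr$lat0, tr$spacing))
  cpp_transform_points(pts, tr$A, tr$b, NULL, c(0, 0, 0), 1)
}

#' Invert a rigid or affine transform
#' @param tr rigid or affine transform.
#' @return transform of the same class.
#' @export
invert_transform <- function(tr) {
  if (inherits(tr, "ffd_transform"))
    stop("FFD transforms have no closed-form inverse")
  Ai <- solve(tr$A)
  out <- list(A = Ai, b = as.numeric(-Ai %*% tr$b))
  class(out) <- class(tr)
  out
}

#' Compose two linear transforms: `(outer o inner)(x) = outer(inner(x))`
#' @param outer,inner rigid or affine transforms.
#' @return affine (or rigid, if both are rigid) transform.
#' @export
compose_transforms <- function(outer, inner) {
  stopifnot(!inherits(outer, "ffd_transform"), !inherits(inner, "ffd_transform"))
  A <- outer$A %*% inner$A
  b <- as.numeric(outer$A %*% inner$b + outer$b)
  if (inherits(outer, "rigid_transform") && inherits(inner, "rigid_transform"))
    rigid_transform(A, b)
  else affine_transform(A, b)
}

#' Least-squares rigid landmark registration
#'
#' Orthogonal Procrustes fit (centroid alignment + SVD with reflection
#' correction) over the landmark names shared by both sets, returning the
#' rigid transform mapping fixed-space points to moving-space points.
#'
#' @param moving,fixed [landmark_set()] data frames.
#' @return `rigid_transform` with attribute `rms` (residual RMS, mm).
#' @export
fit_rigid_landmarks <- function(moving, fixed) {
  shared <- intersect(moving$name, fixed$name)
  if (length(shared) < 3) stop("need at least 3 shared landmark names")
  X <- as.matrix(fixed[match(shared, fixed$name), c("x", "y", "z")])
  Y <- as.matrix(moving[match(shared, moving$name), c("x", "y", "z")])
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  sv <- svd(crossprod(Xc, Yc))  # H = Xc' Yc ; R = V D U'
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) stop("rank deficient")
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  t <- ym - as.numeric(R %*% xm)
  out <- rigid_transform(R, t)
  res <- Y - (X %*% t(R) + matrix(t, nrow(X), 3, byrow = TRUE))
  attr(out, "rms") <- sqrt(mean(rowSums(res^2)))
  out
}

#' Registration configuration
#'
#' The similarity metric is the sum of squared differences over
#' Gaussian-smoothed per-label indicator channels (wall, cavity, scar,
#' equal weights), normalised per fixed voxel. Multi-resolution pairs an
#' image pyramid with the control-point spacing schedule.
#'
#' @param metric_sigma Gaussian smoothing (mm) of the indicator channels.
#' @param levels FFD control-point spacings (mm), strictly decreasing.
#' @param pyramid image downsampling factors paired with `levels`.
#' @param lambda bending-energy weight (per-voxel-normalised metric scale).
#' @param maxit optimiser iteration caps per FFD level.
#' @param rigid_pyramid,rigid_maxit pyramid factors and iteration cap used
#'   by the rigid and affine stages.
#' @param seed RNG seed reserved for stochastic metric sampling (the
#'   default dense metric is deterministic).
#' @return object of class `registration_config`.
#' @export
registration_config <- function(metric_sigma = 1.5, levels = c(20, 10, 5),
                                pyramid = c(4, 2, 1), lambda = 1e-3,
                                maxit = c(60, 45, 30),
                                rigid_pyramid = c(4, 2), rigid_maxit = 50,
                                seed = NULL) {
  stopifnot(all(diff(levels) < 0), lambda >= 0,
            length(pyramid) == length(levels))
  if (length(maxit) == 1) maxit <- rep(maxit, length(levels))
  structure(list(metric_sigma = metric_sigma, levels = levels,
                 pyramid = as.integer(pyramid), lambda = lambda,
                 maxit = as.integer(maxit),
                 rigid_pyramid = as.integer(rigid_pyramid),
                 rigid_maxit = as.integer(rigid_maxit), seed = seed),
            class = "registration_config")
}

# smoothed indicator channels of a label map, optionally pyramid-downsampled
make_channels <- function(lm, sigma_mm, factor = 1) {
  d <- lm$data
  masks <- list(wall = (d == 1L | d == 3L) + 0,
                cavity = (d == 2L) + 0,
                scar = (d == 3L) + 0)
  sig_vox <- sigma_mm / lm$voxel
  ch <- lapply(masks, function(m) {
    dim(m) <- dim(d)
    cpp_gaussian_smooth(m, sig_vox)
  })
  origin <- lm$origin
  voxel <- lm$voxel
  if (factor > 1) {
    ch <- lapply(ch, block_mean, f = factor)
    origin <- origin + (factor - 1) / 2 * voxel
    voxel <- voxel * factor
  }
  list(ch = ch, origin = origin, voxel = voxel, dim = dim(ch[[1]]))
}

# effective channel smoothing at a pyramid level (compose metric smoothing
# with anti-alias smoothing matched to the downsampling factor)
level_sigma <- function(cfg, fixed_voxel, factor) {
  sqrt(cfg$metric_sigma^2 + (factor * fixed_voxel / 3)^2)
}

# matching pyramid factor for the moving grid (same world-space scale)
moving_factor <- function(factor, fixed_voxel, moving_voxel) {
  max(1L, as.integer(round(factor * fixed_voxel / moving_voxel)))
}

reg_cost <- function(A, b, fx, mv, coef = NULL, lat0 = c(0, 0, 0), h = 1,
                     grad = FALSE, movgrad = NULL, lambda = 0) {
  cpp_reg_cost_grad(A, b, coef, lat0, h, fx$ch, fx$origin, fx$voxel,
                    mv$ch, mv$origin, mv$voxel, movgrad, lambda, grad)
}

check_overlap <- function(fixed, moving, init) {
  g <- grid_geom(fixed)
  lo <- g$origin - g$voxel / 2
  hi <- g$origin + (g$dim - 0.5) * g$voxel
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  mapped <- transform_points(init, corners)
  gm <- grid_geom(moving)
  mlo <- gm$origin - gm$voxel / 2
  mhi <- gm$origin + (gm$dim - 0.5) * gm$voxel
  ok <- all(apply(mapped, 2, min) < mhi) && all(apply(mapped, 2, max) > mlo)
  if (!ok) stop("no overlap between fixed and moving bounding boxes after init")
  invisible(TRUE)
}

euler_rotation <- function(th) {
  cx <- cos(th[1]); sx <- sin(th[1])
  cy <- cos(th[2]); sy <- sin(th[2])
  cz <- cos(th[3]); sz <- sin(th[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

#' Image-based rigid registration of label maps
#'
#' Refines an initial rigid transform by minimising the multi-channel SSD
#' metric over 6 parameters (rotation about the fixed-image centre +
#' translation), coarse to fine. The result never degrades the metric
#' relative to the initialisation.
#'
#' @param fixed,moving `lv_labelmap`s sharing the label vocabulary.
#' @param init initial `rigid_transform` (e.g. from
#'   [fit_rigid_landmarks()]).
#' @param cfg a [registration_config()].
#' @return `rigid_transform` with attribute `metric` (initial and final
#'   values at the finest level used).
#' @export
register_rigid <- function(fixed, moving, init = rigid_transform(),
                           cfg = registration_config()) {
  check_overlap(fixed, moving, init)
  g <- grid_geom(fixed)
  ctr <- g$origin + (g$dim - 1) * g$voxel / 2
  cur <- init
  for (factor in cfg$rigid_pyramid) {
    sig <- level_sigma(cfg, g$voxel, factor)
    fx <- make_channels(fixed, sig, factor)
    mv <- make_channels(moving, sig, moving_factor(factor, g$voxel, moving$voxel))
    R0 <- cur$A; t0 <- cur$b
    fn <- function(p) {
      Rth <- euler_rotation(p[1:3])
      A <- R0 %*% Rth
      b <- as.numeric(R0 %*% (ctr - Rth %*% ctr + p[4:6])) + t0
      reg_cost(A, b, fx, mv)$cost
    }
    opt <- optim(rep(0, 6), fn, method = "L-BFGS-B",
                 control = list(maxit = cfg$rigid_maxit,
                                parscale = c(rep(0.02, 3), rep(2, 3)),
                                factr = 1e9))
    p <- opt$par
    Rth <- euler_rotation(p[1:3])
    cur <- rigid_transform(R0 %*% Rth,
                           as.numeric(R0 %*% (ctr - Rth %*% ctr + p[4:6])) + t0)
  }
  factor <- cfg$rigid_pyramid[length(cfg$rigid_pyramid)]
  sig <- level_sigma(cfg, g$voxel, factor)
  fx <- make_channels(fixed, sig, factor)
  mv <- make_channels(moving, sig, moving_factor(factor, g$voxel, moving$voxel))
  m_init <- reg_cost(init$A, init$b, fx, mv)$cost
  m_final <- reg_cost(cur$A, cur$b, fx, mv)$cost
  if (m_final > m_init) {
    cur <- init
    m_final <- m_init
  }
  attr(cur, "metric") <- c(init = m_init, final = m_final)
  cur
}

#' Affine refinement of a rigid initialisation
#'
#' Minimises the same metric over all 12 affine parameters; captures the
#' global anisotropic scaling between conditions. Near-singular updates are
#' rejected through a determinant barrier.
#'
#' @inheritParams register_rigid
#' @param init initial `rigid_transform` or `affine_transform`.
#' @return `affine_transform` with attribute `metric`.
#' @export
register_affine <- function(fixed, moving, init = rigid_transform(),
                            cfg = registration_config()) {
  check_overlap(fixed, moving, init)
  g <- grid_geom(fixed)
  ctr <- g$origin + (g$dim - 1) * g$voxel / 2
  cur <- affine_transform(init$A, init$b)
  for (factor in cfg$rigid_pyramid) {
    sig <- level_sigma(cfg, g$voxel, factor)
    fx <- make_channels(fixed, sig, factor)
    mv <- make_channels(moving, sig, moving_factor(factor, g$voxel, moving$voxel))
    A0 <- cur$A; t0 <- cur$b
    fn <- function(p) {
      M <- diag(3) + matrix(p[1:9], 3)
      if (abs(det(M)) < 1e-3) return(1e6)
      A <- A0 %*% M
      b <- as.numeric(A0 %*% (ctr - M %*% ctr + p[10:12])) + t0
      reg_cost(A, b, fx, mv)$cost
    }
    opt <- optim(rep(0, 12), fn, method = "L-BFGS-B",
                 control = list(maxit = cfg$rigid_maxit,
                                parscale = c(rep(0.02, 9), rep(2, 3)),
                                factr = 1e9))
    p <- opt$par
    M <- diag(3) + matrix(p[1:9], 3)
    cur <- affine_transform(A0 %*% M,
                            as.numeric(A0 %*% (ctr - M %*% ctr + p[10:12])) + t0)
  }
  factor <- cfg$rigid_pyramid[length(cfg$rigid_pyramid)]
  sig <- level_sigma(cfg, g$voxel, factor)
  fx <- make_channels(fixed, sig, factor)
  mv <- make_channels(moving, sig, moving_factor(factor, g$voxel, moving$voxel))
  m_init <- reg_cost(init$A, init$b, fx, mv)$cost
  m_final <- reg_cost(cur$A, cur$b, fx, mv)$cost
  if (m_final > m_init) {
    cur <- affine_transform(init$A, init$b)
    m_final <- m_init
  }
  attr(cur, "metric") <- c(init = m_init, final = m_final)
  cur
}

# lattice covering the fixed-image world box plus spline support margin
ffd_lattice <- function(fixed, h) {
  g <- grid_geom(fixed)
  lo <- g$origin - g$voxel / 2
  hi <- g$origin + (g$dim - 0.5) * g$voxel
  lat0 <- lo - 2 * h
  n <- as.integer(ceiling((hi - lat0) / h)) + 3L
  list(lat0 = lat0, n = n)
}

#' Multi-level B-spline free-form deformation registration
#'
#' Optimises the multi-channel SSD metric plus a bending-energy penalty
#' over the control-point displacements of a cubic B-spline lattice,
#' coarse-to-fine over `cfg$levels`, starting from an affine
#' initialisation. Deterministic given the configuration.
#'
#' @inheritParams register_rigid
#' @param init initial `affine_transform` (or rigid).
#' @param cfg a [registration_config()].
#' @return `ffd_transform` with attribute `metric_trace`: the full-
#'   resolution metric after the affine initialisation and after each
#'   level.
#' @export
register_ffd <- function(fixed, moving, init, cfg = registration_config()) {
  check_overlap(fixed, moving, init)
  g <- grid_geom(fixed)
  A <- init$A; b <- init$b
  fx_full <- make_channels(fixed, cfg$metric_sigma, 1)
  mv_full <- make_channels(moving, cfg$metric_sigma, 1)
  trace <- c(affine = reg_cost(A, b, fx_full, mv_full)$cost)
  coef <- NULL; lat <- NULL
  for (li in seq_along(cfg$levels)) {
    h <- cfg$levels[li]
    factor <- cfg$pyramid[li]
    sig <- level_sigma(cfg, g$voxel, factor)
    fx <- if (factor == 1 && abs(sig - cfg$metric_sigma) < 1e-9) fx_full
          else make_channels(fixed, sig, factor)
    mv <- if (factor == 1 && abs(sig - cfg$metric_sigma) < 1e-9) mv_full
          else make_channels(moving, sig,
                             moving_factor(factor, g$voxel, moving$voxel))
    movgrad <- lapply(mv$ch, cpp_central_gradient, voxel = mv$voxel)
    new_lat <- ffd_lattice(fixed, h)
    new_coef <- array(0, c(new_lat$n, 3))
    if (!is.null(coef)) {
      nodes <- grid_centers(new_lat$n, new_lat$lat0, h)
      up <- cpp_transform_points(nodes, diag(3), c(0, 0, 0), coef,
                                 lat$lat0, lat$h) - nodes
      new_coef <- array(up, c(new_lat$n, 3))
    }
    coef <- new_coef; lat <- list(lat0 = new_lat$lat0, h = h, n = new_lat$n)
    cdim <- dim(coef)
    fn <- function(p) {
      reg_cost(A, b, fx, mv, coef = array(p, cdim), lat0 = lat$lat0, h = h,
               lambda = cfg$lambda)$cost
    }
    gr <- function(p) {
      res <- reg_cost(A, b, fx, mv, coef = array(p, cdim), lat0 = lat$lat0,
                      h = h, grad = TRUE, movgrad = movgrad,
                      lambda = cfg$lambda)
      if (!all(is.finite(res$grad)))
        stop(sprintf("non-finite FFD gradient at level %d (spacing %g mm)",
                     li, h))
      res$grad
    }
    opt <- optim(as.numeric(coef), fn, gr, method = "L-BFGS-B",
                 control = list(maxit = cfg$maxit[li], factr = 1e7))
    coef <- array(opt$par, cdim)
    trace <- c(trace, setNames(
      reg_cost(A, b, fx_full, mv_full, coef = coef, lat0 = lat$lat0,
               h = h)$cost, sprintf("level_%gmm", h)))
  }
  out <- ffd_transform(A, b, lat$lat0, lat$h, coef)
  attr(out, "metric_trace") <- trace
  out
}

#' Resample a volume or label map through a transform
#'
#' Scalar volumes are interpolated trilinearly; label maps by per-label
#' indicator interpolation with argmax and the fixed priority tie-break
#' (scar > cavity > myocardium > aorta > background). Points mapping
#' outside the source grid become 0/background.
#'
#' @param source `lv_volume` or `lv_labelmap` (the moving image).
#' @param tr transform mapping target (fixed) to source (moving) space.
#' @param target target grid: an `lv_volume`/`lv_labelmap` or a
#'   `list(dim, origin, voxel)`.
#' @return resampled object of the same class as `source`, on the target
#'   grid; the target's MV plane metadata (if a volume) is carried over,
#'   otherwise the source's.
#' @export
apply_transform <- function(source, tr, target) {
  g <- if (is.list(target) && !inherits(target, "lv_volume")) target
       else grid_geom(target)
  pts <- grid_centers(g$dim, g$origin, g$voxel)
  y <- transform_points(tr, pts)
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

#' Bending energy of an FFD (discrete second-difference form)
#'
#' Zero for any control field sampled from an affine map.
#'
#' @param tr an `ffd_transform`.
#' @return non-negative scalar.
#' @export
bending_energy <- function(tr) {
  stopifnot(inherits(tr, "ffd_transform"))
  cpp_bending_energy(tr$coef)
}
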