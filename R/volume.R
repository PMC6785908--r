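#' 3D scalar volume with isotropic voxels
#'
#' A minimal container for a 3D image: a numeric array plus an isotropic
#' voxel size (mm) and the world-space position of the centre of voxel
#' `(1,1,1)`. Grids are axis-aligned; the world coordinate of voxel
#' `(i,j,k)` (1-based) is `origin + (c(i,j,k) - 1) * voxel`.
#'
#' @param data numeric 3D array of intensities (finite).
#' @param voxel positive voxel edge length in mm (isotropic).
#' @param origin world position (mm) of the first voxel centre.
#' @param mv_plane optional mitral-valve truncation plane,
#'   `list(point =, normal =)` in world mm; the LV occupies the half-space
#'   below the plane (opposite the normal).
#' @return an object of class `lv_volume`.
#' @export
volume3d <- function(data, voxel, origin = c(0, 0, 0), mv_plane = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!all(is.finite(data))) stop("intensities must be finite")
  stopifnot(length(voxel) == 1, voxel > 0, length(origin) == 3)
  structure(
    list(data = data, voxel = as.numeric(voxel),
         origin = as.numeric(origin), mv_plane = mv_plane),
    class = "lv_volume"
  )
}

#' Integer label map sharing the `volume3d` geometry contract
#'
#' Labels use the fixed vocabulary 0 background, 1 myocardium, 2 cavity,
#' 3 scar, 4 aorta. Scar voxels are stored as label 3 and are anatomically
#' part of the wall: `wall = myocardium | scar`.
#'
#' @inheritParams volume3d
#' @param data integer 3D array with values in 0..4.
#' @return an object of class `lv_labelmap` (also `lv_volume`).
#' @export
label_map <- function(data, voxel, origin = c(0, 0, 0), mv_plane = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  storage.mode(data) <- "integer"
  if (!all(data %in% LBL)) stop("labels outside vocabulary 0..4")
  v <- volume3d(data + 0, voxel, origin, mv_plane)
  v$data <- data
  class(v) <- c("lv_labelmap", "lv_volume")
  v
}

#' @export
print.lv_volume <- function(x, ...) {
  kind <- if (inherits(x, "lv_labelmap")) "label map" else "volume"
  cat(sprintf("<lv %s> %s voxels @ %.3g mm, origin (%s) mm\n", kind,
              paste(dim(x$data), collapse = "x"), x$voxel,
              paste(sprintf("%.2f", x$origin), collapse = ", ")))
  if (inherits(x, "lv_labelmap")) {
    tb <- table(factor(x$data, levels = LBL, labels = names(LBL)))
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  }
  invisible(x)
}

#' Binary masks for the standard compartments
#'
#' @param labels an `lv_labelmap`.
#' @return logical array of the same dimension.
#' @export
wall_mask <- function(labels) {
  stopifnot(inherits(labels, "lv_labelmap"))
  labels$data == LBL[["myocardium"]] | labels$data == LBL[["scar"]]
}

#' @rdname wall_mask
#' @export
cavity_mask <- function(labels) {
  stopifnot(inherits(labels, "lv_labelmap"))
  labels$data == LBL[["cavity"]]
}

#' @rdname wall_mask
#' @export
scar_mask <- function(labels) {
  stopifnot(inherits(labels, "lv_labelmap"))
  labels$data == LBL[["scar"]]
}

# geometry of a grid as a plain list
grid_geom <- function(vol) {
  list(dim = dim(vol$data), origin = vol$origin, voxel = vol$voxel)
}
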