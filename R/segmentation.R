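#' Scar segmentation parameters
#'
#' @param fwhm_fraction fraction of the reference maximum used as the
#'   in-vivo threshold (0.5 = full-width at half-maximum).
#' @param reference_percentile robust-maximum percentile within the seeded
#'   enhancing neighbourhood (guards against single hot voxels).
#' @param sd_multiplier number of standard deviations below the scar-ROI
#'   mean for the ex-vivo lower scar boundary.
#' @param connectivity 6, 18 or 26 neighbourhood for connected components.
#' @param seeds integer N x 3 matrix of 1-based voxel indices placed in
#'   clearly enhancing regions.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(fwhm_fraction = 0.5, reference_percentile = 99,
                                sd_multiplier = 1, connectivity = 26,
                                seeds = NULL) {
  stopifnot(fwhm_fraction > 0, fwhm_fraction < 1, sd_multiplier >= 0,
            connectivity %in% c(6L, 18L, 26L),
            reference_percentile > 0, reference_percentile <= 100)
  if (!is.null(seeds)) seeds <- as_seed_matrix(seeds)
  structure(list(fwhm_fraction = fwhm_fraction,
                 reference_percentile = reference_percentile,
                 sd_multiplier = sd_multiplier,
                 connectivity = as.integer(connectivity), seeds = seeds),
            class = "segmentation_params")
}

as_seed_matrix <- function(seeds) {
  seeds <- if (is.matrix(seeds)) seeds else matrix(seeds, ncol = 3, byrow = TRUE)
  storage.mode(seeds) <- "integer"
  stopifnot(ncol(seeds) == 3, nrow(seeds) >= 1)
  seeds
}

seed_linear_index <- function(seeds, dims) {
  stopifnot(all(seeds >= 1), all(t(seeds) <= dims))
  (seeds[, 3] - 1) * dims[1] * dims[2] + (seeds[, 2] - 1) * dims[1] + seeds[, 1]
}

#' Keep only mask components connected to seed voxels
#'
#' @param mask logical (or 0/1) 3D array.
#' @param seeds integer N x 3 matrix of 1-based voxel indices; seeds falling
#'   outside the mask are ignored with a warning.
#' @param connectivity 6, 18 or 26.
#' @return logical array: the union of connected components that contain at
#'   least one seed (empty if no seed hits the mask).
#' @export
connected_component_filter <- function(mask, seeds, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3)
  seeds <- as_seed_matrix(seeds)
  m <- array(as.integer(mask != 0), dim(mask))
  comp <- cpp_connected_components(m, as.integer(connectivity))
  lin <- seed_linear_index(seeds, dim(mask))
  ids <- comp[lin]
  if (any(ids == 0)) warning("some seeds fall outside the mask; ignored")
  ids <- unique(ids[ids > 0])
  if (length(ids) == 0) {
    warning("no seeds inside the mask; returning empty mask")
    return(array(FALSE, dim(mask)))
  }
  array(comp %in% ids, dim(mask))
}

#' In-vivo scar segmentation by the FWHM rule
#'
#' Thresholds wall voxels at `fwhm_fraction` times a robust reference
#' maximum (the `reference_percentile` intensity among wall voxels in a
#' 5x5x5 neighbourhood of the seeds), then keeps the components connected
#' to the seeds.
#'
#' @param invivo an `lv_volume` (in-vivo LGE intensities).
#' @param wall logical wall mask on the same grid.
#' @param params a [segmentation_params()] with non-empty `seeds` inside
#'   the wall.
#' @return logical scar mask (subset of `wall`), with attribute `threshold`.
#' @export
fwhm_scar <- function(invivo, wall, params) {
  stopifnot(inherits(invivo, "lv_volume"), identical(dim(invivo$data), dim(wall)))
  seeds <- params$seeds
  if (is.null(seeds)) stop("FWHM segmentation requires seeds")
  lin <- seed_linear_index(seeds, dim(wall))
  if (!all(wall[lin])) stop("seeds must lie inside the wall mask")
  # reference region: wall voxels within a 2-voxel box of any seed
  ref_sel <- array(FALSE, dim(wall))
  d <- dim(wall)
  for (s in seq_len(nrow(seeds))) {
    i <- pmax(1, seeds[s, 1] - 2):pmin(d[1], seeds[s, 1] + 2)
    j <- pmax(1, seeds[s, 2] - 2):pmin(d[2], seeds[s, 2] + 2)
    k <- pmax(1, seeds[s, 3] - 2):pmin(d[3], seeds[s, 3] + 2)
    ref_sel[i, j, k] <- TRUE
  }
  ref_vals <- invivo$data[ref_sel & wall]
  ref_max <- quantile(ref_vals, params$reference_percentile / 100, names = FALSE)
  thr <- params$fwhm_fraction * ref_max
  cand <- wall & invivo$data >= thr
  if (!any(cand)) {
    warning("no wall voxels reach the FWHM threshold; empty scar mask")
    out <- array(FALSE, dim(wall))
  } else {
    out <- connected_component_filter(cand, seeds, params$connectivity)
  }
  attr(out, "threshold") <- thr
  out
}

#' Region of interest on a label-map grid
#'
#' @param voxels integer N x 3 matrix of 1-based voxel indices.
#' @param role `"scar_roi"` or `"remote_roi"`.
#' @return object of class `lv_roi`.
#' @export
region_of_interest <- function(voxels, role = c("scar_roi", "remote_roi")) {
  voxels <- as_seed_matrix(voxels)
  structure(list(voxels = voxels, role = match.arg(role)), class = "lv_roi")
}

#' Ex-vivo scar segmentation by the mean-minus-SD rule
#'
#' The lower scar boundary is `mean(scar ROI) - sd_multiplier * SD(scar
#' ROI)`; wall voxels at or above it are kept if connected to the seeds.
#' The remote (non-enhancing) ROI statistics are recorded for QC. An
#' optional exclusion mask removes voxels deemed enhanced-but-remote; no
#' voxels are ever added.
#'
#' @param exvivo an `lv_volume` (ex-vivo intensities).
#' @param wall logical wall mask on the same grid.
#' @param scar_roi,remote_roi [region_of_interest()] objects (non-empty,
#'   inside the wall).
#' @param params a [segmentation_params()]; if `params$seeds` is `NULL` the
#'   scar-ROI voxels act as component seeds.
#' @param exclusion optional logical mask of voxels to remove.
#' @return logical scar mask with attributes `threshold` and `qc`.
#' @export
exvivo_scar <- function(exvivo, wall, scar_roi, remote_roi, params,
                        exclusion = NULL) {
  stopifnot(inherits(exvivo, "lv_volume"), identical(dim(exvivo$data), dim(wall)),
            inherits(scar_roi, "lv_roi"), inherits(remote_roi, "lv_roi"))
  d <- dim(wall)
  lin_s <- seed_linear_index(scar_roi$voxels, d)
  lin_r <- seed_linear_index(remote_roi$voxels, d)
  if (!all(wall[lin_s]) || !all(wall[lin_r]))
    stop("ROIs must lie inside the wall mask")
  vals <- exvivo$data[lin_s]
  if (length(vals) < 2 || sd(vals) == 0) stop("degenerate ROI")
  thr <- mean(vals) - params$sd_multiplier * sd(vals)
  cand <- wall & exvivo$data >= thr
  if (!is.null(exclusion)) cand <- cand & !exclusion
  seeds <- params$seeds %||% scar_roi$voxels
  out <- if (!any(cand)) {
    warning("no wall voxels reach the scar threshold; empty scar mask")
    array(FALSE, d)
  } else {
    connected_component_filter(cand, seeds, params$connectivity)
  }
  attr(out, "threshold") <- thr
  attr(out, "qc") <- list(scar_roi_mean = mean(vals), scar_roi_sd = sd(vals),
                          remote_mean = mean(exvivo$data[lin_r]),
                          remote_sd = sd(exvivo$data[lin_r]))
  out
}

#' Downsample a label map by world-space majority voting
#'
#' Each coarse voxel takes the most frequent label among the fine voxels
#' whose centres fall in its (half-open) box; ties are broken by the fixed
#' priority scar > cavity > myocardium > aorta > background. Non-integer
#' voxel ratios are handled naturally by the world-space binning.
#'
#' @param fine an `lv_labelmap`.
#' @param target_voxel coarse voxel size, mm (must be >= the fine voxel).
#' @return coarse `lv_labelmap` covering the fine grid.
#' @export
downsample_labels <- function(fine, target_voxel) {
  stopifnot(inherits(fine, "lv_labelmap"), target_voxel >= fine$voxel)
  g <- grid_geom(fine)
  lo <- g$origin - g$voxel / 2
  ext <- g$dim * g$voxel
  cdim <- pmax(1L, as.integer(ceiling(ext / target_voxel)))
  corig <- lo + target_voxel / 2
  lab <- cpp_box_downsample_labels(fine$data, g$origin, g$voxel,
                                   cdim, corig, target_voxel, LABEL_PRIORITY)
  label_map(lab, target_voxel, corig, fine$mv_plane)
}

#' Replace the scar compartment of a label map with a segmented mask
#'
#' Scar voxels must lie within the wall; former scar voxels not in the mask
#' revert to myocardium.
#'
#' @param labels an `lv_labelmap`.
#' @param scar logical scar mask (subset of the wall).
#' @return updated `lv_labelmap`.
#' @export
set_scar_label <- function(labels, scar) {
  stopifnot(inherits(labels, "lv_labelmap"), identical(dim(labels$data), dim(scar)))
  wall <- wall_mask(labels)
  if (any(scar & !wall)) stop("scar mask must be a subset of the wall")
  d <- labels$data
  d[wall] <- LBL[["myocardium"]]
  d[scar] <- LBL[["scar"]]
  label_map(d, labels$voxel, labels$origin, labels$mv_plane)
}
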