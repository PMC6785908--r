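#' Triangulated cardiac surface mesh
#'
#' @param vertices N x 3 matrix of node coordinates (world mm).
#' @param triangles M x 3 integer matrix of 1-based node indices.
#' @param attributes named list of per-node attribute vectors (e.g.
#'   `thickness_mm`, `transmurality`, `scar_flag`, `paired_epi_node`).
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, attributes = list()) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3,
            all(triangles >= 1), all(triangles <= nrow(vertices)))
  for (a in attributes) stopifnot(length(a) == nrow(vertices))
  structure(list(vertices = vertices, triangles = triangles,
                 attributes = attributes), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d nodes, %d triangles, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$triangles), surface_area(x)))
  if (length(x$attributes))
    cat("  attributes:", paste(names(x$attributes), collapse = ", "), "\n")
  invisible(x)
}

#' Total mesh surface area (mm^2)
#' @param mesh a `surface_mesh`.
#' @export
surface_area <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Extract the endocardial or epicardial surface of a label map
#'
#' Marching-tetrahedra iso-surface at level 0.5 of the relevant indicator
#' (cavity for the endocardium; cavity + wall for the epicardium), after a
#' light fixed Gaussian pre-smoothing of the indicator (sigma 0.8 voxel) to
#' suppress voxelisation stair-casing, followed by 5 Laplacian smoothing
#' iterations. The mesh is truncated at the mitral-valve disc plane (cap
#' triangles removed). A disconnected indicator reduces to its largest
#' component with a warning.
#'
#' @param labels an `lv_labelmap` with MV plane metadata.
#' @param which `"endo"` or `"epi"`.
#' @return a `surface_mesh`.
#' @export
extract_surface <- function(labels, which = c("endo", "epi")) {
  which <- match.arg(which)
  stopifnot(inherits(labels, "lv_labelmap"))
  if (is.null(labels$mv_plane)) stop("MV plane metadata required")
  if (!any(wall_mask(labels))) stop("empty wall")
  ind <- if (which == "endo") cavity_mask(labels)
         else labels$data %in% c(LBL[["myocardium"]], LBL[["cavity"]], LBL[["scar"]])
  if (!any(ind)) stop(sprintf("empty %s indicator", which))
  ind <- array(as.integer(ind), dim(labels$data))
  comp <- cpp_connected_components(ind, 26L)
  ncomp <- max(comp)
  if (ncomp > 1) {
    warning(sprintf("%s indicator has %d components; using the largest",
                    which, ncomp))
    big <- which.max(tabulate(comp[comp > 0], ncomp))
    ind <- array(as.integer(comp == big), dim(ind))
  }
  f <- array(as.numeric(ind), dim(ind))
  f <- cpp_gaussian_smooth(f, 0.8)
  mt <- cpp_marching_tetra(f, labels$origin, labels$voxel, 0.5)
  if (nrow(mt$vertices) == 0) stop("iso-surface is empty")
  verts <- cpp_laplacian_smooth(mt$vertices, mt$triangles, 5L, 0.5)
  tris <- mt$triangles
  # cut the flat cap at the MV plane
  pl <- labels$mv_plane
  cen <- (verts[tris[, 1], , drop = FALSE] + verts[tris[, 2], , drop = FALSE] +
            verts[tris[, 3], , drop = FALSE]) / 3
  dsig <- (cen[, 1] - pl$point[1]) * pl$normal[1] +
    (cen[, 2] - pl$point[2]) * pl$normal[2] +
    (cen[, 3] - pl$point[3]) * pl$normal[3]
  keep <- dsig < -0.75 * labels$voxel
  tris <- tris[keep, , drop = FALSE]
  if (nrow(tris) == 0) stop("no surface below the MV plane")
  used <- sort(unique(as.integer(tris)))
  remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
  surface_mesh(verts[used, , drop = FALSE],
               matrix(remap[tris], ncol = 3))
}

#' Pair each endocardial node with its nearest epicardial node
#'
#' The "projection" used for all wall measurements is the straight segment
#' from an endocardial node to the Euclidean-nearest epicardial node (ties
#' broken to the lowest index).
#'
#' @param endo,epi `surface_mesh` objects.
#' @return data frame of projection records: `endo_node`, `epi_node`,
#'   `length_mm`.
#' @export
pair_nearest_epi <- function(endo, epi) {
  stopifnot(nrow(endo$vertices) > 0, nrow(epi$vertices) > 0)
  idx <- cpp_nn_index(endo$vertices, epi$vertices)
  d <- sqrt(rowSums((epi$vertices[idx, , drop = FALSE] - endo$vertices)^2))
  data.frame(endo_node = seq_len(nrow(endo$vertices)), epi_node = idx,
             length_mm = d)
}

#' Wall thickness from projection records
#'
#' Thickness at an endocardial node is the absolute distance to its paired
#' epicardial node (the projection segment length).
#'
#' @param records output of [pair_nearest_epi()].
#' @return numeric vector of per-node thickness (mm).
#' @export
wall_thickness <- function(records) {
  records$length_mm
}

#' Nodal scar flag and transmurality by segment sampling
#'
#' Each projection segment is sampled at steps of `0.5 * voxel` (endpoints
#' included); a node is flagged as scar if at least one sample falls inside
#' a scar voxel (half-open voxel boxes), and transmurality is the fraction
#' of samples inside scar.
#'
#' @param records output of [pair_nearest_epi()].
#' @param endo,epi the paired meshes.
#' @param scar an `lv_labelmap` (its scar label is used) or a logical scar
#'   mask with `geom` = `list(dim, origin, voxel)` supplied.
#' @param geom grid geometry when `scar` is a plain mask.
#' @return data frame with `scar_flag` and `transmurality` per endo node.
#' @export
nodal_scar_and_transmurality <- function(records, endo, epi, scar, geom = NULL) {
  if (inherits(scar, "lv_labelmap")) {
    geom <- grid_geom(scar)
    scar <- scar_mask(scar)
  }
  stopifnot(!is.null(geom))
  step <- 0.5 * geom$voxel
  p0 <- endo$vertices[records$endo_node, , drop = FALSE]
  p1 <- epi$vertices[records$epi_node, , drop = FALSE]
  nseg <- pmax(1L, as.integer(ceiling(records$length_mm / step)))
  nsamp <- nseg + 1L
  grp <- rep.int(seq_len(nrow(records)), nsamp)
  tfrac <- unlist(lapply(nsamp, function(n) seq(0, 1, length.out = n)),
                  use.names = FALSE)
  pts <- p0[grp, , drop = FALSE] +
    tfrac * (p1[grp, , drop = FALSE] - p0[grp, , drop = FALSE])
  idx <- sweep(pts, 2, geom$origin) / geom$voxel + 0.5
  ijk <- floor(idx)
  inside <- ijk[, 1] >= 0 & ijk[, 2] >= 0 & ijk[, 3] >= 0 &
    ijk[, 1] < geom$dim[1] & ijk[, 2] < geom$dim[2] & ijk[, 3] < geom$dim[3]
  hit <- logical(length(grp))
  lin <- ijk[inside, 1] + geom$dim[1] * (ijk[inside, 2] + geom$dim[2] * ijk[inside, 3])
  hit[inside] <- scar[lin + 1]
  nhit <- rowsum(as.integer(hit), grp)[, 1]
  data.frame(scar_flag = nhit >= 1, transmurality = nhit / nsamp)
}

#' Full projection morphometry of one condition
#'
#' Extracts endo/epi meshes, pairs nodes, and attaches thickness, scar flag
#' and transmurality attributes to the endocardial mesh.
#'
#' @param labels an `lv_labelmap` (its scar label defines scar, unless a
#'   `scar` mask is supplied).
#' @param scar optional logical scar mask on the label grid.
#' @return list with `endo` (attributed mesh), `epi`, `records`.
#' @export
lv_morphometry <- function(labels, scar = NULL) {
  endo <- extract_surface(labels, "endo")
  epi <- extract_surface(labels, "epi")
  rec <- pair_nearest_epi(endo, epi)
  th <- wall_thickness(rec)
  st <- if (is.null(scar))
    nodal_scar_and_transmurality(rec, endo, epi, labels)
  else
    nodal_scar_and_transmurality(rec, endo, epi, scar, grid_geom(labels))
  endo$attributes <- list(thickness_mm = th, transmurality = st$transmurality,
                          scar_flag = st$scar_flag,
                          paired_epi_node = rec$epi_node)
  list(endo = endo, epi = epi, records = rec)
}

#' Nodal-wise scar DICE between two attributed endocardial meshes
#'
#' Each node of `mesh_a` is paired with its nearest node of `mesh_b`;
#' DICE = 2 x (pairs where both are scar) / (scar nodes of a + mapped scar
#' nodes of b). Returns 1 with a warning when both meshes carry no scar.
#'
#' @param mesh_a,mesh_b `surface_mesh` objects with a `scar_flag`
#'   attribute.
#' @return DICE fraction in `[0, 1]`.
#' @export
nodal_dice_scar <- function(mesh_a, mesh_b) {
  fa <- mesh_a$attributes$scar_flag
  fb <- mesh_b$attributes$scar_flag
  if (is.null(fa) || is.null(fb)) stop("meshes must carry scar_flag")
  idx <- cpp_nn_index(mesh_a$vertices, mesh_b$vertices)
  fbm <- fb[idx]
  denom <- sum(fa) + sum(fbm)
  if (denom == 0) {
    warning("no scar nodes on either mesh; DICE defined as 1")
    return(1)
  }
  2 * sum(fa & fbm) / denom
}

#' Apply a point transform to a mesh
#' @param mesh a `surface_mesh`.
#' @param tr an `lv_transform`.
#' @return transformed mesh (attributes preserved).
#' @export
transform_mesh <- function(mesh, tr) {
  mesh$vertices <- transform_points(tr, mesh$vertices)
  mesh
}

#' LV long-axis and basal short-axis dimensions
#'
#' Long axis: distance from the cavity point farthest below the MV plane
#' (the apex) to the plane. Short axes: the extents of the cavity
#' cross-section in the plane parallel to the MV disc at 25% of the long
#' axis below it, along the cross-section's two principal directions. A
#' half-voxel is added to each extreme to compensate voxel-centre
#' truncation.
#'
#' @param labels an `lv_labelmap` with MV plane metadata and a non-empty
#'   cavity.
#' @return named vector `c(long_axis_mm, short_axis_1_mm, short_axis_2_mm)`.
#' @export
measure_lv_dimensions <- function(labels) {
  stopifnot(inherits(labels, "lv_labelmap"))
  if (is.null(labels$mv_plane)) stop("MV plane metadata required")
  cav <- which(cavity_mask(labels))
  if (length(cav) == 0) stop("empty cavity")
  d <- dim(labels$data)
  ijk <- cbind((cav - 1) %% d[1],
               ((cav - 1) %/% d[1]) %% d[2],
               (cav - 1) %/% (d[1] * d[2]))
  pts <- sweep(ijk * labels$voxel, 2, labels$origin, "+")
  pl <- labels$mv_plane
  depth <- -((pts[, 1] - pl$point[1]) * pl$normal[1] +
               (pts[, 2] - pl$point[2]) * pl$normal[2] +
               (pts[, 3] - pl$point[3]) * pl$normal[3])
  long_axis <- max(depth) + labels$voxel / 2
  d0 <- 0.25 * long_axis
  sel <- abs(depth - d0) <= labels$voxel / 2
  if (!any(sel)) stop("basal slice empty")
  # in-plane basis
  n <- pl$normal / sqrt(sum(pl$normal^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  uv <- cbind(pts[sel, , drop = FALSE] %*% e1, pts[sel, , drop = FALSE] %*% e2)
  pc <- prcomp(uv, center = TRUE, scale. = FALSE)
  ranges <- unname(apply(pc$x, 2, function(s) diff(range(s)))) + labels$voxel
  c(long_axis_mm = unname(long_axis), short_axis_1_mm = ranges[1],
    short_axis_2_mm = ranges[2])
}
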