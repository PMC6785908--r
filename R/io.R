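KNOWN_LANDMARKS <- c("LM_bifurcation", "RCA_ostium", "LV_apex",
                     "papillary_1", "papillary_2")

#' Ordered set of named anatomical landmarks (world mm)
#'
#' @param df data frame with columns `name`, `x`, `y`, `z`.
#' @param allow_custom accept names outside the standard vocabulary
#'   (left main bifurcation, RCA ostium, LV apex, papillary muscles).
#' @return data frame of class `landmark_set`.
#' @export
landmark_set <- function(df, allow_custom = FALSE) {
  stopifnot(all(c("name", "x", "y", "z") %in% names(df)))
  if (anyDuplicated(df$name)) stop("duplicate landmark names")
  if (!allow_custom && !all(df$name %in% KNOWN_LANDMARKS))
    stop("unknown landmark names (use allow_custom = TRUE to accept)")
  df <- df[, c("name", "x", "y", "z")]
  df$name <- as.character(df$name)
  class(df) <- c("landmark_set", "data.frame")
  df
}

#' Read / write NIfTI-1 volumes and label maps
#'
#' Volumes are written as single-file NIfTI-1 with isotropic spacing; grid
#' origin is carried in the qform. A JSON sidecar (`<path>.json`, written
#' alongside) stores what NIfTI cannot: the object kind (volume vs label
#' map) and the MV plane metadata. Reading enforces isotropic voxels and
#' restores integer label maps bit-exactly.
#'
#' @param x an `lv_volume` or `lv_labelmap`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_nifti` returns an `lv_volume`/`lv_labelmap`;
#'   `write_nifti` returns `path` invisibly.
#' @export
write_nifti <- function(x, path) {
  stopifnot(inherits(x, "lv_volume"))
  im <- RNifti::asNifti(x$data)
  RNifti::pixdim(im) <- rep(x$voxel, 3)
  sf <- diag(4)
  diag(sf)[1:3] <- x$voxel
  sf[1:3, 4] <- x$origin
  RNifti::`qform<-`(im, structure(sf, code = 2L))
  RNifti::writeNifti(im, path)
  side <- list(kind = if (inherits(x, "lv_labelmap")) "labelmap" else "volume",
               voxel = x$voxel, origin = x$origin, mv_plane = x$mv_plane)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  im <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(im)[1:3]
  if (max(pd) - min(pd) > 1e-6 * max(pd)) stop("isotropic voxels required")
  xf <- RNifti::xform(im)
  origin <- xf[1:3, 4]
  arr <- array(as.numeric(im), dim(im))
  side_path <- paste0(path, ".json")
  kind <- "volume"; mv <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    kind <- side$kind %||% "volume"
    if (!is.null(side$mv_plane))
      mv <- list(point = as.numeric(side$mv_plane$point),
                 normal = as.numeric(side$mv_plane$normal))
    if (!is.null(side$origin)) origin <- as.numeric(side$origin)
  }
  if (kind == "labelmap") {
    arr <- array(as.integer(round(arr)), dim(arr))
    label_map(arr, pd[1], origin, mv)
  } else {
    volume3d(arr, pd[1], origin, mv)
  }
}

#' Read / write landmark CSV files (`name,x_mm,y_mm,z_mm`)
#'
#' @param lm a [landmark_set()].
#' @param path CSV path.
#' @param allow_custom accept non-standard landmark names.
#' @return `read_landmarks` returns a `landmark_set`; `write_landmarks`
#'   returns `path` invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  df <- data.frame(name = lm$name,
                   x_mm = format(lm$x, digits = 17),
                   y_mm = format(lm$y, digits = 17),
                   z_mm = format(lm$z, digits = 17))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path, allow_custom = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "x_mm", "y_mm", "z_mm") %in% names(df)))
  landmark_set(data.frame(name = df$name, x = as.numeric(df$x_mm),
                          y = as.numeric(df$y_mm), z = as.numeric(df$z_mm)),
               allow_custom = allow_custom)
}

#' Serialise transforms as JSON documents
#'
#' Matrices are stored row-major; FFD transforms additionally store the
#' lattice origin, spacing and control coefficients.
#'
#' @param tr an `lv_transform`.
#' @param path JSON path.
#' @return `read_transform` returns the transform; `write_transform`
#'   returns `path` invisibly.
#' @export
write_transform <- function(tr, path) {
  stopifnot(inherits(tr, "lv_transform"))
  doc <- list(type = class(tr)[1],
              A = as.numeric(t(tr$A)), b = tr$b)
  if (inherits(tr, "ffd_transform")) {
    doc$lat0 <- tr$lat0
    doc$spacing <- tr$spacing
    doc$coef_dim <- dim(tr$coef)
    doc$coef <- as.numeric(tr$coef)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- matrix(doc$A, 3, 3, byrow = TRUE)
  switch(doc$type,
         rigid_transform = rigid_transform(A, doc$b),
         affine_transform = affine_transform(A, doc$b),
         ffd_transform = ffd_transform(A, doc$b, doc$lat0, doc$spacing,
                                       array(doc$coef, doc$coef_dim)),
         stop("unknown transform type: ", doc$type))
}

#' Read / write surface meshes (ASCII PLY and legacy VTK PolyData)
#'
#' Per-node attributes are written as extra vertex properties (PLY) or
#' POINT_DATA arrays (VTK) and restored on read.
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @return readers return a `surface_mesh`; writers return `path`
#'   invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  at <- mesh$attributes
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  writeLines(c("ply", "format ascii 1.0", sprintf("element vertex %d", nv),
               "property double x", "property double y", "property double z",
               sprintf("property double %s", names(at)),
               sprintf("element face %d", nt),
               "property list uchar int vertex_indices", "end_header"), con)
  vm <- cbind(mesh$vertices, do.call(cbind, lapply(at, as.numeric)))
  writeLines(apply(format(vm, digits = 17, trim = TRUE, scientific = FALSE),
                   1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$triangles[, 1] - 1, mesh$triangles[, 2] - 1,
                   mesh$triangles[, 3] - 1), con)
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  hd_end <- which(lines == "end_header")[1]
  hd <- lines[seq_len(hd_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hd, value = TRUE)))
  nt <- as.integer(sub("element face ", "", grep("^element face", hd, value = TRUE)))
  props <- sub("^property double ", "", grep("^property double", hd, value = TRUE))
  vdat <- read.table(text = lines[hd_end + seq_len(nv)])
  names(vdat) <- props
  fdat <- read.table(text = lines[hd_end + nv + seq_len(nt)])
  at <- as.list(vdat[setdiff(props, c("x", "y", "z"))])
  if ("scar_flag" %in% names(at)) at$scar_flag <- at$scar_flag != 0
  surface_mesh(as.matrix(vdat[, c("x", "y", "z")]),
               as.matrix(fdat[, 2:4]) + 1L, at)
}

#' @rdname write_mesh_ply
#' @export
write_mesh_vtk <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0", "lvcoreg surface mesh", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nv)), con)
  writeLines(apply(format(mesh$vertices, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(sprintf("POLYGONS %d %d", nt, 4 * nt), con)
  writeLines(paste(3, mesh$triangles[, 1] - 1, mesh$triangles[, 2] - 1,
                   mesh$triangles[, 3] - 1), con)
  at <- mesh$attributes
  if (length(at)) {
    writeLines(sprintf("POINT_DATA %d", nv), con)
    for (nm in names(at)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(format(as.numeric(at[[nm]]), digits = 17, trim = TRUE,
                        scientific = FALSE), con)
    }
  }
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  nv <- as.integer(strsplit(lines[ip], " ")[[1]][2])
  verts <- as.matrix(read.table(text = lines[ip + seq_len(nv)]))
  it <- grep("^POLYGONS", lines)[1]
  nt <- as.integer(strsplit(lines[it], " ")[[1]][2])
  tris <- as.matrix(read.table(text = lines[it + seq_len(nt)]))[, 2:4] + 1L
  at <- list()
  isc <- grep("^SCALARS", lines)
  for (i in isc) {
    nm <- strsplit(lines[i], " ")[[1]][2]
    vals <- as.numeric(lines[i + 1 + seq_len(nv)])
    at[[nm]] <- if (nm == "scar_flag") vals != 0 else vals
  }
  surface_mesh(verts, tris, at)
}

#' Read / write pipeline and phantom configuration as YAML
#'
#' @param cfg a named list (e.g. from [pipeline_config()]); classed objects
#'   are stored as plain lists and re-validated on use.
#' @param path YAML path.
#' @return `read_config` returns a named list; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(rapply(cfg, unclass, how = "replace"), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Rebuild a `phantom_spec` from a plain list (e.g. YAML config)
#' @param x named list of `phantom_spec` fields.
#' @return validated `phantom_spec`.
#' @export
as_phantom_spec <- function(x) {
  x <- unclass(x)
  spec <- do.call(phantom_spec, x[intersect(names(x), names(formals(phantom_spec)))])
  spec
}
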