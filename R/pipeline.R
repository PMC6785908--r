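#' Pipeline configuration
#'
#' Bundles the phantom specification, segmentation parameters and
#' registration configuration with the replicate count (default 7,
#' one per simulated animal), seeding and output options.
#'
#' @param phantom a [phantom_spec()].
#' @param seg a [segmentation_params()] (seeds are auto-placed per
#'   replicate when `NULL`).
#' @param reg a [registration_config()].
#' @param n_replicates number of simulated animals.
#' @param seed global seed; replicate `i` uses `seed + i - 1`.
#' @param jitter apply per-replicate geometry jitter
#'   ([jitter_phantom_spec()]).
#' @param registration run the rigid/affine/FFD chain (the expensive
#'   stage); when `FALSE` only native comparisons are produced.
#' @param outdir optional output directory for artifacts and the manifest.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_spec(),
                            seg = segmentation_params(),
                            reg = registration_config(),
                            n_replicates = 7, seed = 1, jitter = TRUE,
                            registration = TRUE, outdir = NULL) {
  stopifnot(n_replicates >= 1)
  structure(list(phantom = phantom, seg = seg, reg = reg,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), jitter = jitter,
                 registration = registration, outdir = outdir),
            class = "pipeline_config")
}

# interior scar voxels usable as component seeds (stand-in for the
# operator's seed placement in clearly enhancing tissue)
auto_scar_seeds <- function(labels, k = 3) {
  sc <- which(labels$data == LBL[["scar"]])
  if (length(sc) == 0) return(NULL)
  d <- dim(labels$data)
  ijk <- cbind((sc - 1) %% d[1] + 1,
               ((sc - 1) %/% d[1]) %% d[2] + 1,
               (sc - 1) %/% (d[1] * d[2]) + 1)
  # prefer voxels whose 6-neighbourhood is all scar
  interior <- rep(TRUE, nrow(ijk))
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
    nb <- sweep(ijk, 2, off, "+")
    ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
      nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
    lin <- (nb[, 3] - 1) * d[1] * d[2] + (nb[, 2] - 1) * d[1] + nb[, 1]
    interior <- interior & ok & (labels$data[pmin(pmax(lin, 1), length(labels$data))] == LBL[["scar"]]) & ok
  }
  cand <- ijk[interior, , drop = FALSE]
  if (nrow(cand) == 0) cand <- ijk
  sel <- unique(pmax(1, round(quantile(seq_len(nrow(cand)),
                                       probs = seq(0.2, 0.8, length.out = k),
                                       names = FALSE))))
  cand[sel, , drop = FALSE]
}

# automatic ROIs for the ex-vivo threshold: the scar region itself as the
# enhancing ROI, basal myocardium opposite the scar as the remote ROI
auto_exvivo_rois <- function(labels, spec) {
  sc <- which(labels$data == LBL[["scar"]])
  my <- which(labels$data == LBL[["myocardium"]])
  stopifnot(length(sc) > 0, length(my) > 0)
  d <- dim(labels$data)
  to_ijk <- function(lin) cbind((lin - 1) %% d[1] + 1,
                                ((lin - 1) %/% d[1]) %% d[2] + 1,
                                (lin - 1) %/% (d[1] * d[2]) + 1)
  ijk_my <- to_ijk(my)
  pts <- sweep((ijk_my - 1) * labels$voxel, 2, labels$origin, "+")
  phi <- atan2(pts[, 2], pts[, 1])
  opp <- (spec$scar_angle_start + spec$scar_angular_extent / 2 + 180) * pi / 180
  dphi <- atan2(sin(phi - opp), cos(phi - opp))
  zq <- quantile(pts[, 3], 0.7)
  sel <- abs(dphi) < pi / 6 & pts[, 3] > zq
  if (!any(sel)) sel <- abs(dphi) < pi / 3
  list(scar = region_of_interest(to_ijk(sc), "scar_roi"),
       remote = region_of_interest(ijk_my[sel, , drop = FALSE], "remote_roi"))
}

#' Full co-registration chain for one phantom pair
#'
#' Landmark rigid initialisation, then image-based rigid, affine and
#' multi-level FFD registration of the (downsampled) ex-vivo label map
#' onto the in-vivo grid.
#'
#' @param fixed in-vivo `lv_labelmap` (fixed image).
#' @param moving downsampled ex-vivo `lv_labelmap` (moving image).
#' @param lm_fixed,lm_moving landmark sets of the two conditions.
#' @param cfg a [registration_config()].
#' @return list with the four transforms (`landmark`, `rigid`, `affine`,
#'   `ffd`) and `registered`, the moving labels resampled onto the fixed
#'   grid through the full chain.
#' @export
coregister_pair <- function(fixed, moving, lm_fixed, lm_moving,
                            cfg = registration_config()) {
  t_lm <- fit_rigid_landmarks(lm_moving, lm_fixed)
  t_rig <- register_rigid(fixed, moving, t_lm, cfg)
  t_aff <- register_affine(fixed, moving, t_rig, cfg)
  t_ffd <- register_ffd(fixed, moving, t_aff, cfg)
  reg <- apply_transform(moving, t_ffd, fixed)
  list(landmark = t_lm, rigid = t_rig, affine = t_aff, ffd = t_ffd,
       registered = reg)
}

segment_pair <- function(invivo, exvivo, spec, seg) {
  wall_in <- wall_mask(invivo$labels)
  seeds_in <- seg$seeds %||% auto_scar_seeds(invivo$labels)
  seg_in <- seg
  seg_in$seeds <- seeds_in
  scar_in <- fwhm_scar(invivo$volume, wall_in, seg_in)
  labels_in <- set_scar_label(invivo$labels, scar_in)
  rois <- auto_exvivo_rois(exvivo$labels, spec)
  seg_ex <- seg
  seg_ex$seeds <- auto_scar_seeds(exvivo$labels)
  scar_ex <- exvivo_scar(exvivo$volume, wall_mask(exvivo$labels),
                         rois$scar, rois$remote, seg_ex)
  labels_ex <- set_scar_label(exvivo$labels, scar_ex)
  list(labels_in = labels_in, labels_ex = labels_ex)
}

replicate_analysis <- function(spec, seg, reg_cfg, run_registration = TRUE) {
  invivo <- make_invivo_phantom(spec)
  exvivo <- make_exvivo_pair(spec, invivo$labels)
  segres <- segment_pair(invivo, exvivo, spec, seg)
  scar_recovery_in <- sum(scar_mask(segres$labels_in)) /
    max(1, sum(scar_mask(invivo$labels)))
  scar_recovery_ex <- sum(scar_mask(segres$labels_ex)) /
    max(1, sum(scar_mask(exvivo$labels)))
  labels_in <- segres$labels_in
  labels_ex <- segres$labels_ex
  labels_ex_ds <- downsample_labels(labels_ex, spec$invivo_voxel)

  dims_in <- measure_lv_dimensions(labels_in)
  dims_ex <- measure_lv_dimensions(labels_ex)
  vols_in <- compartment_volumes(labels_in)
  vols_ex_ds <- compartment_volumes(labels_ex_ds)

  morpho_in <- lv_morphometry(labels_in)
  morpho_ex <- lv_morphometry(labels_ex)
  t_lm <- fit_rigid_landmarks(exvivo$landmarks, invivo$landmarks)
  # native comparison: ex-vivo meshes brought into the in-vivo frame by the
  # inverse landmark rigid transform
  endo_ex_nat <- transform_mesh(morpho_ex$endo, invert_transform(t_lm))
  thick <- thickness_change_by_bin(morpho_in$endo, endo_ex_nat)
  dice_scar_rigid <- nodal_dice_scar(morpho_in$endo, endo_ex_nat)

  out <- list(
    long_axis_ratio = unname(dims_ex["long_axis_mm"] / dims_in["long_axis_mm"]),
    short_axis_ratio = unname(mean(dims_ex[2:3]) / mean(dims_in[2:3])),
    dims_in = dims_in, dims_ex = dims_ex,
    vols_in = vols_in, vols_ex_ds = vols_ex_ds,
    thickness_change = thick,
    mean_thickness_in_healthy =
      mean(morpho_in$endo$attributes$thickness_mm[!morpho_in$endo$attributes$scar_flag]),
    nodal_dice_scar_rigid = dice_scar_rigid,
    landmark_rms = attr(t_lm, "rms"),
    scar_recovery_in = scar_recovery_in,
    scar_recovery_ex = scar_recovery_ex,
    n_voxels_in = prod(dim(labels_in$data)),
    n_endo_nodes = nrow(morpho_in$endo$vertices)
  )
  if (run_registration) {
    chain <- coregister_pair(labels_in, labels_ex_ds, invivo$landmarks,
                             exvivo$landmarks, reg_cfg)
    reg <- chain$registered
    out$dice_wall <- voxel_dice(wall_mask(labels_in), wall_mask(reg))
    out$dice_cavity <- voxel_dice(cavity_mask(labels_in), cavity_mask(reg))
    morpho_reg <- lv_morphometry(reg)
    out$nodal_dice_scar_ffd <- nodal_dice_scar(morpho_in$endo, morpho_reg$endo)
    vols_reg <- compartment_volumes(reg)
    out$wall_volume_ratio <- vols_in$wall_ml / vols_reg$wall_ml
    out$cavity_volume_ratio <- vols_in$cavity_ml / vols_reg$cavity_ml
    out$vols_reg <- vols_reg
    out$metric_trace <- attr(chain$ffd, "metric_trace")
    out$transforms <- chain[c("landmark", "rigid", "affine", "ffd")]
  }
  out
}

#' Run the full simulated experiment
#'
#' For each replicate (seed = global seed + replicate index - 1): generate
#' a phantom pair, segment scar in both conditions, downsample the ex-vivo
#' labels, run the landmark/rigid/affine/FFD chain, and measure native and
#' post-registration morphometry. Results are aggregated over replicates
#' into a comparison report; artifacts and a run manifest are written when
#' an output directory is configured.
#'
#' @param config a [pipeline_config()].
#' @return comparison report (list), invisibly also written as JSON when
#'   `config$outdir` is set.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  reps <- list()
  timings <- numeric(0)
  for (i in seq_len(config$n_replicates)) {
    seed_i <- config$seed + i - 1L
    spec_i <- if (config$jitter) jitter_phantom_spec(config$phantom, seed_i)
              else { s <- config$phantom; s$seed <- as.integer(seed_i); s }
    t0 <- Sys.time()
    reps[[i]] <- replicate_analysis(spec_i, config$seg, config$reg,
                                    config$registration)
    timings[i] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  report <- aggregate_report(reps)
  report$n_replicates <- config$n_replicates
  report$seed <- config$seed
  if (!is.null(config$outdir)) write_report(report, reps, config, timings)
  report
}

pull <- function(reps, what) vapply(reps, function(r) r[[what]], numeric(1))

aggregate_report <- function(reps) {
  n <- length(reps)
  lar <- pull(reps, "long_axis_ratio")
  sar <- pull(reps, "short_axis_ratio")
  cav_in <- vapply(reps, function(r) r$vols_in$cavity_ml, numeric(1))
  cav_ex <- vapply(reps, function(r) r$vols_ex_ds$cavity_ml, numeric(1))
  wall_in <- vapply(reps, function(r) r$vols_in$wall_ml, numeric(1))
  wall_ex <- vapply(reps, function(r) r$vols_ex_ds$wall_ml, numeric(1))
  scar_in <- vapply(reps, function(r) r$vols_in$scar_ml, numeric(1))
  scar_ex <- vapply(reps, function(r) r$vols_ex_ds$scar_ml, numeric(1))
  bins <- c("healthy", "low", "high")
  thick <- sapply(bins, function(b) {
    mean(vapply(reps, function(r) {
      tc <- r$thickness_change
      tc$mean_pct[tc$bin == b]
    }, numeric(1)))
  })
  rep <- list(
    long_axis_ratio = mean(lar), short_axis_ratio = mean(sar),
    long_axis_ratio_sd = sd(lar), short_axis_ratio_sd = sd(sar),
    cavity_ratio = if (n >= 2) paired_ratio_test(cav_in, cav_ex) else
      list(mean_ratio = mean(cav_ex / cav_in)),
    scar_regression = if (n >= 2) regression(scar_in, scar_ex) else NULL,
    scar_fraction_in = mean(scar_in / wall_in),
    scar_fraction_ex = mean(scar_ex / wall_ex),
    thickness_change_pct = as.list(thick),
    mean_thickness_in_healthy = mean(pull(reps, "mean_thickness_in_healthy")),
    nodal_dice_scar_rigid = mean(pull(reps, "nodal_dice_scar_rigid"))
  )
  if (n >= 2) {
    per_rep <- do.call(rbind, lapply(seq_along(reps), function(i) {
      tc <- reps[[i]]$thickness_change
      data.frame(rep = i, bin = tc$bin, mean_pct = tc$mean_pct)
    }))
    per_rep <- per_rep[is.finite(per_rep$mean_pct), ]
    if (nlevels(factor(per_rep$bin)) >= 2)
      rep$thickness_anova <- anova_tukey(per_rep$mean_pct, per_rep$bin)
  }
  if (!is.null(reps[[1]]$dice_wall)) {
    rep$dice_wall <- mean(pull(reps, "dice_wall"))
    rep$dice_cavity <- mean(pull(reps, "dice_cavity"))
    rep$nodal_dice_scar_ffd <- mean(pull(reps, "nodal_dice_scar_ffd"))
    rep$wall_volume_ratio <- mean(pull(reps, "wall_volume_ratio"))
    rep$cavity_volume_ratio <- mean(pull(reps, "cavity_volume_ratio"))
  }
  rep
}

write_report <- function(report, reps, config, timings) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  strip <- function(x) {
    if (is.list(x)) lapply(x[!vapply(x, is.function, logical(1))], strip)
    else x
  }
  jsonlite::write_json(strip(report), file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  cfg_path <- file.path(config$outdir, "config.yaml")
  write_config(unclass(config), cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("lvcoreg")),
    seed = config$seed,
    replicate_seconds = timings,
    files = list()
  )
  per_rep <- do.call(rbind, lapply(seq_along(reps), function(i) {
    r <- reps[[i]]
    data.frame(replicate = i, long_axis_ratio = r$long_axis_ratio,
               short_axis_ratio = r$short_axis_ratio,
               cavity_ml_in = r$vols_in$cavity_ml,
               cavity_ml_ex = r$vols_ex_ds$cavity_ml,
               wall_ml_in = r$vols_in$wall_ml,
               scar_ml_in = r$vols_in$scar_ml,
               dice_wall = r$dice_wall %||% NA_real_,
               dice_cavity = r$dice_cavity %||% NA_real_,
               nodal_dice_scar_ffd = r$nodal_dice_scar_ffd %||% NA_real_,
               nodal_dice_scar_rigid = r$nodal_dice_scar_rigid)
  }))
  rep_path <- file.path(config$outdir, "replicates.csv")
  write.csv(per_rep, rep_path, row.names = FALSE)
  manifest$files <- as.list(tools::md5sum(c(cfg_path, rep_path,
                                            file.path(config$outdir, "report.json"))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
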