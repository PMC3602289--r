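#' Least-squares rigid fit between paired point sets (Kabsch)
#'
#' @param source,target n x 3 matrices of paired points.
#' @return A [rigid_transform()] minimizing the RMS of `T(source) - target`.
#' @export
fit_rigid_points <- function(source, target) {
  P <- unname(as.matrix(source)); Q <- unname(as.matrix(target))
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L) stop("need paired n x 3 point sets")
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2L, cp), sweep(Q, 2L, cq))
  sv <- svd(H)
  d <- det(sv$v %*% t(sv$u))
  R <- sv$v %*% diag(c(1, 1, sign(d))) %*% t(sv$u)
  rigid_transform(R, cq - as.numeric(R %*% cp))
}

#' Global rigid baseline between two spines
#'
#' The single best rigid transform over the full vertebral frame sets: each
#' frame contributes its center plus three axis-offset points (center +
#' 20 mm along each axis), and one Kabsch fit is made over all of them. This
#' is the rigid-registration comparator the articulated and proposed methods
#' are measured against.
#'
#' @param mri_frames,xray_frames Lists of [vertebra_frame()] (source, target).
#' @param axis_scale Offset (mm) of the axis points (default 20).
#' @return A [rigid_transform()].
#' @export
fit_global_rigid <- function(mri_frames, xray_frames, axis_scale = 20) {
  pts <- function(frames) do.call(rbind, lapply(frames, function(f)
    rbind(f$center,
          f$center + axis_scale * f$axes[, 1],
          f$center + axis_scale * f$axes[, 2],
          f$center + axis_scale * f$axes[, 3])))
  fit_rigid_points(pts(mri_frames), pts(xray_frames))
}

#' Default phantom-study pipeline configuration
#'
#' The study conditions of the phantom experiment: a ~50-degree right
#' thoracic curve (apex T9) over 17 vertebrae at 24 mm spacing (~400 mm
#' trunk), prone perturbations of up to 3 degrees / 2 mm per joint with 0.85
#' anterior compression, 12 mm axial slice spacing at 1 x 1 mm in-plane, an
#' interpolating TP/X-ray marker TPS and a lightly regularized
#' (`lambda = 1e-3`) edge TPS with 30-degree correspondence rays.
#'
#' @param seed Integer seed.
#' @return A named list accepted by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       cobb_deg = 50, apex = "T9", axial_rot = 15,
       spacing = 24,
       prone_bounds = list(max_rot_deg = 3, max_trans_mm = 2),
       body = list(rx = 140, ry = 100, anterior_offset = 40),
       compression = 0.85,
       slice_spacing = 12, inplane = 1,
       lambda_markers = 0, lambda_edge = 1e-3, angular_step = 30,
       methods = c("rigid", "articulated", "proposed"),
       voxel_spacing = c(1, 1, 3), contour_points = 72,
       do_3d = FALSE, test = "wilcoxon")
}

tp_mask_for_slice <- function(slice, tp_mesh) {
  vidx <- which(slice$vertebra_mask, arr.ind = TRUE)
  vij <- colMeans(vidx) - 1
  vcen_world <- slice$origin + vij[1] * slice$spacing[1] * slice$e1 +
    vij[2] * slice$spacing[2] * slice$e2
  cut <- planar_cut(tp_mesh, list(point = slice$origin, normal = slice$normal),
                    inner_point = vcen_world)
  uv <- contour_in_slice_coords(cut$points, slice)
  rasterize_polygon_mask(uv, nrow(slice$torso_mask), ncol(slice$torso_mask),
                         slice$spacing)
}

#' Run the end-to-end phantom registration study
#'
#' Generates the standing and prone phantoms, registers surface topography
#' to X-ray space with the marker thin-plate spline, builds the MRI and
#' X-ray articulated models from their landmark sets, carries every axial
#' slice into standing space with each selected method (global rigid
#' baseline, articulated bone transform, or the proposed
#' articulated-plus-weighted-TPS registration), and scores each slice's
#' torso mask against the surface-topography planar cut with the Dice
#' coefficient. Optionally rebuilds the registered torso volume and computes
#' the volumetric Dice against the voxelized TP surface.
#'
#' @param config List from [pipeline_config()] (fields may be overridden).
#' @param out_dir Optional output directory; when given, landmarks, meshes,
#'   transforms, slice stacks, reports and a run manifest are written there.
#' @return An object of class `pipeline_result`: `reports` (named list of
#'   [dice_report()]), `comparison` ([compare_methods()] output), `dice_3d`
#'   (when `do_3d`), `registrations` (per-slice outputs of the proposed
#'   method), `phantoms`, `transforms`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  t_start <- proc.time()[["elapsed"]]
  cfg <- utils::modifyList(pipeline_config(config$seed %||% 1L), config)
  timings <- c()
  tick <- function(stage, t0) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  t0 <- proc.time()[["elapsed"]]
  amp <- amplitude_for_cobb(cfg$cobb_deg, apex = cfg$apex,
                            axial_rot = cfg$axial_rot, spacing = cfg$spacing)
  curv <- list(amplitude = amp, apex = cfg$apex, axial_rot = cfg$axial_rot)
  standing <- generate_spine(curv, "standing", seed = cfg$seed, spacing = cfg$spacing,
                             prone_bounds = cfg$prone_bounds)
  prone <- generate_spine(curv, "prone", seed = cfg$seed, spacing = cfg$spacing,
                          prone_bounds = cfg$prone_bounds)
  torso_standing <- generate_torso(standing, cfg$body, seed = cfg$seed)
  body_prone <- cfg$body; body_prone$compression <- cfg$compression
  torso_prone <- generate_torso(prone, body_prone, seed = cfg$seed)
  torso_prone <- generate_axial_slices(prone, torso_prone,
                                       spacing_mm = cfg$slice_spacing,
                                       inplane = cfg$inplane)
  tick("phantom", t0)

  t0 <- proc.time()[["elapsed"]]
  tp_reg <- register_tp_to_xray(torso_standing$markers, torso_standing$markers,
                                torso_standing$surface, lambda = cfg$lambda_markers)
  tp_mesh <- tp_reg$mesh
  tick("tp_xray", t0)

  t0 <- proc.time()[["elapsed"]]
  labels <- names(standing$xray_landmarks)
  xray_frames <- lapply(labels, function(l)
    frame_from_xray_landmarks(standing$xray_landmarks[[l]], label = l))
  mri_frames <- lapply(labels, function(l)
    frame_from_mri_landmarks(prone$mri_landmarks[[l]], label = l))
  mri_model <- build_articulated(mri_frames, "MRI")
  xray_model <- build_articulated(xray_frames, "Xray")
  bone <- cross_modality_transforms(mri_model, xray_model)
  global_rigid <- fit_global_rigid(mri_frames, xray_frames)
  tick("articulated", t0)

  t0 <- proc.time()[["elapsed"]]
  slices <- torso_prone$slices
  n <- length(slices)
  dice <- list()
  registrations <- vector("list", n)
  for (m in cfg$methods) dice[[m]] <- numeric(n)
  for (k in seq_len(n)) {
    sl <- slices[[k]]
    tf <- bone[[sl$vertebra]]
    if ("rigid" %in% cfg$methods) {
      s_r <- apply_articulated_to_slice(sl, global_rigid)
      dice$rigid[k] <- dice_2d(s_r$torso_mask, tp_mask_for_slice(s_r, tp_mesh))
    }
    if ("articulated" %in% cfg$methods) {
      s_a <- apply_articulated_to_slice(sl, tf)
      dice$articulated[k] <- dice_2d(s_a$torso_mask, tp_mask_for_slice(s_a, tp_mesh))
    }
    if ("proposed" %in% cfg$methods) {
      reg <- register_slice(sl, tf, tp_mesh, lambda = cfg$lambda_edge,
                            angular_step = cfg$angular_step)
      registrations[[k]] <- reg
      dice$proposed[k] <- dice_2d(reg$slice$torso_mask, reg$tp_mask)
    }
  }
  reports <- lapply(names(dice), function(m) dice_report(dice[[m]], m))
  names(reports) <- names(dice)
  comparison <- compare_methods(reports, test = cfg$test)
  tick("registration", t0)

  d3 <- NULL
  if (isTRUE(cfg$do_3d) && "proposed" %in% cfg$methods) {
    t0 <- proc.time()[["elapsed"]]
    contours <- lapply(registrations, function(reg) {
      uv <- reg$warped_contour
      s <- reg$slice
      sweep(uv[, 1, drop = FALSE] %*% rbind(s$e1) +
            uv[, 2, drop = FALSE] %*% rbind(s$e2), 2L, -s$origin)
    })
    mri_mesh <- build_torso_mesh(contours, n_points = cfg$contour_points)
    vol_mri <- voxelize(mri_mesh, spacing = cfg$voxel_spacing)
    vol_tp <- voxelize(tp_mesh, spacing = cfg$voxel_spacing)
    # align grids: re-origin both to the joint bounding box via common spacing
    d3 <- dice_3d(vol_mri, vol_tp)
    tick("dice3d", t0)
  }

  manifest <- list(config = cfg,
                   version = as.character(utils::packageVersion("torsofuse")),
                   seed = cfg$seed,
                   timings_s = as.list(timings),
                   total_s = round(proc.time()[["elapsed"]] - t_start, 3),
                   checksums = list())
  result <- structure(list(reports = reports, comparison = comparison,
                           dice_3d = d3, registrations = registrations,
                           phantoms = list(standing = standing, prone = prone,
                                           torso_standing = torso_standing,
                                           torso_prone = torso_prone),
                           transforms = list(bone = bone, global_rigid = global_rigid,
                                             tp_xray = tp_reg$model),
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) result <- write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$comparison)
  if (!is.null(x$dice_3d)) cat(sprintf("3D Dice (proposed): %.4f\n", x$dice_3d))
  invisible(x)
}
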