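#' Read and write landmark / marker CSV files
#'
#' The on-disk format is a plain CSV with columns `name`, `vertebra`, `x`,
#' `y`, `z`, `modality` (the last two optional on read). `write_landmarks`
#' accepts a matrix with row names (markers) or a named list of per-vertebra
#' matrices (vertebral landmark sets).
#'
#' @param x Matrix with row names, or named list of such matrices.
#' @param path CSV path.
#' @param modality Optional modality tag written with every row.
#' @return `read_landmarks`: a data frame; `landmarks_to_matrices`: a named
#'   list of per-vertebra matrices (or a single matrix when no vertebra
#'   column is present).
#' @export
write_landmarks <- function(x, path, modality = NA_character_) {
  rows <- if (is.list(x) && !is.data.frame(x)) {
    do.call(rbind, lapply(names(x), function(v) {
      m <- as.matrix(x[[v]])
      data.frame(name = rownames(m), vertebra = v,
                 x = m[, 1], y = m[, 2], z = m[, 3],
                 modality = modality, row.names = NULL)
    }))
  } else {
    m <- as.matrix(x)
    data.frame(name = rownames(m), vertebra = NA_character_,
               x = m[, 1], y = m[, 2], z = m[, 3],
               modality = modality, row.names = NULL)
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed landmark CSV '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z)) {
    bad <- which(is.na(df$x) | is.na(df$y) | is.na(df$z))[1]
    stop("malformed landmark CSV '", path, "': non-numeric coordinates at record ", bad)
  }
  df
}

#' @rdname write_landmarks
#' @param df Data frame from [read_landmarks()].
#' @export
landmarks_to_matrices <- function(df) {
  tomat <- function(d) {
    m <- as.matrix(d[, c("x", "y", "z")])
    rownames(m) <- d$name
    m
  }
  if (!"vertebra" %in% names(df) || all(is.na(df$vertebra))) return(tomat(df))
  sp <- split(df, df$vertebra)
  out <- lapply(sp, tomat)
  out[unique(df$vertebra)]
}

#' Read and write Wavefront OBJ triangle meshes
#'
#' Minimal OBJ support (`v` and `f` records, triangular faces) — sufficient
#' to round-trip torso surfaces losslessly at full double precision.
#'
#' @param mesh A [surface_mesh()].
#' @param path OBJ path.
#' @return `read_mesh_obj`: a [surface_mesh()].
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_mesh_obj
#' @export
read_mesh_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (!length(vl) || !length(fl))
    stop("malformed OBJ '", path, "': no vertex or face records")
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(t) as.numeric(t[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(t)
    as.integer(sub("/.*", "", t[2:4]))))
  if (anyNA(verts) || anyNA(faces))
    stop("malformed OBJ '", path, "': unparseable record")
  surface_mesh(verts, faces)
}

#' Read and write transforms as JSON
#'
#' Rigid transforms are stored as a row-major 4x4 homogeneous matrix;
#' thin-plate spline models store control points, affine coefficients,
#' kernel weights, lambda and the kernel tag.
#'
#' @param tf A [rigid_transform()] or `tps_model`.
#' @param path JSON path.
#' @return `read_transform_json`: the reconstructed object.
#' @export
write_transform_json <- function(tf, path) {
  obj <- if (inherits(tf, "rigid_transform")) {
    list(type = "rigid", matrix = as.numeric(t(rigid_to_matrix(tf))))
  } else if (inherits(tf, "tps_model")) {
    list(type = "tps", dim = tf$dim, kernel = tf$kernel, lambda = tf$lambda,
         control_points = tf$control_points, affine = tf$affine,
         weights = tf$weights)
  } else stop("unsupported transform type")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "rigid")) {
    rigid_from_matrix(matrix(obj$matrix, 4, 4, byrow = TRUE))
  } else if (identical(obj$type, "tps")) {
    structure(list(control_points = as.matrix(obj$control_points),
                   weights = as.matrix(obj$weights),
                   affine = as.matrix(obj$affine),
                   lambda = obj$lambda, dim = obj$dim, kernel = obj$kernel),
              class = "tps_model")
  } else stop("malformed transform JSON '", path, "'")
}

#' Write / read an axial slice stack as NIfTI masks plus a JSON pose sidecar
#'
#' Each slice's torso and vertebra masks are written as uint8 NIfTI volumes
#' (`<prefix>_torso_###.nii.gz`, `<prefix>_vertebra_###.nii.gz`); the sidecar
#' `<prefix>_poses.json` holds every slice's 4x4 pixel-to-world pose,
#' vertebra label, spacing and thickness.
#'
#' @param slices List of [axial_slice()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"slice"`).
#' @return `read_slices_nifti`: the reconstructed list of [axial_slice()].
#' @export
write_slices_nifti <- function(slices, dir, prefix = "slice") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- vector("list", length(slices))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    tpath <- file.path(dir, sprintf("%s_torso_%03d.nii.gz", prefix, k))
    vpath <- file.path(dir, sprintf("%s_vertebra_%03d.nii.gz", prefix, k))
    arr <- array(as.integer(s$torso_mask), dim = c(dim(s$torso_mask), 1L))
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), tpath)
    arr <- array(as.integer(s$vertebra_mask), dim = c(dim(s$vertebra_mask), 1L))
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), vpath)
    meta[[k]] <- list(index = s$index, pose = as.numeric(t(slice_pose(s))),
                      spacing = s$spacing, vertebra = s$vertebra,
                      thickness = s$thickness,
                      torso = basename(tpath), vertebra_mask = basename(vpath))
  }
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_poses.json")),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_slices_nifti
#' @export
read_slices_nifti <- function(dir, prefix = "slice") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_poses.json")),
                              simplifyVector = FALSE)
  lapply(meta, function(m) {
    pose <- matrix(unlist(m$pose), 4, 4, byrow = TRUE)
    as_mask <- function(img) {
      a <- as.array(img)
      if (length(dim(a)) > 2L) a <- a[, , 1L]
      matrix(as.logical(a), nrow(a), ncol(a))
    }
    tm <- as_mask(RNifti::readNifti(file.path(dir, m$torso)))
    vm <- as_mask(RNifti::readNifti(file.path(dir, m$vertebra_mask)))
    sp <- unlist(m$spacing)
    axial_slice(index = m$index,
                origin = pose[1:3, 4],
                e1 = pose[1:3, 1] / sp[1], e2 = pose[1:3, 2] / sp[2],
                normal = pose[1:3, 3],
                spacing = sp,
                torso_mask = tm,
                vertebra_mask = vm,
                vertebra = m$vertebra, thickness = m$thickness)
  })
}

#' Write a deformation field as a NIfTI vector image
#' @param field A `deformation_field`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_field_nifti <- function(field, path) {
  arr <- array(0, dim = c(dim(field$ux), 1L, 1L, 2L))
  arr[, , 1L, 1L, 1L] <- field$ux
  arr[, , 1L, 1L, 2L] <- field$uy
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Read/write the pipeline YAML configuration
#' @param path YAML path.
#' @return `read_config`: a config list for [run_pipeline()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  cfg <- yaml::read_yaml(path)
  utils::modifyList(pipeline_config(cfg$seed %||% 1L), cfg)
}

#' @rdname read_config
#' @param config Config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write all pipeline artifacts plus a run manifest
#'
#' Writes the Dice reports (CSV + JSON), per-vertebra bone transforms, the
#' TP/X-ray TPS, the global rigid baseline, phantom landmark CSVs, torso
#' meshes (OBJ), the slice stack (NIfTI + pose sidecar) and a
#' `manifest.json` with the config snapshot, package version, seed, stage
#' timings and md5 checksums of every written file.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return The `pipeline_result` with its manifest updated.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  add <- function(p) paths <<- c(paths, p)

  per <- do.call(rbind, lapply(result$reports, function(r)
    cbind(method = r$method, r$per_slice)))
  p <- file.path(out_dir, "dice_report.csv")
  utils::write.csv(per, p, row.names = FALSE); add(p)
  p <- file.path(out_dir, "dice_report.json")
  jsonlite::write_json(
    lapply(result$reports, function(r)
      list(method = r$method, mean = r$mean, variance = r$variance,
           per_slice = r$per_slice)),
    p, digits = NA, auto_unbox = TRUE, dataframe = "rows"); add(p)

  tdir <- file.path(out_dir, "transforms")
  dir.create(tdir, showWarnings = FALSE)
  for (v in names(result$transforms$bone)) {
    p <- file.path(tdir, paste0("bone_", v, ".json"))
    write_transform_json(result$transforms$bone[[v]], p); add(p)
  }
  p <- file.path(tdir, "global_rigid.json")
  write_transform_json(result$transforms$global_rigid, p); add(p)
  p <- file.path(tdir, "tp_xray_tps.json")
  write_transform_json(result$transforms$tp_xray, p); add(p)

  ph <- result$phantoms
  p <- file.path(out_dir, "xray_landmarks_standing.csv")
  write_landmarks(ph$standing$xray_landmarks, p, modality = "Xray"); add(p)
  p <- file.path(out_dir, "mri_landmarks_prone.csv")
  write_landmarks(ph$prone$mri_landmarks, p, modality = "MRI"); add(p)
  p <- file.path(out_dir, "markers_tp.csv")
  write_landmarks(ph$torso_standing$markers, p, modality = "TP"); add(p)
  p <- file.path(out_dir, "torso_standing.obj")
  write_mesh_obj(ph$torso_standing$surface, p); add(p)
  p <- file.path(out_dir, "torso_prone.obj")
  write_mesh_obj(ph$torso_prone$surface, p); add(p)
  sdir <- file.path(out_dir, "slices")
  write_slices_nifti(ph$torso_prone$slices, sdir)
  add(list.files(sdir, full.names = TRUE))

  manifest <- result$manifest
  manifest$checksums <- as.list(tools::md5sum(unlist(paths)))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, digits = NA, auto_unbox = TRUE)
  result$manifest <- manifest
  result
}
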