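#' Articulated spine model
#'
#' Represents the spine of one modality as a chain of rigid transforms: the
#' world-to-first-vertebra transform plus 16 local intervertebral transforms
#' between consecutive vertebral frames. Global per-vertebra transforms are
#' the right-to-left composition of the chain:
#' `T(0,v) = T(v-1,v) o ... o T(1,2) o T(0,1)`, where "o" applies the
#' right-hand transform first ([compose_rigid()]).
#'
#' @param frames List of 17 [vertebra_frame()] in anatomical order (inferior
#'   to superior).
#' @param modality `"MRI"` or `"Xray"` tag.
#' @return An object of class `articulated_model` with `frames`, `modality`,
#'   `world_to_first`, `locals` (16), `globals` (17).
#' @export
build_articulated <- function(frames, modality = c("MRI", "Xray")) {
  modality <- match.arg(modality)
  if (!is.list(frames) || length(frames) != 17L)
    stop("expected exactly 17 vertebral frames, got ", length(frames))
  ok <- vapply(frames, inherits, logical(1), what = "vertebra_frame")
  if (!all(ok)) stop("all elements must be vertebra_frame objects")
  poses <- lapply(frames, frame_pose)
  world_to_first <- poses[[1]]
  locals <- lapply(seq_len(16L), function(v) rigid_between(frames[[v]], frames[[v + 1L]]))
  globals <- vector("list", 17L)
  globals[[1]] <- world_to_first
  for (v in seq_len(16L))
    globals[[v + 1L]] <- compose_rigid(locals[[v]], globals[[v]])
  structure(list(frames = frames, modality = modality,
                 world_to_first = world_to_first,
                 locals = locals, globals = globals),
            class = "articulated_model")
}

#' @export
print.articulated_model <- function(x, ...) {
  cat(sprintf("articulated_model (%s): %d vertebrae, %s ... %s\n",
              x$modality, length(x$frames),
              x$frames[[1]]$label, x$frames[[length(x$frames)]]$label))
  invisible(x)
}

#' Per-vertebra cross-modality bone transforms
#'
#' For each vertebra v, the rigid transform taking the MRI vertebral frame
#' onto its X-ray counterpart: the concatenation of the global X-ray
#' transform with the inverse global MRI transform,
#' `T(v, MRI-bone) = T(0,v; Xray) o T(0,v; MRI)^-1`. Applying it to the MRI
#' frame reproduces the X-ray frame; the same transform carries each axial
#' MRI slice into standing X-ray space.
#'
#' @param mri,xray `articulated_model` objects with matching vertebra labels.
#' @return Named list of 17 [rigid_transform()], one per vertebra.
#' @export
cross_modality_transforms <- function(mri, xray) {
  if (!inherits(mri, "articulated_model") || !inherits(xray, "articulated_model"))
    stop("expected two articulated_model objects")
  lm <- vapply(mri$frames, function(f) f$label, "")
  lx <- vapply(xray$frames, function(f) f$label, "")
  if (!identical(lm, lx))
    stop("vertebra label mismatch between MRI and X-ray models")
  out <- lapply(seq_along(lm), function(v)
    compose_rigid(xray$globals[[v]], invert_rigid(mri$globals[[v]])))
  names(out) <- lm
  out
}

#' Assign an axial slice to its nearest vertebra
#'
#' Returns the label of the vertebra whose frame center has the closest z
#' value to the slice; equidistant ties go to the inferior vertebra.
#'
#' @param slice_z Slice z position (mm), or an [axial_slice()] (its
#'   torso-mask centroid mapped to world supplies z, so the assignment
#'   survives arbitrary slice poses).
#' @param frames List of [vertebra_frame()] ordered inferior to superior.
#' @return Vertebra label.
#' @export
assign_slice_vertebra <- function(slice_z, frames) {
  if (inherits(slice_z, "axial_slice")) slice_z <- slice_centroid_world(slice_z)[3]
  zc <- vapply(frames, function(f) f$center[3], 0)
  d <- abs(zc - slice_z)
  frames[[which.min(d)]]$label   # which.min takes the first = inferior on ties
}

slice_centroid_world <- function(slice) {
  idx <- which(slice$torso_mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("slice has an empty torso mask")
  ij <- colMeans(idx) - 1
  slice$origin + ij[1] * slice$spacing[1] * slice$e1 +
    ij[2] * slice$spacing[2] * slice$e2
}

#' Apply a rigid transform to an axial slice (pose-only reslicing)
#'
#' Pre-multiplies the slice's world pose by the transform; the pixel data are
#' untouched, so in-plane pixel geometry (and hence vertebra rigidity) is
#' preserved exactly and the slice remains planar.
#'
#' @param slice An [axial_slice()].
#' @param transform A [rigid_transform()].
#' @return The resliced [axial_slice()].
#' @export
apply_articulated_to_slice <- function(slice, transform) {
  assert_rigid(transform)
  slice$origin <- apply_rigid(transform, slice$origin)
  slice$e1 <- as.numeric(transform$rotation %*% slice$e1)
  slice$e2 <- as.numeric(transform$rotation %*% slice$e2)
  slice$normal <- as.numeric(transform$rotation %*% slice$normal)
  slice
}
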