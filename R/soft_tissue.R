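#' Extract the boundary contour of a binary mask
#'
#' Marching-squares contour (level 0.5) of a mask, returned as an ordered
#' closed polygon in the slice's in-plane mm coordinates (pixel (1,1) center
#' at the origin). When the mask has several boundary loops the longest is
#' returned.
#'
#' @param mask Binary matrix (dimension 1 = in-plane axis 1).
#' @param spacing In-plane pixel size, mm (length 2 or scalar).
#' @return k x 2 matrix of contour points (mm).
#' @export
mask_contour <- function(mask, spacing = c(1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (!any(mask)) stop("mask is empty")
  gx <- (seq_len(nrow(mask)) - 1) * spacing[1]
  gy <- (seq_len(ncol(mask)) - 1) * spacing[2]
  cl <- grDevices::contourLines(x = gx, y = gy, z = mask * 1, levels = 0.5)
  if (!length(cl)) stop("mask has no boundary contour")
  lens <- vapply(cl, function(c) length(c$x), 0L)
  best <- cl[[which.max(lens)]]
  pts <- cbind(best$x, best$y)
  if (sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < 1e-9)
    pts <- pts[-nrow(pts), , drop = FALSE]
  pts
}

rotate2 <- function(v, theta_deg) {
  th <- theta_deg * pi / 180
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
}

ray_outermost_crossing <- function(center, dir, poly) {
  p1 <- poly
  p2 <- poly[c(seq_len(nrow(poly))[-1], 1L), , drop = FALSE]
  e <- p2 - p1
  w <- sweep(p1, 2L, center)
  denom <- dir[1] * e[, 2] - dir[2] * e[, 1]
  s_num <- w[, 1] * dir[2] - w[, 2] * dir[1]
  t_num <- w[, 1] * e[, 2] - w[, 2] * e[, 1]
  ok <- abs(denom) > 1e-12
  s <- ifelse(ok, s_num / denom, NA_real_)
  t <- ifelse(ok, t_num / denom, NA_real_)
  hit <- ok & s >= 0 & s < 1 & t > 1e-9
  if (!any(hit, na.rm = TRUE)) return(NA_real_)
  max(t[hit], na.rm = TRUE)
}

#' Radial correspondence points between an MRI contour and a TP cut
#'
#' Casts rays from the vertebra center at fixed angular intervals (default
#' 30 degrees, i.e. 12 rays), angle 0 pointing along the anterior direction
#' of the vertebra, and pairs the outermost crossing of each ray with the MRI
#' torso contour (source) and with the planar surface-topography contour
#' (target). These pairs drive the per-slice edge thin-plate spline.
#'
#' @param mri_contour k x 2 polygon of the MRI torso boundary (in-plane mm),
#'   or a binary mask (then `spacing` applies).
#' @param tp_contour k x 2 polygon of the TP planar cut in the same in-plane
#'   coordinates.
#' @param vertebra_center Length-2 in-plane position of the vertebra center;
#'   must lie inside both contours.
#' @param anterior_dir Length-2 in-plane anterior direction (angle 0).
#' @param angular_step Degrees between rays; must divide 360.
#' @param spacing Pixel size when `mri_contour` is a mask.
#' @return An object of class `correspondence_set`: `angles` (deg), `source`
#'   and `target` (k x 2 matrices), `center`, `anterior`.
#' @export
extract_ray_correspondences <- function(mri_contour, tp_contour, vertebra_center,
                                        anterior_dir, angular_step = 30,
                                        spacing = c(1, 1)) {
  if (is.matrix(mri_contour) && (is.logical(mri_contour) || ncol(mri_contour) != 2L))
    mri_contour <- mask_contour(mri_contour, spacing)
  if (360 %% angular_step != 0) stop("angular_step must divide 360")
  anterior_dir <- anterior_dir / sqrt(sum(anterior_dir^2))
  angles <- seq(0, 360 - angular_step, by = angular_step)
  k <- length(angles)
  src <- matrix(0, k, 2); tgt <- matrix(0, k, 2)
  for (i in seq_len(k)) {
    d <- rotate2(anterior_dir, angles[i])
    ts <- ray_outermost_crossing(vertebra_center, d, mri_contour)
    tt <- ray_outermost_crossing(vertebra_center, d, tp_contour)
    if (is.na(ts))
      stop("ray at angle ", angles[i], " deg does not cross the MRI contour (center outside?)")
    if (is.na(tt))
      stop("ray at angle ", angles[i], " deg does not cross the TP contour (center outside?)")
    src[i, ] <- vertebra_center + ts * d
    tgt[i, ] <- vertebra_center + tt * d
  }
  structure(list(angles = angles, source = src, target = tgt,
                 center = vertebra_center, anterior = anterior_dir),
            class = "correspondence_set")
}

#' Fit the per-slice edge thin-plate spline
#'
#' The preliminary contour-driven in-plane TPS mapping the MRI torso boundary
#' points onto their surface-topography counterparts, fitted with the same
#' linear system as the 3D marker registration (|r| kernel, 2D affine part).
#'
#' @param correspondences A `correspondence_set`.
#' @param lambda Regularization (mm); default `1e-3` — the edge transform is
#'   an approximation, not an exact interpolation.
#' @return A `tps_model` (2D).
#' @export
fit_edge_tps <- function(correspondences, lambda = 1e-3) {
  fit_tps(correspondences$source, correspondences$target, lambda = lambda)
}

mask_border <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  padded <- matrix(FALSE, nx + 2L, ny + 2L)
  padded[2:(nx + 1L), 2:(ny + 1L)] <- mask
  nb <- padded[1:nx, 2:(ny + 1L)] & padded[3:(nx + 2L), 2:(ny + 1L)] &
        padded[2:(nx + 1L), 1:ny] & padded[2:(nx + 1L), 3:(ny + 2L)]
  mask & !nb
}

#' Distance maps to the vertebra and torso borders
#'
#' Per-pixel Euclidean distances (mm) to the border of the vertebra mask and
#' to the border of the torso mask, exactly zero on the respective borders
#' (border = mask pixels 4-adjacent to the complement). These are the two
#' distances whose ratio weights the soft-tissue deformation.
#'
#' @param torso_mask,vertebra_mask Binary matrices on the same grid;
#'   `vertebra_mask` must be contained in `torso_mask`.
#' @param pixel_size Isotropic in-plane pixel size, mm.
#' @return List with matrices `d_vertebra` and `d_surface` (mm).
#' @export
distance_maps <- function(torso_mask, vertebra_mask, pixel_size = 1) {
  if (!any(torso_mask) || !any(vertebra_mask)) stop("empty mask")
  if (any(vertebra_mask & !torso_mask))
    stop("vertebra mask must be contained in the torso mask")
  dist_to_border <- function(mask) {
    b <- mask_border(mask)
    as.matrix(EBImage::distmap(1 - b)) * pixel_size
  }
  list(d_vertebra = dist_to_border(vertebra_mask),
       d_surface = dist_to_border(torso_mask))
}

#' Weighted (rigidity-constrained) soft-tissue deformation
#'
#' Container for the per-slice constrained deformation: the edge TPS plus the
#' two distance maps and the vertebra mask that gate it. The deformation of a
#' point p is the identity inside the vertebra and otherwise the
#' identity-blended TPS displacement `p + rho * (T_edge(p) - p)` with blend
#' weight `rho = D_vertebra / (D_surface + D_vertebra)` — zero on the
#' vertebra border (full rigidity), one on the torso surface (full TPS), and
#' graded in between so that more weight goes to the non-rigid deformation
#' the further a point lies from the vertebra.
#'
#' @param edge_model 2D `tps_model` from [fit_edge_tps()].
#' @param d_vertebra,d_surface Distance maps from [distance_maps()] (mm).
#' @param vertebra_mask Binary matrix.
#' @param spacing In-plane pixel size, mm (length 2 or scalar).
#' @return An object of class `weighted_deformation`.
#' @export
weighted_deformation <- function(edge_model, d_vertebra, d_surface,
                                 vertebra_mask, spacing = c(1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  structure(list(edge_model = edge_model, d_vertebra = d_vertebra,
                 d_surface = d_surface, vertebra_mask = vertebra_mask,
                 spacing = as.numeric(spacing)),
            class = "weighted_deformation")
}

interp_grid <- function(mat, ui, vj) {
  # bilinear interpolation at continuous pixel coordinates (1-based)
  nx <- nrow(mat); ny <- ncol(mat)
  ui <- pmin(pmax(ui, 1), nx); vj <- pmin(pmax(vj, 1), ny)
  i0 <- pmin(floor(ui), nx - 1L); j0 <- pmin(floor(vj), ny - 1L)
  fu <- ui - i0; fv <- vj - j0
  m <- function(i, j) mat[cbind(i, j)]
  (1 - fu) * (1 - fv) * m(i0, j0) + fu * (1 - fv) * m(i0 + 1L, j0) +
    (1 - fu) * fv * m(i0, j0 + 1L) + fu * fv * m(i0 + 1L, j0 + 1L)
}

#' Apply the weighted deformation to points
#'
#' @param p n x 2 matrix (or length-2 vector) of in-plane points, mm.
#' @param deformation A [weighted_deformation()].
#' @return Deformed points, same shape. Points inside the vertebra mask are
#'   returned unchanged; elsewhere the identity-blended TPS displacement is
#'   applied with the distance-ratio weight (distance maps interpolated
#'   bilinearly between pixel centers).
#' @export
weighted_displace <- function(p, deformation) {
  vec <- is.null(dim(p))
  pts <- if (vec) matrix(p, nrow = 1L) else unname(as.matrix(p))
  sp <- deformation$spacing
  ui <- pts[, 1] / sp[1] + 1; vj <- pts[, 2] / sp[2] + 1
  vm <- deformation$vertebra_mask
  nx <- nrow(vm); ny <- ncol(vm)
  ii <- pmin(pmax(round(ui), 1L), nx); jj <- pmin(pmax(round(vj), 1L), ny)
  inside <- vm[cbind(ii, jj)]
  dv <- interp_grid(deformation$d_vertebra, ui, vj)
  ds <- interp_grid(deformation$d_surface, ui, vj)
  rho <- ifelse(dv + ds > 0, dv / (ds + dv), 0)
  rho <- pmin(pmax(rho, 0), 1)
  rho[inside] <- 0
  warped <- evaluate_tps(deformation$edge_model, pts)
  out <- pts + rho * (warped - pts)
  out[inside, ] <- pts[inside, , drop = FALSE]
  if (vec) as.numeric(out) else out
}

#' Dense displacement field of a weighted deformation
#'
#' Evaluates the deformation at every pixel center of the slice grid and
#' returns the in-plane displacement components (mm). Pixels inside the
#' vertebra mask have exactly zero displacement.
#'
#' @param deformation A [weighted_deformation()].
#' @return An object of class `deformation_field`: `ux`, `uy` matrices (mm),
#'   `spacing`.
#' @export
dense_displacement_field <- function(deformation) {
  vm <- deformation$vertebra_mask
  nx <- nrow(vm); ny <- ncol(vm)
  sp <- deformation$spacing
  pu <- rep((seq_len(nx) - 1) * sp[1], times = ny)
  pv <- rep((seq_len(ny) - 1) * sp[2], each = nx)
  pts <- cbind(pu, pv)
  dv <- as.numeric(deformation$d_vertebra)
  ds <- as.numeric(deformation$d_surface)
  rho <- ifelse(dv + ds > 0, dv / (ds + dv), 0)
  rho <- pmin(pmax(rho, 0), 1)
  rho[as.logical(vm)] <- 0
  warped <- evaluate_tps(deformation$edge_model, pts)
  disp <- rho * (warped - pts)
  disp[as.logical(vm), ] <- 0
  structure(list(ux = matrix(disp[, 1], nx, ny),
                 uy = matrix(disp[, 2], nx, ny),
                 spacing = sp),
            class = "deformation_field")
}

rasterize_polygon_mask <- function(poly_uv, nx, ny, spacing) {
  pu <- rep((seq_len(nx) - 1) * spacing[1], times = ny)
  pv <- rep((seq_len(ny) - 1) * spacing[2], each = nx)
  matrix(point_in_polygon(pu, pv, poly_uv[, 1], poly_uv[, 2]), nx, ny)
}

contour_in_slice_coords <- function(points3, slice) {
  rel <- sweep(points3, 2L, slice$origin)
  cbind(as.numeric(rel %*% slice$e1), as.numeric(rel %*% slice$e2))
}

#' Register one axial MRI slice into standing patient space
#'
#' The full per-slice registration: the slice is carried into X-ray space by
#' its vertebra's articulated bone transform, the surface topography is cut
#' at the resliced plane, radial correspondences between the MRI torso
#' contour and the TP cut drive the edge TPS, and the distance-weighted
#' rigidity-constrained deformation warps the soft tissue while leaving the
#' vertebra untouched. The overall map is the composition soft-tissue-after-
#' bone.
#'
#' @param slice An [axial_slice()] (prone MRI geometry).
#' @param bone_transform The slice's per-vertebra [rigid_transform()] from
#'   [cross_modality_transforms()].
#' @param tp_mesh The standing-space torso [surface_mesh()] (surface
#'   topography after TP-to-X-ray registration).
#' @param lambda Edge-TPS regularization (default 1e-3).
#' @param angular_step Degrees between correspondence rays (default 30).
#' @return A list: `slice` (resliced, torso mask replaced by the warped
#'   mask), `deformation` ([weighted_deformation()]), `field` (dense
#'   [deformation_field][dense_displacement_field()]), `correspondences`,
#'   `tp_contour_uv` (TP cut in slice in-plane mm), `tp_mask` (TP cut
#'   interior rasterized on the slice grid), `warped_contour` (warped MRI
#'   torso boundary, in-plane mm).
#' @export
register_slice <- function(slice, bone_transform, tp_mesh,
                           lambda = 1e-3, angular_step = 30) {
  s2 <- apply_articulated_to_slice(slice, bone_transform)
  vidx <- which(s2$vertebra_mask, arr.ind = TRUE)
  if (!nrow(vidx)) stop("slice has an empty vertebra mask")
  vij <- colMeans(vidx) - 1
  vcen_uv <- c(vij[1] * s2$spacing[1], vij[2] * s2$spacing[2])
  vcen_world <- s2$origin + vcen_uv[1] * s2$e1 + vcen_uv[2] * s2$e2
  cut <- planar_cut(tp_mesh, list(point = s2$origin, normal = s2$normal),
                    inner_point = vcen_world)
  tp_uv <- contour_in_slice_coords(cut$points, s2)
  mri_uv <- mask_contour(s2$torso_mask, s2$spacing)
  corr <- extract_ray_correspondences(mri_uv, tp_uv, vcen_uv,
                                      anterior_dir = c(0, 1),
                                      angular_step = angular_step)
  edge <- fit_edge_tps(corr, lambda = lambda)
  dm <- distance_maps(s2$torso_mask, s2$vertebra_mask,
                      pixel_size = s2$spacing[1])
  wd <- weighted_deformation(edge, dm$d_vertebra, dm$d_surface,
                             s2$vertebra_mask, spacing = s2$spacing)
  field <- dense_displacement_field(wd)
  warped_contour <- weighted_displace(mri_uv, wd)
  nx <- nrow(s2$torso_mask); ny <- ncol(s2$torso_mask)
  warped_mask <- rasterize_polygon_mask(warped_contour, nx, ny, s2$spacing)
  tp_mask <- rasterize_polygon_mask(tp_uv, nx, ny, s2$spacing)
  out_slice <- s2
  out_slice$torso_mask <- warped_mask
  list(slice = out_slice, deformation = wd, field = field,
       correspondences = corr, tp_contour_uv = tp_uv, tp_mask = tp_mask,
       warped_contour = warped_contour)
}
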