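#' Generate a synthetic torso around a spine phantom
#'
#' Builds a watertight elliptical-cross-section torso surface whose centerline
#' follows the spine's lateral curve (so the trunk asymmetry tracks the
#' scoliotic curve), places named external markers at the anatomical roles
#' used clinically (vertebra prominens, pilonidal dimple, sternum, spinous
#' process, iliac spines, scapular angles), and records the cross-section
#' parameters needed to rasterize axial slices analytically.
#'
#' For a prone spine the anterior half of every cross-section is compressed
#' radially by `compression` (< 1), emulating the soft-tissue flattening of
#' lying prone; the standing torso uses `compression = 1`.
#'
#' @param spine A `spine_phantom`.
#' @param body_params List: `rx`, `ry` (lateral / antero-posterior semi-axes,
#'   mm; defaults 140, 100), `anterior_offset` (ellipse center anterior of the
#'   spine, mm; default 40), `compression` (anterior radial scale for prone;
#'   default 0.85 when the spine is prone, 1 otherwise), `n_theta`, `n_z`
#'   (mesh resolution; defaults 96, 40), `end_margin` (mm beyond the spine
#'   ends; default 10).
#' @param seed Integer seed (kept for interface symmetry; the torso geometry
#'   is deterministic given the spine).
#' @return An object of class `torso_phantom`: `surface` ([surface_mesh()]),
#'   `markers` (named matrix, rows exactly on mesh vertices), `params`,
#'   `posture`, `slices` (`NULL` until [generate_axial_slices()]).
#' @export
generate_torso <- function(spine, body_params = list(), seed = 1L) {
  if (!inherits(spine, "spine_phantom")) stop("spine must be a spine_phantom")
  p <- body_params
  rx <- p$rx %||% 140; ry <- p$ry %||% 100
  if (rx <= 0 || ry <= 0) stop("degenerate body_params: radii must be positive")
  ant_off <- p$anterior_offset %||% 40
  comp <- p$compression %||% (if (spine$posture == "prone") 0.85 else 1)
  if (comp <= 0 || comp > 1) stop("compression must be in (0, 1]")
  n_theta <- p$n_theta %||% 96L; n_z <- p$n_z %||% 40L
  margin <- p$end_margin %||% 10
  centers <- spine_centers(spine)
  zr <- range(centers[, 3]) + c(-margin, margin)
  params <- list(rx = rx, ry = ry, anterior_offset = ant_off,
                 compression = comp, z_range = zr,
                 spine_centers = centers)
  zs <- seq(zr[1], zr[2], length.out = n_z)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  verts <- matrix(0, n_z * n_theta, 3)
  for (k in seq_len(n_z)) {
    sec <- torso_section(params, zs[k])
    s <- sin(theta)
    ry_eff <- sec$ry * ifelse(s > 0, sec$compression, 1)
    idx <- (k - 1L) * n_theta + seq_len(n_theta)
    verts[idx, ] <- cbind(sec$center[1] + sec$rx * cos(theta),
                          sec$center[2] + ry_eff * s,
                          zs[k])
  }
  faces <- matrix(0L, 0, 3)
  ring <- function(k) (k - 1L) * n_theta + seq_len(n_theta)
  for (k in seq_len(n_z - 1L)) {
    a <- ring(k); b <- ring(k + 1L)
    jn <- c(seq_len(n_theta)[-1], 1L)
    faces <- rbind(faces,
                   cbind(a, a[jn], b[jn]),
                   cbind(a, b[jn], b))
  }
  lo_sec <- torso_section(params, zs[1]); hi_sec <- torso_section(params, zs[n_z])
  c_lo <- nrow(verts) + 1L; c_hi <- nrow(verts) + 2L
  verts <- rbind(verts,
                 c(lo_sec$center, zs[1]),
                 c(hi_sec$center, zs[n_z]))
  a <- ring(1L); b <- ring(n_z)
  jn <- c(seq_len(n_theta)[-1], 1L)
  faces <- rbind(faces,
                 cbind(c_lo, a[jn], a),
                 cbind(c_hi, b, b[jn]))
  mesh <- surface_mesh(verts, faces)

  # named markers snapped to exact mesh vertices near their anatomical role
  roles <- rbind(vertebra_prominens = c(270, 1.00),
                 pilonidal_dimple   = c(270, 0.00),
                 spinous_process    = c(270, 0.50),
                 sternum            = c(90,  0.80),
                 iliac_spine_left   = c(205, 0.10),
                 iliac_spine_right  = c(335, 0.10),
                 scapula_left       = c(235, 0.85),
                 scapula_right      = c(305, 0.85))
  markers <- matrix(0, nrow(roles), 3, dimnames = list(rownames(roles), c("x", "y", "z")))
  side <- verts[seq_len(n_z * n_theta), , drop = FALSE]
  for (i in seq_len(nrow(roles))) {
    th <- roles[i, 1] * pi / 180
    zf <- zr[1] + roles[i, 2] * diff(zr)
    sec <- torso_section(params, zf)
    tgt <- c(sec$center[1] + sec$rx * cos(th),
             sec$center[2] + sec$ry * ifelse(sin(th) > 0, sec$compression, 1) * sin(th),
             zf)
    d2 <- rowSums(sweep(side, 2L, tgt)^2)
    markers[i, ] <- side[which.min(d2), ]
  }
  structure(list(surface = mesh, markers = markers, params = params,
                 posture = spine$posture, slices = NULL),
            class = "torso_phantom")
}

#' @export
print.torso_phantom <- function(x, ...) {
  cat(sprintf("torso_phantom (%s): %d-vertex surface, %d markers, %s slices\n",
              x$posture, nrow(x$surface$vertices), nrow(x$markers),
              if (is.null(x$slices)) "no" else length(x$slices)))
  invisible(x)
}

#' Analytic torso cross-section at height z
#'
#' @param params `torso_phantom$params` (or the phantom itself).
#' @param z Height, mm.
#' @return List: `center` (x, y of the ellipse center), `rx`, `ry`,
#'   `compression`.
#' @export
torso_section <- function(params, z) {
  if (inherits(params, "torso_phantom")) params <- params$params
  sc <- params$spine_centers
  ord <- order(sc[, 3])
  cx <- stats::approx(sc[ord, 3], sc[ord, 1], xout = z, rule = 2)$y
  cy <- stats::approx(sc[ord, 3], sc[ord, 2], xout = z, rule = 2)$y
  list(center = c(cx, cy + params$anterior_offset),
       rx = params$rx, ry = params$ry, compression = params$compression)
}

spine_xy_at <- function(spine_or_centers, z) {
  sc <- if (inherits(spine_or_centers, "spine_phantom")) spine_centers(spine_or_centers) else spine_or_centers
  ord <- order(sc[, 3])
  c(stats::approx(sc[ord, 3], sc[ord, 1], xout = z, rule = 2)$y,
    stats::approx(sc[ord, 3], sc[ord, 2], xout = z, rule = 2)$y)
}

#' One axial MRI slice (geometry + masks)
#'
#' @param index Slice index (1 = most inferior).
#' @param origin World position of the center of pixel (1, 1), mm.
#' @param e1,e2,normal In-plane axes and plane normal (unit 3-vectors);
#'   dimension 1 of the masks runs along `e1` (patient left-to-right before
#'   registration), dimension 2 along `e2` (posterior-to-anterior).
#' @param spacing In-plane pixel size, mm (length 2).
#' @param torso_mask,vertebra_mask Binary matrices on the slice grid.
#' @param vertebra Assigned vertebra label.
#' @param thickness Slice thickness, mm.
#' @param gt Optional ground-truth annotations.
#' @return An object of class `axial_slice`.
#' @export
axial_slice <- function(index, origin, e1, e2, normal, spacing,
                        torso_mask, vertebra_mask, vertebra = NA_character_,
                        thickness = 2, gt = NULL) {
  structure(list(index = index, origin = as.numeric(origin),
                 e1 = as.numeric(e1), e2 = as.numeric(e2),
                 normal = as.numeric(normal), spacing = as.numeric(spacing),
                 torso_mask = torso_mask, vertebra_mask = vertebra_mask,
                 vertebra = vertebra, thickness = thickness, gt = gt),
            class = "axial_slice")
}

#' @export
print.axial_slice <- function(x, ...) {
  cat(sprintf("axial_slice %d (%s): %d x %d px @ %.1f mm, origin z %.1f\n",
              x$index, x$vertebra, nrow(x$torso_mask), ncol(x$torso_mask),
              x$spacing[1], x$origin[3]))
  invisible(x)
}

#' 4x4 pose matrix of a slice (pixel index to world mm)
#' @param slice An [axial_slice()].
#' @return 4x4 matrix mapping homogeneous (i-1, j-1, 0, 1) pixel indices to
#'   world coordinates.
#' @export
slice_pose <- function(slice) {
  m <- diag(4)
  m[1:3, 1] <- slice$e1 * slice$spacing[1]
  m[1:3, 2] <- slice$e2 * slice$spacing[2]
  m[1:3, 3] <- slice$normal
  m[1:3, 4] <- slice$origin
  m
}

#' World coordinates of all pixel centers of a slice
#' @param slice An [axial_slice()].
#' @return (nx*ny) x 3 matrix, column-major over the mask grid.
#' @keywords internal
slice_pixel_world <- function(slice) {
  nx <- nrow(slice$torso_mask); ny <- ncol(slice$torso_mask)
  i <- rep(seq_len(nx) - 1L, times = ny); j <- rep(seq_len(ny) - 1L, each = nx)
  outer(i * slice$spacing[1], slice$e1) + outer(j * slice$spacing[2], slice$e2) +
    matrix(slice$origin, nx * ny, 3, byrow = TRUE)
}

#' Generate the axial MRI slice stack of a torso phantom
#'
#' Slices are perpendicular to the world z axis (scanner axial acquisition),
#' spaced `spacing_mm` apart with the stack centered on the torso's z extent;
#' the default 12 mm spacing over a ~400 mm trunk yields ~33 slices. Each
#' slice carries a binary torso mask (analytic elliptical cross-section,
#' anterior-compressed for a prone torso), the vertebra mask of the nearest
#' vertebra (filled ellipse of the vertebral body), its world pose, and the
#' assigned-vertebra ground truth.
#'
#' @param spine A `spine_phantom` (typically prone).
#' @param torso The matching `torso_phantom`.
#' @param spacing_mm Distance between slice planes, mm (default 12).
#' @param n_slices Number of slices; default covers the torso.
#' @param inplane In-plane pixel size, mm (default 1).
#' @param thickness Slice thickness, mm (default 2); must be < `spacing_mm`.
#' @param vertebra_radii Semi-axes of the vertebral-body cross-section, mm.
#' @return The `torso_phantom` with `slices` filled (list of
#'   [axial_slice()]).
#' @export
generate_axial_slices <- function(spine, torso, spacing_mm = 12, n_slices = NULL,
                                  inplane = 1, thickness = 2,
                                  vertebra_radii = c(15, 11)) {
  if (!inherits(torso, "torso_phantom")) stop("torso must be a torso_phantom")
  if (spacing_mm <= thickness) stop("slice spacing must exceed slice thickness")
  zr <- torso$params$z_range
  if (is.null(n_slices)) n_slices <- floor(diff(zr) / spacing_mm)
  if (n_slices <= 0) stop("n_slices must be positive")
  z0 <- mean(zr) - (n_slices - 1) / 2 * spacing_mm
  zs <- z0 + (seq_len(n_slices) - 1L) * spacing_mm
  # common in-plane grid over all sections
  secs <- lapply(zs, function(z) torso_section(torso$params, z))
  cxs <- vapply(secs, function(s) s$center[1], 0)
  cys <- vapply(secs, function(s) s$center[2], 0)
  pad <- 5
  x0 <- min(cxs) - torso$params$rx - pad; x1 <- max(cxs) + torso$params$rx + pad
  y0 <- min(cys) - torso$params$ry - pad; y1 <- max(cys) + torso$params$ry + pad
  nx <- ceiling((x1 - x0) / inplane); ny <- ceiling((y1 - y0) / inplane)
  gx <- x0 + (seq_len(nx) - 0.5) * inplane
  gy <- y0 + (seq_len(ny) - 0.5) * inplane
  X <- matrix(gx, nx, ny); Y <- matrix(gy, nx, ny, byrow = TRUE)
  centers_z <- spine_centers(spine)[, 3]
  labels <- vapply(spine$frames, function(f) f$label, "")
  slices <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    sec <- secs[[k]]
    ry_eff <- ifelse(Y > sec$center[2], sec$ry * sec$compression, sec$ry)
    torso_mask <- ((X - sec$center[1]) / sec$rx)^2 +
                  ((Y - sec$center[2]) / ry_eff)^2 <= 1
    v <- assign_slice_vertebra(zs[k], spine$frames)
    vi <- match(v, labels)
    vxy <- spine_xy_at(spine, zs[k])
    vert_mask <- ((X - vxy[1]) / vertebra_radii[1])^2 +
                 ((Y - vxy[2]) / vertebra_radii[2])^2 <= 1
    vert_mask <- vert_mask & torso_mask
    slices[[k]] <- axial_slice(
      index = k,
      origin = c(gx[1], gy[1], zs[k]),
      e1 = c(1, 0, 0), e2 = c(0, 1, 0), normal = c(0, 0, 1),
      spacing = c(inplane, inplane),
      torso_mask = torso_mask, vertebra_mask = vert_mask,
      vertebra = v, thickness = thickness,
      gt = list(vertebra = v, vertebra_index = vi,
                section = sec, slice_z = zs[k]))
  }
  torso$slices <- slices
  torso
}
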