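#' Triangulated surface mesh
#'
#' Minimal triangle-mesh container used for the torso surface topography and
#' for surfaces rebuilt from registered MRI contours.
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices, consistently
#'   oriented (counter-clockwise seen from outside).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- unname(as.matrix(vertices))
  faces <- unname(as.matrix(faces))
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices must be n x 3, faces m x 3")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Watertightness check
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces and each directed edge appears exactly once (consistent orientation).
#'
#' @param mesh A [surface_mesh()].
#' @return `TRUE`/`FALSE`; attribute `leak` holds offending edge vertex
#'   indices when `FALSE`.
#' @export
is_watertight <- function(mesh) {
  keys <- edge_keys(mesh$faces)
  tab <- table(keys)
  bad <- names(tab)[tab != 2L]
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(3, 1)])
  dkeys <- paste(e[, 1], e[, 2])
  dup <- unique(dkeys[duplicated(dkeys)])
  if (length(bad) || length(dup)) {
    leak <- if (length(bad)) bad[1] else dup[1]
    return(structure(FALSE, leak = leak))
  }
  TRUE
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for an
#' outward-oriented watertight mesh.
#' @param mesh A [surface_mesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
              b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
              b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(rowSums(a * cr)) / 6
}

#' One round of 1-to-4 linear (midpoint) subdivision
#'
#' Splits every triangle into four by inserting edge midpoints; the surface is
#' unchanged geometrically (midpoints lie on the original faces) but sampled
#' more densely, as used when building a detailed torso mesh from sparse MRI
#' contour rings.
#' @param mesh A [surface_mesh()].
#' @return The subdivided [surface_mesh()].
#' @export
subdivide_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ukey <- unique(key)
  idx <- match(key, ukey)
  first <- match(ukey, key)
  mids <- (v[e[first, 1], , drop = FALSE] + v[e[first, 2], , drop = FALSE]) / 2
  mid_id <- nrow(v) + idx
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2L * nf + seq_len(nf)]
  faces <- rbind(cbind(f[, 1], m12, m31),
                 cbind(m12, f[, 2], m23),
                 cbind(m31, m23, f[, 3]),
                 cbind(m12, m23, m31))
  surface_mesh(rbind(v, mids), faces)
}

plane_basis <- function(normal) {
  n <- normalize3(normal, "plane normal")
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- normalize3(a - sum(a * n) * n, "plane basis")
  e2 <- cross3(n, e1)
  list(n = n, e1 = e1, e2 = e2)
}

#' Planar cross-section of a watertight mesh
#'
#' Intersects the mesh with a plane and returns the closed intersection
#' polyline — the "planar cut" through the surface topography taken at the
#' position and orientation of a registered MRI slice. When the plane produces
#' several loops the one enclosing `inner_point` (projected in-plane) is
#' returned, otherwise the longest loop.
#'
#' @param mesh A [surface_mesh()], watertight.
#' @param plane List with `point` (length-3) and `normal` (length-3).
#' @param inner_point Optional length-3 point (e.g. the slice's vertebra
#'   center) used to pick among multiple loops.
#' @return An object of class `planar_contour`: list with `plane` (point,
#'   normal, in-plane basis `e1`, `e2`), `points` (k x 3, ordered, closed
#'   implicitly), `uv` (k x 2 in-plane mm coordinates).
#' @export
planar_cut <- function(mesh, plane, inner_point = NULL) {
  b <- plane_basis(plane$normal)
  p0 <- as.numeric(plane$point)
  s <- as.numeric((mesh$vertices - matrix(p0, nrow(mesh$vertices), 3, byrow = TRUE)) %*% b$n)
  s[s == 0] <- 1e-12          # nudge on-plane vertices off the plane
  f <- mesh$faces
  sf <- matrix(s[f], ncol = 3L)
  crossing <- (rowSums(sf > 0) %in% c(1L, 2L))
  if (!any(crossing)) stop("plane does not intersect the mesh (no cut)")
  segs <- vector("list", sum(crossing))
  fi <- which(crossing)
  # for each crossing triangle, find the two crossed edges and interpolate
  v <- mesh$vertices
  seg_a <- matrix(0, length(fi), 3); seg_b <- matrix(0, length(fi), 3)
  for (k in seq_along(fi)) {
    tri <- f[fi[k], ]
    sv <- s[tri]
    pts <- matrix(0, 0, 3)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      if (sv[e[1]] * sv[e[2]] < 0) {
        t <- sv[e[1]] / (sv[e[1]] - sv[e[2]])
        pts <- rbind(pts, (1 - t) * v[tri[e[1]], ] + t * v[tri[e[2]], ])
      }
    }
    seg_a[k, ] <- pts[1, ]; seg_b[k, ] <- pts[2, ]
  }
  # chain segments into loops by matching endpoints (rounded keys)
  keyof <- function(p) paste(round(p[, 1], 6), round(p[, 2], 6), round(p[, 3], 6))
  ka <- keyof(seg_a); kb <- keyof(seg_b)
  nseg <- length(fi)
  used <- rep(FALSE, nseg)
  loops <- list()
  adj <- split(seq_len(2L * nseg), c(ka, kb))
  endpoint <- function(i) if (i <= nseg) list(seg = i, side = 1L) else list(seg = i - nseg, side = 2L)
  for (start in seq_len(nseg)) {
    if (used[start]) next
    loop <- list(seg_a[start, ])
    cur_seg <- start; cur_key <- kb[start]; cur_pt <- seg_b[start, ]
    used[start] <- TRUE
    repeat {
      loop[[length(loop) + 1L]] <- cur_pt
      cand <- adj[[cur_key]]
      nxt <- NULL
      for (ci in cand) {
        ep <- endpoint(ci)
        if (!used[ep$seg]) { nxt <- ep; break }
      }
      if (is.null(nxt)) break
      used[nxt$seg] <- TRUE
      if (nxt$side == 1L) { cur_pt <- seg_b[nxt$seg, ]; cur_key <- kb[nxt$seg] }
      else { cur_pt <- seg_a[nxt$seg, ]; cur_key <- ka[nxt$seg] }
    }
    # drop duplicated closing point
    pts <- do.call(rbind, loop)
    if (nrow(pts) > 1L && sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < 1e-6)
      pts <- pts[-nrow(pts), , drop = FALSE]
    if (nrow(pts) >= 3L) loops[[length(loops) + 1L]] <- pts
  }
  if (!length(loops)) stop("plane does not intersect the mesh (no closed loop)")
  to_uv <- function(pts) cbind((pts - matrix(p0, nrow(pts), 3, byrow = TRUE)) %*% b$e1,
                               (pts - matrix(p0, nrow(pts), 3, byrow = TRUE)) %*% b$e2)
  pick <- 1L
  if (length(loops) > 1L) {
    if (!is.null(inner_point)) {
      q <- c(sum((inner_point - p0) * b$e1), sum((inner_point - p0) * b$e2))
      enc <- vapply(loops, function(L) {
        uv <- to_uv(L); point_in_polygon(q[1], q[2], uv[, 1], uv[, 2])
      }, logical(1))
      pick <- if (any(enc)) which(enc)[1] else which.max(vapply(loops, nrow, 1L))
    } else pick <- which.max(vapply(loops, nrow, 1L))
  }
  pts <- loops[[pick]]
  structure(list(plane = list(point = p0, normal = b$n, e1 = b$e1, e2 = b$e2),
                 points = pts, uv = to_uv(pts)),
            class = "planar_contour")
}

#' Vectorized point-in-polygon (crossing number)
#'
#' @param px,py Numeric vectors of query coordinates.
#' @param polyx,polyy Polygon vertex coordinates (closed implicitly).
#' @return Logical vector, `TRUE` for points inside.
#' @export
point_in_polygon <- function(px, py, polyx, polyy) {
  n <- length(polyx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- polyx[i]; yi <- polyy[i]; xj <- polyx[j]; yj <- polyy[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Voxel occupancy volume
#'
#' Binary 3D occupancy grid with anisotropic spacing, the container compared
#' voxel-by-voxel in the volumetric Dice analysis.
#' @param occupancy 3D array of 0/1.
#' @param spacing Length-3 positive voxel size, mm; default `c(1, 1, 3)`.
#' @param origin Length-3 world position of the corner of voxel (1,1,1), mm.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(occupancy, spacing = c(1, 1, 3), origin = c(0, 0, 0)) {
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (!all(occupancy %in% c(0, 1))) stop("occupancy must be binary")
  structure(list(occupancy = occupancy, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "voxel_volume")
}

#' Voxelize a watertight mesh
#'
#' Rasterizes the mesh interior onto an axis-aligned grid: voxel centers
#' strictly inside the surface are set to 1, all others 0. The grid origin is
#' aligned to the mesh bounding box; the default resolution is 1 x 1 x 3 mm
#' with slices parallel to the x-y plane. Interior tests use per-column
#' z-ray casting with parity counting.
#'
#' @param mesh A watertight [surface_mesh()].
#' @param spacing Length-3 voxel size, mm.
#' @return A [voxel_volume()].
#' @export
voxelize <- function(mesh, spacing = c(1, 1, 3)) {
  wt <- is_watertight(mesh)
  if (!isTRUE(wt))
    stop("mesh is not watertight (leak at edge ", attr(wt, "leak"), ")")
  v <- mesh$vertices; f <- mesh$faces
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  nx <- max(1L, ceiling((hi[1] - lo[1]) / spacing[1]))
  ny <- max(1L, ceiling((hi[2] - lo[2]) / spacing[2]))
  nz <- max(1L, ceiling((hi[3] - lo[3]) / spacing[3]))
  cx <- lo[1] + (seq_len(nx) - 0.5) * spacing[1]
  cy <- lo[2] + (seq_len(ny) - 0.5) * spacing[2]
  cz <- lo[3] + (seq_len(nz) - 0.5) * spacing[3]
  # accumulate z-crossings of vertical rays through each (x,y) voxel column
  col_id <- vector("list", nrow(f)); col_z <- vector("list", nrow(f))
  for (k in seq_len(nrow(f))) {
    tri <- v[f[k, ], , drop = FALSE]
    xr <- range(tri[, 1]); yr <- range(tri[, 2])
    i0 <- max(1L, ceiling((xr[1] - lo[1]) / spacing[1] + 0.5))
    i1 <- min(nx, floor((xr[2] - lo[1]) / spacing[1] + 0.5))
    j0 <- max(1L, ceiling((yr[1] - lo[2]) / spacing[2] + 0.5))
    j1 <- min(ny, floor((yr[2] - lo[2]) / spacing[2] + 0.5))
    if (i0 > i1 || j0 > j1) next
    gx <- cx[i0:i1]; gy <- cy[j0:j1]
    px <- rep(gx, times = length(gy)); py <- rep(gy, each = length(gx))
    # barycentric in xy-projection
    d <- (tri[2, 2] - tri[3, 2]) * (tri[1, 1] - tri[3, 1]) +
         (tri[3, 1] - tri[2, 1]) * (tri[1, 2] - tri[3, 2])
    if (abs(d) < 1e-12) next   # triangle vertical in z: no transversal crossing
    l1 <- ((tri[2, 2] - tri[3, 2]) * (px - tri[3, 1]) +
           (tri[3, 1] - tri[2, 1]) * (py - tri[3, 2])) / d
    l2 <- ((tri[3, 2] - tri[1, 2]) * (px - tri[3, 1]) +
           (tri[1, 1] - tri[3, 1]) * (py - tri[3, 2])) / d
    l3 <- 1 - l1 - l2
    inside <- l1 >= 0 & l2 >= 0 & l3 >= 0 & l1 <= 1 & l2 <= 1 & l3 <= 1
    if (!any(inside)) next
    zc <- l1[inside] * tri[1, 3] + l2[inside] * tri[2, 3] + l3[inside] * tri[3, 3]
    ii <- (i0:i1)[((which(inside) - 1L) %% length(gx)) + 1L]
    jj <- (j0:j1)[((which(inside) - 1L) %/% length(gx)) + 1L]
    col_id[[k]] <- ii + (jj - 1L) * nx
    col_z[[k]] <- zc
  }
  ids <- unlist(col_id); zs <- unlist(col_z)
  occ <- array(0L, dim = c(nx, ny, nz))
  if (length(ids)) {
    by_col <- split(zs, ids)
    for (nm in names(by_col)) {
      z <- sort(by_col[[nm]])
      # collapse duplicate crossings (edge-shared hits)
      if (length(z) > 1L) z <- z[c(TRUE, diff(z) > 1e-9)]
      if (length(z) < 2L) next
      cid <- as.integer(nm)
      i <- ((cid - 1L) %% nx) + 1L
      j <- ((cid - 1L) %/% nx) + 1L
      # parity fill
      inside_z <- (findInterval(cz, z) %% 2L) == 1L
      occ[i, j, inside_z] <- 1L
    }
  }
  voxel_volume(occ, spacing = spacing, origin = lo)
}
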