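#' Dice similarity coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`, in `[0, 1]`, symmetric; 1 means perfect
#' overlap. Both masks empty is undefined and raises an error rather than
#' silently returning 0.
#'
#' @param mask_a,mask_b Binary matrices (or arrays) of identical shape.
#' @return Dice value in `[0, 1]`.
#' @export
dice_2d <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks must have identical shape")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) stop("Dice is undefined for two empty masks")
  2 * sum(a & b) / (sa + sb)
}

#' Per-method Dice report
#'
#' @param per_slice Numeric vector of per-slice Dice values.
#' @param method Method label (`"rigid"`, `"articulated"`, `"proposed"`...).
#' @param slice_index Integer slice indices (default sequential).
#' @return An object of class `dice_report` with `per_slice` (data frame),
#'   `mean`, `variance`, `method`.
#' @export
dice_report <- function(per_slice, method, slice_index = seq_along(per_slice)) {
  stopifnot(length(per_slice) == length(slice_index))
  structure(list(per_slice = data.frame(slice = slice_index, dice = per_slice),
                 mean = mean(per_slice), variance = stats::var(per_slice),
                 method = method),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("dice_report [%s]: mean %.4f, sd %.4f over %d slices\n",
              x$method, x$mean, sqrt(x$variance), nrow(x$per_slice)))
  invisible(x)
}

resample_contour <- function(pts, n) {
  # arc-length resampling of a closed polyline to n points
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  ts <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  idx <- findInterval(ts, s, rightmost.closed = TRUE)
  idx[idx >= nrow(closed)] <- nrow(closed) - 1L
  f <- (ts - s[idx]) / pmax(seg[idx], 1e-12)
  closed[idx, , drop = FALSE] * (1 - f) + closed[idx + 1L, , drop = FALSE] * f
}

#' Build a torso surface mesh from a stack of registered slice contours
#'
#' Triangulates the registered MRI torso contours into a closed surface:
#' each contour is resampled to `n_points` by arc length, consecutive rings
#' are stitched with triangle bands (ring starts aligned by nearest point to
#' avoid twist), the ends are capped with centroid fans, and one round of
#' 1-to-4 linear subdivision densifies the result (the slice spacing is large
#' relative to the in-plane sampling). The sampled contour points are
#' vertices of the mesh.
#'
#' @param contours List of k x 3 matrices (closed torso contours of the
#'   registered slices, in order along the stack); at least 2.
#' @param n_points Points per resampled contour ring (default 72).
#' @param subdivide Apply one linear subdivision round (default TRUE).
#' @return A watertight [surface_mesh()].
#' @export
build_torso_mesh <- function(contours, n_points = 72L, subdivide = TRUE) {
  if (length(contours) < 2L) stop("need at least 2 slice contours")
  rings <- lapply(contours, function(p) {
    p <- unname(as.matrix(p))
    if (ncol(p) != 3L) stop("contours must be k x 3 matrices")
    if (nrow(p) < 3L) stop("open or degenerate contour")
    resample_contour(p, n_points)
  })
  # consistent winding: make all rings counter-clockwise in their own plane
  signed_area <- function(p) {
    x <- p[, 1]; y <- p[, 2]
    sum(x * y[c(2:length(y), 1)] - x[c(2:length(x), 1)] * y) / 2
  }
  rings <- lapply(rings, function(r) if (signed_area(r) < 0) r[rev(seq_len(nrow(r))), ] else r)
  # align ring start points to the previous ring (avoid twist)
  for (k in 2:length(rings)) {
    d2 <- rowSums(sweep(rings[[k]][, 1:2, drop = FALSE], 2L, rings[[k - 1L]][1, 1:2])^2)
    s <- which.min(d2)
    if (s > 1L) rings[[k]] <- rings[[k]][c(s:nrow(rings[[k]]), 1:(s - 1L)), ]
  }
  n <- n_points
  verts <- do.call(rbind, rings)
  faces <- matrix(0L, 0, 3)
  jn <- c(seq_len(n)[-1], 1L)
  for (k in seq_len(length(rings) - 1L)) {
    a <- (k - 1L) * n + seq_len(n); b <- k * n + seq_len(n)
    faces <- rbind(faces, cbind(a, a[jn], b[jn]), cbind(a, b[jn], b))
  }
  lo_c <- colMeans(rings[[1]]); hi_c <- colMeans(rings[[length(rings)]])
  c_lo <- nrow(verts) + 1L; c_hi <- nrow(verts) + 2L
  verts <- rbind(verts, lo_c, hi_c)
  a <- seq_len(n); b <- (length(rings) - 1L) * n + seq_len(n)
  # ring order along +z decides cap orientation; fix by overall volume sign
  faces <- rbind(faces, cbind(c_lo, a[jn], a), cbind(c_hi, b, b[jn]))
  mesh <- surface_mesh(verts, faces)
  if (mesh_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  if (subdivide) mesh <- subdivide_mesh(mesh)
  mesh
}

#' Volumetric Dice of two voxel volumes
#'
#' Resamples both occupancy grids onto a common origin/extent (nearest-voxel
#' alignment; the grids must share the same spacing) and computes the Dice
#' coefficient over all voxels of the union extent.
#'
#' @param vol_a,vol_b [voxel_volume()] objects with identical spacing.
#' @return Dice value in `[0, 1]`.
#' @export
dice_3d <- function(vol_a, vol_b) {
  if (max(abs(vol_a$spacing - vol_b$spacing)) > 1e-9)
    stop("voxel volumes must share the same spacing")
  sp <- vol_a$spacing
  lo <- pmin(vol_a$origin, vol_b$origin)
  hi <- pmax(vol_a$origin + dim(vol_a$occupancy) * sp,
             vol_b$origin + dim(vol_b$occupancy) * sp)
  n <- pmax(1L, as.integer(ceiling((hi - lo) / sp - 1e-9)))
  embed <- function(vol) {
    out <- array(0L, dim = n)
    off <- as.integer(round((vol$origin - lo) / sp))
    d <- dim(vol$occupancy)
    out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])] <-
      vol$occupancy
    out
  }
  dice_2d(embed(vol_a), embed(vol_b))
}

gaussian_kernels <- function(sigma) {
  r <- ceiling(3 * sigma)
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  dg <- -x / sigma^2 * exp(-x^2 / (2 * sigma^2))
  dg <- dg / sum(-x * dg)        # unit response to a unit linear ramp
  list(g = g, dg = dg, r = r)
}

conv_sep <- function(mat, kx, ky) {
  # separable 2D convolution with replicate padding
  r1 <- (length(kx) - 1L) / 2L; r2 <- (length(ky) - 1L) / 2L
  nx <- nrow(mat); ny <- ncol(mat)
  padx <- mat[c(rep(1L, r1), seq_len(nx), rep(nx, r1)), , drop = FALSE]
  out1 <- matrix(0, nx, ny)
  for (k in seq_along(kx))
    out1 <- out1 + kx[k] * padx[(seq_len(nx) + length(kx) - k), , drop = FALSE]
  pady <- out1[, c(rep(1L, r2), seq_len(ny), rep(ny, r2)), drop = FALSE]
  out <- matrix(0, nx, ny)
  for (k in seq_along(ky))
    out <- out + ky[k] * pady[, (seq_len(ny) + length(ky) - k), drop = FALSE]
  out
}

#' Jacobian determinant of a deformation field
#'
#' Per-pixel determinant of the Jacobian of the mapping x -> x + u(x). The
#' partial derivatives of the displacement are approximated with first-order
#' Gaussian-derivative filters (default sigma = 1 pixel, kernels truncated at
#' 3 sigma; smoothing with the matched Gaussian along the other axis). The
#' determinant is 1 wherever the mapping is locally the identity; values
#' above 1 indicate local expansion of the forward mapping, below 1 local
#' compression.
#'
#' @param field A `deformation_field` (from [dense_displacement_field()]), or
#'   a list with `ux`, `uy` displacement matrices (mm) and `spacing`.
#' @param sigma Gaussian derivative scale in pixels (default 1).
#' @return Matrix of per-pixel determinant values.
#' @export
jacobian_determinant <- function(field, sigma = 1) {
  if (sigma <= 0) stop("sigma must be > 0")
  ux <- field$ux; uy <- field$uy
  if (!all(is.finite(ux)) || !all(is.finite(uy)))
    stop("displacement field must be finite")
  sp <- field$spacing %||% c(1, 1)
  if (length(sp) == 1L) sp <- rep(sp, 2L)
  k <- gaussian_kernels(sigma)
  dux_dx <- conv_sep(ux, k$dg, k$g) / sp[1]
  dux_dy <- conv_sep(ux, k$g, k$dg) / sp[2]
  duy_dx <- conv_sep(uy, k$dg, k$g) / sp[1]
  duy_dy <- conv_sep(uy, k$g, k$dg) / sp[2]
  (1 + dux_dx) * (1 + duy_dy) - dux_dy * duy_dx
}

#' Erode a binary mask with a square structuring element
#'
#' Keeps the pixels whose full `(2 radius + 1)^2` neighborhood lies inside
#' the mask — the erosion matched to the square support of the truncated
#' separable Gaussian-derivative kernels, used to select the strict vertebra
#' interior when checking the rigidity signature of the Jacobian
#' determinant.
#'
#' @param mask Binary matrix.
#' @param radius Erosion radius in pixels (e.g. `ceiling(3 * sigma)`).
#' @return Logical matrix.
#' @export
erode_mask <- function(mask, radius) {
  m <- mask
  for (r in seq_len(radius)) {
    nx <- nrow(m); ny <- ncol(m)
    p <- matrix(FALSE, nx + 2L, ny + 2L)
    p[2:(nx + 1L), 2:(ny + 1L)] <- m
    m <- p[1:nx, 1:ny] & p[2:(nx + 1L), 1:ny] & p[3:(nx + 2L), 1:ny] &
         p[1:nx, 2:(ny + 1L)] & p[2:(nx + 1L), 2:(ny + 1L)] & p[3:(nx + 2L), 2:(ny + 1L)] &
         p[1:nx, 3:(ny + 2L)] & p[2:(nx + 1L), 3:(ny + 2L)] & p[3:(nx + 2L), 3:(ny + 2L)]
  }
  m
}

#' Compare registration methods on their per-slice Dice values
#'
#' Summarizes per-method mean and standard deviation and tests pairwise
#' differences with a paired two-sided test on the per-slice values
#' (Wilcoxon signed-rank by default; paired t-test optionally).
#'
#' @param reports Named list of [dice_report()] objects over the same slice
#'   index sets.
#' @param test `"wilcoxon"` (default) or `"ttest"`.
#' @return An object of class `method_comparison`: `summary` (data frame:
#'   method, mean, sd, n), `p_values` (symmetric matrix), `best` (method with
#'   the highest mean), `test`.
#' @export
compare_methods <- function(reports, test = c("wilcoxon", "ttest")) {
  test <- match.arg(test)
  if (is.null(names(reports))) names(reports) <- vapply(reports, function(r) r$method, "")
  idx <- lapply(reports, function(r) r$per_slice$slice)
  for (i in seq_along(idx))
    if (!identical(idx[[i]], idx[[1]]))
      stop("slice index sets differ between methods")
  sm <- data.frame(method = names(reports),
                   mean = vapply(reports, function(r) r$mean, 0),
                   sd = vapply(reports, function(r) sqrt(r$variance), 0),
                   n = vapply(reports, function(r) nrow(r$per_slice), 0L),
                   row.names = NULL)
  k <- length(reports)
  p <- matrix(NA_real_, k, k, dimnames = list(names(reports), names(reports)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { p[i, j] <- 1; next }
    a <- reports[[i]]$per_slice$dice; b <- reports[[j]]$per_slice$dice
    if (max(abs(a - b)) < 1e-15) { p[i, j] <- 1; next }
    if (stats::sd(a - b) < 1e-14) { p[i, j] <- 0; next }  # constant nonzero shift
    p[i, j] <- if (test == "wilcoxon")
      suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
    else stats::t.test(a, b, paired = TRUE)$p.value
  }
  structure(list(summary = sm, p_values = p,
                 best = sm$method[which.max(sm$mean)], test = test),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("method_comparison (", x$test, " paired test)\n", sep = "")
  print(x$summary, row.names = FALSE)
  cat("best by mean Dice:", x$best, "\n")
  invisible(x)
}
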