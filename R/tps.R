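#' Thin-plate spline fit with the |r| kernel
#'
#' Fits the landmark-interpolating map f(p) = a1 + a2 x + a3 y (+ a4 z) +
#' sum_i w_i U(|p - p_i|), one coefficient set per output coordinate, with the
#' 3D radial kernel U(r) = |r|. The coefficients solve the block system
#' `[[K + lambda I, P], [P', 0]] [w; a] = [V; 0]`, where K holds the pairwise
#' kernel values of the source (control) points, P = [1, source] and V the
#' targets. The side condition P'w = 0 removes the affine component from the
#' kernel part. The same machinery serves the 2D in-plane fits of the
#' per-slice soft-tissue step (same |r| kernel, 2D affine part).
#'
#' With `lambda = 0` the map interpolates the targets exactly; `lambda > 0`
#' relaxes it to an approximation (in kernel units, i.e. mm here).
#'
#' @param source n x d matrix of control points (d = 2 or 3), mm.
#' @param target n x d matrix of target points.
#' @param lambda Regularization, >= 0. Default 0 (interpolating).
#' @return An object of class `tps_model` with elements `control_points`,
#'   `weights` (n x d), `affine` ((d+1) x d, first row the constant term),
#'   `lambda`, `dim`, `kernel`.
#' @export
fit_tps <- function(source, target, lambda = 0) {
  source <- unname(as.matrix(source)); target <- unname(as.matrix(target))
  d <- ncol(source); n <- nrow(source)
  if (!d %in% c(2L, 3L)) stop("source must have 2 or 3 columns")
  if (!all(dim(target) == dim(source)))
    stop("source and target must have identical dimensions")
  if (lambda < 0) stop("lambda must be >= 0")
  if (n < d + 1L)
    stop("need at least ", d + 1L, " control points for a ", d, "D fit")
  if (anyNA(source) || anyNA(target)) stop("landmarks contain NA")
  P <- cbind(1, source)
  if (qr(P)$rank < d + 1L)
    stop("degenerate control points: ",
         if (d == 3L) "coplanar or coincident" else "collinear or coincident",
         " source set")
  K <- as.matrix(stats::dist(source))          # U(r) = |r|
  # the |r| kernel is conditionally negative definite, so the smoothing term
  # is added on the flipped-sign system (identical solution at lambda = 0;
  # monotone, resonance-free approximation for lambda > 0); the weights are
  # negated back so that evaluation uses U(r) = |r| directly
  A <- rbind(cbind(-K + lambda * diag(n), P),
             cbind(t(P), matrix(0, d + 1L, d + 1L)))
  kappa <- kappa(A, exact = FALSE)
  if (!is.finite(kappa) || kappa > 1e12)
    stop(sprintf("singular thin-plate spline system (condition number %.3g)", kappa))
  if (kappa > 1e10)
    warning(sprintf("ill-conditioned thin-plate spline system (condition number %.3g)", kappa))
  rhs <- rbind(target, matrix(0, d + 1L, d))
  coef <- solve(A, rhs)
  coef <- coef + solve(A, rhs - A %*% coef)   # one iterative-refinement step
  structure(list(control_points = source,
                 weights = -coef[seq_len(n), , drop = FALSE],
                 affine = coef[n + seq_len(d + 1L), , drop = FALSE],
                 lambda = lambda, dim = d, kernel = "|r|"),
            class = "tps_model")
}

#' Evaluate a thin-plate spline at arbitrary points
#'
#' @param model A `tps_model` from [fit_tps()].
#' @param points m x d matrix (or length-d vector) of evaluation points.
#' @return Transformed points, same shape as the input.
#' @export
evaluate_tps <- function(model, points) {
  if (!inherits(model, "tps_model")) stop("expected a tps_model")
  vec <- is.null(dim(points))
  pts <- if (vec) matrix(points, nrow = 1L) else unname(as.matrix(points))
  if (ncol(pts) != model$dim)
    stop("points must have ", model$dim, " columns")
  cp <- model$control_points
  # |r| kernel matrix between evaluation and control points; differences are
  # formed explicitly per control point (the expanded |a|^2+|b|^2-2ab form
  # cancels catastrophically near the control points)
  U <- matrix(0, nrow(pts), nrow(cp))
  for (j in seq_len(nrow(cp))) {
    d2 <- (pts[, 1] - cp[j, 1])^2 + (pts[, 2] - cp[j, 2])^2
    if (model$dim == 3L) d2 <- d2 + (pts[, 3] - cp[j, 3])^2
    U[, j] <- sqrt(d2)
  }
  out <- cbind(1, pts) %*% model$affine + U %*% model$weights
  if (vec) as.numeric(out) else out
}

#' @export
print.tps_model <- function(x, ...) {
  cat(sprintf("tps_model: %dD, %d control points, kernel U(r)=%s, lambda=%g\n",
              x$dim, nrow(x$control_points), x$kernel, x$lambda))
  invisible(x)
}

match_markers <- function(a, b, what_a = "source", what_b = "target") {
  a <- as.matrix(a); b <- as.matrix(b)
  if (is.null(rownames(a)) || is.null(rownames(b)))
    stop("marker sets must carry row names")
  miss_b <- setdiff(rownames(a), rownames(b))
  miss_a <- setdiff(rownames(b), rownames(a))
  if (length(miss_a) || length(miss_b))
    stop("marker names do not match; missing in ", what_a, ": ",
         paste(miss_a, collapse = ", "), "; missing in ", what_b, ": ",
         paste(miss_b, collapse = ", "))
  list(a = a, b = b[rownames(a), , drop = FALSE])
}

#' Register surface topography to X-ray space with a thin-plate spline
#'
#' Fits the TP-to-X-ray transform on paired external markers (adhesive markers
#' digitized on the surface topography; radio-opaque markers affixed on top of
#' them, reconstructed from the biplanar X-rays) and applies it to every
#' vertex of the TP torso mesh. Marker pairs are matched by name; the mesh
#' topology is unchanged.
#'
#' @param tp_markers n x 3 matrix of TP marker positions (mm), row names =
#'   marker names.
#' @param xray_markers n x 3 matrix of the same markers reconstructed from the
#'   X-rays, same row names.
#' @param tp_mesh A [surface_mesh()] of the torso surface topography.
#' @param lambda TPS regularization; default 0 (interpolating).
#' @return A list with `model` (the fitted `tps_model`) and `mesh` (the
#'   transformed [surface_mesh()]).
#' @export
register_tp_to_xray <- function(tp_markers, xray_markers, tp_mesh, lambda = 0) {
  m <- match_markers(tp_markers, xray_markers, "TP markers", "X-ray markers")
  if (nrow(m$a) < 4L) stop("need at least 4 matched markers")
  model <- fit_tps(m$a, m$b, lambda = lambda)
  mesh <- tp_mesh
  mesh$vertices <- evaluate_tps(model, tp_mesh$vertices)
  list(model = model, mesh = mesh)
}
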