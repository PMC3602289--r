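#' Landmark templates of the phantom vertebra
#'
#' Local-frame (mm) positions of the 6 X-ray reconstruction landmarks
#' (endplate centers, points above/below the left and right pedicles) and the
#' 8 MRI landmarks (left/right edges of the posterior, anterior, inferior and
#' superior ends of the vertebral body). Both templates have their centroid
#' exactly at the frame origin so that the frames recovered from either
#' landmark set agree.
#' @name landmark_templates
#' @keywords internal
NULL

xray_landmark_template <- function() {
  m <- rbind(plate_sup          = c(0,  6,  12),
             plate_inf          = c(0,  6, -12),
             pedicle_sup_left   = c(-8, -3,   5),
             pedicle_sup_right  = c(8,  -3,   5),
             pedicle_inf_left   = c(-8, -3,  -5),
             pedicle_inf_right  = c(8,  -3,  -5))
  colnames(m) <- c("x", "y", "z")
  m
}

mri_landmark_template <- function() {
  m <- rbind(left_sup   = c(-6,   0,  12),
             right_sup  = c(6,    0,  12),
             left_inf   = c(-6,   0, -12),
             right_inf  = c(6,    0, -12),
             left_ant   = c(-6,  14,   0),
             right_ant  = c(6,   14,   0),
             left_post  = c(-6, -14,   0),
             right_post = c(6,  -14,   0))
  colnames(m) <- c("x", "y", "z")
  m
}

spine_levels_inferior_up <- function() rev(vertebra_levels())  # L5 ... T1

#' Generate a synthetic scoliotic spine
#'
#' Builds the 17 thoracic and lumbar vertebral frames (L5 up to T1, ordered
#' inferior to superior, centers strictly increasing in z) along a laterally
#' curved centerline with coupled axial rotation — the geometry of a right
#' (or left, negative amplitude) thoracic scoliotic curve. Each vertebra
#' carries the 6-point X-ray and 8-point MRI landmark sets, rigid-body
#' consistent with its frame.
#'
#' The `"prone"` posture perturbs the standing intervertebral chain with
#' per-joint random rotations/translations drawn uniformly within
#' `prone_bounds` (emulating the postural change between standing radiographs
#' and prone MRI) and records the exact prone-to-standing joint offsets as
#' ground truth.
#'
#' @param curvature List with `amplitude` (lateral Gaussian-bump amplitude,
#'   mm, >= 0), `apex` (vertebra name, T1..L5), `axial_rot` (apex axial
#'   rotation, deg), optionally `sigma` (bump width, mm; default 60).
#' @param posture `"standing"` or `"prone"`.
#' @param seed Integer seed; identical seeds give bitwise-identical phantoms.
#' @param spacing Intervertebral center spacing, mm (default 24, giving a
#'   ~400 mm trunk over the 17 levels).
#' @param prone_bounds List with `max_rot_deg` (default 3) and `max_trans_mm`
#'   (default 2): per-joint uniform perturbation bounds for the prone posture.
#' @return An object of class `spine_phantom`: `frames` (list of 17
#'   [vertebra_frame()]), `xray_landmarks` / `mri_landmarks` (named lists of
#'   per-vertebra matrices), `curvature`, `posture`, `seed`, and for prone
#'   posture `ground_truth` (per-joint prone-to-standing rigid offsets plus
#'   the root offset).
#' @export
generate_spine <- function(curvature = list(amplitude = 30, apex = "T9", axial_rot = 15),
                           posture = c("standing", "prone"),
                           seed = 1L,
                           spacing = 24,
                           prone_bounds = list(max_rot_deg = 3, max_trans_mm = 2)) {
  posture <- match.arg(posture)
  amp <- curvature$amplitude %||% 30
  apex <- curvature$apex %||% "T9"
  rot_amp <- curvature$axial_rot %||% 15
  sigma <- curvature$sigma %||% 60
  if (amp < 0) stop("curve amplitude must be >= 0")
  levels <- spine_levels_inferior_up()
  if (!apex %in% vertebra_levels())
    stop("invalid apex level '", apex, "': must be one of T1..T12, L1..L5")
  n <- length(levels)
  z <- (seq_len(n) - 1) * spacing
  z_apex <- z[match(apex, levels)]
  bump <- exp(-((z - z_apex)^2) / (2 * sigma^2))
  x <- amp * bump
  y <- rep(0, n)
  centers <- cbind(x, y, z)
  frames <- frames_from_centerline(centers, levels, rot_amp * bump)
  standing <- build_spine_object(frames, curvature, "standing", seed, spacing)
  if (posture == "standing") return(standing)

  # prone: perturb the standing intervertebral chain, record ground truth
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  mr <- prone_bounds$max_rot_deg %||% 3
  mt <- prone_bounds$max_trans_mm %||% 2
  rand_offset <- function() {
    ang <- stats::runif(3, -mr, mr)
    tr <- stats::runif(3, -mt, mt)
    rigid_transform(rotation_xyz(ang[1], ang[2], ang[3]), tr)
  }
  root_pert <- rand_offset()
  joint_pert <- replicate(n - 1L, rand_offset(), simplify = FALSE)
  poses <- lapply(standing$frames, frame_pose)
  locals <- lapply(seq_len(n - 1L), function(v)
    compose_rigid(poses[[v + 1L]], invert_rigid(poses[[v]])))
  prone_poses <- vector("list", n)
  prone_poses[[1]] <- compose_rigid(poses[[1]], root_pert)
  for (v in seq_len(n - 1L))
    prone_poses[[v + 1L]] <- compose_rigid(compose_rigid(locals[[v]], joint_pert[[v]]),
                                           prone_poses[[v]])
  prone_frames <- lapply(seq_len(n), function(v)
    vertebra_frame(levels[v], prone_poses[[v]]$translation, prone_poses[[v]]$rotation))
  out <- build_spine_object(prone_frames, curvature, "prone", seed, spacing)
  out$ground_truth <- list(
    root_offset = root_pert,          # standing root pose = prone root pose o root_offset^-1
    joint_offsets = joint_pert)       # standing local_v = prone local_v' with offset removed
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

frames_from_centerline <- function(centers, levels, axial_rot_deg) {
  n <- nrow(centers)
  frames <- vector("list", n)
  for (v in seq_len(n)) {
    lo <- max(1L, v - 1L); hi <- min(n, v + 1L)
    sup <- normalize3(centers[hi, ] - centers[lo, ], "centerline tangent")
    theta <- axial_rot_deg[v] * pi / 180
    lat0 <- c(cos(theta), sin(theta), 0)
    lat <- lat0 - sum(lat0 * sup) * sup
    lat <- normalize3(lat, "lateral axis")
    ant <- cross3(sup, lat)
    frames[[v]] <- vertebra_frame(levels[v], centers[v, ], cbind(lat, ant, sup))
  }
  frames
}

build_spine_object <- function(frames, curvature, posture, seed, spacing) {
  xt <- xray_landmark_template(); mt <- mri_landmark_template()
  place <- function(frame, template) {
    w <- sweep(template %*% t(frame$axes), 2L, frame$center, "+")
    rownames(w) <- rownames(template); colnames(w) <- c("x", "y", "z")
    w
  }
  xl <- lapply(frames, place, template = xt)
  ml <- lapply(frames, place, template = mt)
  labels <- vapply(frames, function(f) f$label, "")
  names(xl) <- labels; names(ml) <- labels
  structure(list(frames = frames, xray_landmarks = xl, mri_landmarks = ml,
                 curvature = curvature, posture = posture,
                 seed = seed, spacing = spacing, ground_truth = NULL),
            class = "spine_phantom")
}

#' @export
print.spine_phantom <- function(x, ...) {
  cat(sprintf("spine_phantom (%s): %d vertebrae, Cobb-like angle %.1f deg, seed %d\n",
              x$posture, length(x$frames), cobb_angle(x), x$seed))
  invisible(x)
}

spine_centers <- function(spine) {
  t(vapply(spine$frames, function(f) f$center, numeric(3)))
}

#' Coronal Cobb-like angle of a spine phantom
#'
#' Maximum angle (degrees) between the coronal-plane projections of any two
#' vertebral superior axes — the analog of the clinical Cobb angle measured
#' between the most tilted endplates of the curve.
#' @param spine A `spine_phantom` or list of [vertebra_frame()].
#' @return Angle in degrees.
#' @export
cobb_angle <- function(spine) {
  frames <- if (inherits(spine, "spine_phantom")) spine$frames else spine
  sup <- t(vapply(frames, function(f) f$axes[, 3], numeric(3)))
  proj <- sup[, c(1, 3)]                       # coronal (x-z) projection
  ang <- atan2(proj[, 1], proj[, 2])           # tilt from vertical
  (max(ang) - min(ang)) * 180 / pi
}

#' Lateral-curve amplitude producing a requested Cobb-like angle
#'
#' Numerically inverts the deterministic standing-geometry relation between
#' the Gaussian-bump amplitude and the resulting Cobb-like angle.
#' @param target_deg Requested angle, degrees (> 0).
#' @param apex Apex vertebra (default `"T9"`).
#' @param axial_rot Apex axial rotation passed through (deg).
#' @param spacing,sigma Centerline geometry parameters (mm).
#' @return Amplitude in mm.
#' @export
amplitude_for_cobb <- function(target_deg, apex = "T9", axial_rot = 15,
                               spacing = 24, sigma = 60) {
  if (target_deg <= 0) stop("target angle must be > 0")
  f <- function(a) cobb_angle(generate_spine(
    curvature = list(amplitude = a, apex = apex, axial_rot = axial_rot, sigma = sigma),
    posture = "standing", seed = 0L, spacing = spacing)) - target_deg
  stats::uniroot(f, c(1e-3, 200), tol = 1e-8)$root
}

#' Reconstruct the standing spine from a prone phantom and its ground truth
#'
#' Applies the recorded prone-to-standing joint offsets (and root offset) to
#' the prone intervertebral chain; on an unmodified phantom this reproduces
#' the standing spine to numerical precision, which is the phantom's
#' ground-truth closure property.
#' @param prone A prone `spine_phantom` with `ground_truth`.
#' @return The list of 17 standing [vertebra_frame()].
#' @export
reconstruct_standing_frames <- function(prone) {
  if (is.null(prone$ground_truth)) stop("phantom carries no ground truth")
  gt <- prone$ground_truth
  poses <- lapply(prone$frames, frame_pose)
  n <- length(poses)
  locals <- lapply(seq_len(n - 1L), function(v)
    compose_rigid(poses[[v + 1L]], invert_rigid(poses[[v]])))
  st <- vector("list", n)
  st[[1]] <- compose_rigid(poses[[1]], invert_rigid(gt$root_offset))
  for (v in seq_len(n - 1L)) {
    # prone local = standing local o offset  =>  standing local = prone local o offset^-1
    standing_local <- compose_rigid(locals[[v]], invert_rigid(gt$joint_offsets[[v]]))
    st[[v + 1L]] <- compose_rigid(standing_local, st[[v]])
  }
  labels <- vapply(prone$frames, function(f) f$label, "")
  lapply(seq_len(n), function(v)
    vertebra_frame(labels[v], st[[v]]$translation, st[[v]]$rotation))
}
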