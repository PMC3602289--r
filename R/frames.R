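#' Vertebral coordinate frame
#'
#' The local coordinate system of one vertebra: its center plus an orthonormal
#' right-handed triad whose columns are the lateral (left-to-right), anterior
#' (posterior-to-anterior) and superior (inferior-to-superior) axes. Frames are
#' estimated per modality from landmark sets and linked by rigid intervertebral
#' transforms to form the articulated spine model.
#'
#' @param label Vertebra name, `"T1"`..`"T12"`, `"L1"`..`"L5"`.
#' @param center Length-3 numeric, mm.
#' @param axes 3x3 orthonormal matrix with det +1, columns = lateral,
#'   anterior, superior.
#' @return An object of class `vertebra_frame`.
#' @export
vertebra_frame <- function(label, center, axes) {
  center <- unname(as.numeric(center))
  axes <- unname(as.matrix(axes))
  if (length(center) != 3L || !all(dim(axes) == c(3L, 3L)))
    stop("vertebra_frame needs a length-3 center and 3x3 axes")
  if (max(abs(crossprod(axes) - diag(3))) > 1e-8 || abs(det(axes) - 1) > 1e-8)
    stop("axes must be orthonormal with det +1")
  structure(list(label = as.character(label), center = center, axes = axes),
            class = "vertebra_frame")
}

#' @export
print.vertebra_frame <- function(x, ...) {
  cat(sprintf("vertebra_frame %s: center [%.1f, %.1f, %.1f] mm\n",
              x$label, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

vertebra_levels <- function() c(paste0("T", 1:12), paste0("L", 1:5))

xray_landmark_names <- function() {
  c("plate_sup", "plate_inf",
    "pedicle_sup_left", "pedicle_sup_right",
    "pedicle_inf_left", "pedicle_inf_right")
}

mri_landmark_names <- function() {
  c("left_sup", "right_sup", "left_inf", "right_inf",
    "left_ant", "right_ant", "left_post", "right_post")
}

normalize3 <- function(v, what = "axis") {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) stop("degenerate landmark geometry: ", what, " has near-zero length")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

get_named_points <- function(landmarks, needed) {
  lm <- as.matrix(landmarks)
  if (is.null(rownames(lm)))
    stop("landmarks must carry row names identifying their anatomical role")
  missing <- setdiff(needed, rownames(lm))
  if (length(missing))
    stop("missing landmark(s): ", paste(missing, collapse = ", "))
  lm[needed, , drop = FALSE]
}

#' Vertebral frame from the six X-ray reconstruction landmarks
#'
#' The landmarks sit at the centers of the superior and inferior endplates and
#' above/below the left and right pedicles. The center is the centroid of all
#' six points; the superior axis follows the endplate-center difference (the
#' most reliably placed landmarks, trusted most in the orthogonalization); the
#' lateral axis derives from the left/right pedicle midpoint difference
#' orthogonalized against the superior axis; the anterior axis completes the
#' right-handed triad.
#'
#' @param landmarks 6x3 matrix (mm) with row names `plate_sup`, `plate_inf`,
#'   `pedicle_sup_left`, `pedicle_sup_right`, `pedicle_inf_left`,
#'   `pedicle_inf_right`.
#' @param label Vertebra name attached to the frame.
#' @return A [vertebra_frame()].
#' @export
frame_from_xray_landmarks <- function(landmarks, label = "") {
  lm <- get_named_points(landmarks, xray_landmark_names())
  center <- colMeans(lm)
  sup <- normalize3(lm["plate_sup", ] - lm["plate_inf", ], "superior (endplates)")
  left_mid <- (lm["pedicle_sup_left", ] + lm["pedicle_inf_left", ]) / 2
  right_mid <- (lm["pedicle_sup_right", ] + lm["pedicle_inf_right", ]) / 2
  lat_raw <- right_mid - left_mid
  lat <- lat_raw - sum(lat_raw * sup) * sup
  lat <- normalize3(lat, "lateral (pedicles, after orthogonalization)")
  ant <- cross3(sup, lat)
  vertebra_frame(label, center, cbind(lat, ant, sup))
}

#' Vertebral frame from the eight MRI sagittal-segmentation landmarks
#'
#' Landmarks on the left and right edges of the posterior, anterior, inferior
#' and superior ends of the vertebral body. The center is the centroid of the
#' eight points; the superior axis follows the superior-pair midpoint minus
#' the inferior-pair midpoint; the anterior axis follows the anterior-pair
#' midpoint minus the posterior-pair midpoint (orthogonalized); the lateral
#' axis completes the right-handed triad.
#'
#' @param landmarks 8x3 matrix (mm) with row names `left_sup`, `right_sup`,
#'   `left_inf`, `right_inf`, `left_ant`, `right_ant`, `left_post`,
#'   `right_post`.
#' @param label Vertebra name attached to the frame.
#' @return A [vertebra_frame()].
#' @export
frame_from_mri_landmarks <- function(landmarks, label = "") {
  lm <- get_named_points(landmarks, mri_landmark_names())
  center <- colMeans(lm)
  sup_mid <- (lm["left_sup", ] + lm["right_sup", ]) / 2
  inf_mid <- (lm["left_inf", ] + lm["right_inf", ]) / 2
  ant_mid <- (lm["left_ant", ] + lm["right_ant", ]) / 2
  post_mid <- (lm["left_post", ] + lm["right_post", ]) / 2
  sup <- normalize3(sup_mid - inf_mid, "superior (sup/inf pairs)")
  ant_raw <- ant_mid - post_mid
  ant <- ant_raw - sum(ant_raw * sup) * sup
  ant <- normalize3(ant, "anterior (ant/post pairs, after orthogonalization)")
  lat <- cross3(ant, sup)
  vertebra_frame(label, center, cbind(lat, ant, sup))
}

#' Rigid transform mapping one vertebral frame onto another
#'
#' Returns the unique rigid transform `T` with `T(a.center) = b.center` and
#' `T.rotation %*% a.axes = b.axes`. Used to build intervertebral transforms
#' and the cross-modality per-vertebra bone transforms.
#'
#' @param frame_a,frame_b [vertebra_frame()] objects (source, target).
#' @return A [rigid_transform()].
#' @export
rigid_between <- function(frame_a, frame_b) {
  if (!inherits(frame_a, "vertebra_frame") || !inherits(frame_b, "vertebra_frame"))
    stop("rigid_between expects two vertebra_frame objects")
  R <- frame_b$axes %*% t(frame_a$axes)
  rigid_transform(R, frame_b$center - as.numeric(R %*% frame_a$center))
}

#' Frame pose as a rigid transform from the world frame
#'
#' The rigid transform mapping the canonical world frame (origin, identity
#' axes) onto the vertebra's frame — the global per-vertebra transform of the
#' articulated model.
#' @param frame A [vertebra_frame()].
#' @return A [rigid_transform()].
#' @export
frame_pose <- function(frame) {
  rigid_transform(frame$axes, frame$center)
}

#' Apply a rigid transform to a vertebral frame
#' @param tf A [rigid_transform()].
#' @param frame A [vertebra_frame()].
#' @return The transformed [vertebra_frame()].
#' @export
transform_frame <- function(tf, frame) {
  assert_rigid(tf)
  vertebra_frame(frame$label,
                 apply_rigid(tf, frame$center),
                 tf$rotation %*% frame$axes)
}
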