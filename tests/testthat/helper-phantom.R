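# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a moderately curved phantom pair at coarse slice resolution (fast)
small_phantom <- function() fixture("small_phantom", function() {
  curv <- list(amplitude = 35, apex = "T9", axial_rot = 12)
  standing <- generate_spine(curv, "standing", seed = 11)
  prone <- generate_spine(curv, "prone", seed = 11)
  torso_standing <- generate_torso(standing, list(n_theta = 72, n_z = 30))
  torso_prone <- generate_torso(prone, list(n_theta = 72, n_z = 30))
  torso_prone <- generate_axial_slices(prone, torso_prone, inplane = 2)
  labels <- names(standing$xray_landmarks)
  xray_frames <- lapply(labels, function(l)
    frame_from_xray_landmarks(standing$xray_landmarks[[l]], l))
  mri_frames <- lapply(labels, function(l)
    frame_from_mri_landmarks(prone$mri_landmarks[[l]], l))
  mri_model <- build_articulated(mri_frames, "MRI")
  xray_model <- build_articulated(xray_frames, "Xray")
  list(standing = standing, prone = prone,
       torso_standing = torso_standing, torso_prone = torso_prone,
       xray_frames = xray_frames, mri_frames = mri_frames,
       mri_model = mri_model, xray_model = xray_model,
       bone = cross_modality_transforms(mri_model, xray_model))
})

# one registered mid-stack slice of the small phantom
small_registration <- function() fixture("small_registration", function() {
  ph <- small_phantom()
  sl <- ph$torso_prone$slices[[15]]
  reg <- register_slice(sl, ph$bone[[sl$vertebra]], ph$torso_standing$surface)
  list(slice = sl, reg = reg)
})

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

random_rigid <- function(scale = 50) {
  rigid_transform(random_rotation(), stats::rnorm(3, sd = scale))
}

# closed ring of n points: circle of radius r at height z, centered (cx, cy)
circle_contour <- function(r, z, n = 72, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th), z)
}

max_frame_error <- function(fa, fb) {
  max(max(abs(fa$center - fb$center)), max(abs(fa$axes - fb$axes)))
}
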