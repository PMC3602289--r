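test_that("spine generation is deterministic and respects the zero-curvature case", {
  a <- generate_spine(list(amplitude = 0, apex = "T9", axial_rot = 0), "prone", seed = 5)
  b <- generate_spine(list(amplitude = 0, apex = "T9", axial_rot = 0), "prone", seed = 5)
  expect_identical(a$mri_landmarks, b$mri_landmarks)
  expect_identical(a$xray_landmarks, b$xray_landmarks)
  st <- generate_spine(list(amplitude = 0, apex = "T9", axial_rot = 0), "standing", seed = 5)
  centers <- t(sapply(st$frames, function(f) f$center))
  # all centers on the best-fit line (here: the z axis)
  expect_lt(max(abs(centers[, 1:2])), 1e-9)
  expect_true(all(diff(centers[, 3]) > 0))
  expect_error(generate_spine(list(amplitude = 10, apex = "C3"), seed = 1), "invalid apex")
  expect_error(generate_spine(list(amplitude = -2, apex = "T9"), seed = 1), ">= 0")
})

test_that("spine frames are orthonormal and landmark sets rigid-body consistent", {
  ph <- small_phantom()
  for (sp in list(ph$standing, ph$prone)) {
    expect_length(sp$frames, 17)
    centers <- t(sapply(sp$frames, function(f) f$center))
    expect_true(all(diff(centers[, 3]) > 0))   # strictly monotonic in z
    for (f in sp$frames) {
      expect_lt(max(abs(crossprod(f$axes) - diag(3))), 1e-10)
      expect_equal(det(f$axes), 1, tolerance = 1e-10)
    }
    # landmarks are the frame-mapped templates: pairwise distances equal across vertebrae
    d1 <- dist(sp$xray_landmarks[[1]])
    d9 <- dist(sp$xray_landmarks[[9]])
    expect_lt(max(abs(d1 - d9)), 1e-9)
  }
})

test_that("requested Cobb-like angle is achieved within 2 degrees", {
  amp <- amplitude_for_cobb(50)
  sp <- generate_spine(list(amplitude = amp, apex = "T9", axial_rot = 15), "standing", seed = 1)
  # independent measurement from the generated centers: coronal fan of
  # central-difference tangents (endplate normals follow the centerline)
  centers <- t(sapply(sp$frames, function(f) f$center))
  n <- nrow(centers)
  tang <- centers[c(2:n, n), ] - centers[c(1, 1:(n - 1)), ]
  ang <- atan2(tang[, 1], tang[, 3]) * 180 / pi
  expect_lt(abs((max(ang) - min(ang)) - 50), 2)
  expect_lt(abs(cobb_angle(sp) - 50), 2)
})

test_that("recorded prone-to-standing perturbations close back onto the standing spine", {
  curv <- list(amplitude = 40, apex = "T8", axial_rot = 10)
  st <- generate_spine(curv, "standing", seed = 99)
  pr <- generate_spine(curv, "prone", seed = 99)
  rec <- reconstruct_standing_frames(pr)
  err <- max(vapply(seq_len(17), function(v)
    max_frame_error(rec[[v]], st$frames[[v]]), 0))
  expect_lt(err, 1e-9)
})

test_that("torso mesh is watertight, encloses the spine, and markers sit on it", {
  ph <- small_phantom()
  to <- ph$torso_standing
  expect_true(isTRUE(is_watertight(to$surface)))
  expect_gt(mesh_volume(to$surface), 0)
  # vertebra centers strictly inside: voxel-free check by ray parity per center
  v <- to$surface$vertices
  for (f in ph$standing$frames) {
    sec <- torso_section(to$params, f$center[3])
    expect_true(((f$center[1] - sec$center[1]) / sec$rx)^2 +
                ((f$center[2] - sec$center[2]) / sec$ry)^2 < 1)
  }
  # markers coincide with mesh vertices
  for (i in seq_len(nrow(to$markers))) {
    d <- sqrt(rowSums(sweep(v, 2, to$markers[i, ])^2))
    expect_lt(min(d), 1e-9)
  }
  expect_error(generate_torso(ph$standing, list(rx = -5)), "positive")
})

test_that("straight circular torso has analytic sections and volume", {
  st <- generate_spine(list(amplitude = 0, apex = "T9", axial_rot = 0), "standing", seed = 1)
  to <- generate_torso(st, list(rx = 100, ry = 100, anterior_offset = 0,
                                n_theta = 96, n_z = 20, end_margin = 8))
  # planar cut at interior height is a circle of radius 100
  cut <- planar_cut(to$surface, list(point = c(0, 0, 200), normal = c(0, 0, 1)))
  r <- sqrt(rowSums(sweep(cut$points[, 1:2], 2, c(0, 0))^2))
  expect_lt(max(abs(r - 100)), 0.3)    # chord tolerance of the 96-gon
  # cylinder volume pi R^2 L within 1%
  L <- 16 * 24 + 2 * 8
  expect_lt(abs(mesh_volume(to$surface) - pi * 100^2 * L) / (pi * 100^2 * L), 0.01)
})

test_that("axial slices carry consistent masks with analytic areas", {
  st <- generate_spine(list(amplitude = 0, apex = "T9", axial_rot = 0), "standing", seed = 1)
  to <- generate_torso(st, list(rx = 120, ry = 120, anterior_offset = 0))
  to <- generate_axial_slices(st, to)
  expect_equal(length(to$slices), 33)   # ~400 mm trunk / 12 mm spacing
  for (sl in to$slices[c(1, 10, 20, 33)]) {
    expect_true(all(sl$torso_mask[sl$vertebra_mask]))   # vertebra inside torso
    area <- sum(sl$torso_mask) * prod(sl$spacing)
    expect_lt(abs(area - pi * 120^2) / (pi * 120^2), 0.02)
  }
  expect_error(generate_axial_slices(st, to, n_slices = 0), "positive")
  expect_error(generate_axial_slices(st, to, spacing_mm = 1, thickness = 2), "exceed")
})

test_that("identical seeds reproduce identical torsos and slices", {
  curv <- list(amplitude = 25, apex = "T10", axial_rot = 8)
  mk <- function() {
    pr <- generate_spine(curv, "prone", seed = 77)
    generate_axial_slices(pr, generate_torso(pr, list(n_theta = 48, n_z = 16)),
                          inplane = 4)
  }
  a <- mk(); b <- mk()
  expect_identical(a$surface$vertices, b$surface$vertices)
  expect_identical(a$markers, b$markers)
  expect_identical(lapply(a$slices, `[[`, "torso_mask"),
                   lapply(b$slices, `[[`, "torso_mask"))
})
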