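test_that("planar cuts match analytic cross-sections", {
  # vertical cylinder radius 150: horizontal cut is a circle of radius 150
  rings <- lapply(seq(0, 100, 10), function(z) circle_contour(150, z, n = 144))
  cyl <- build_torso_mesh(rings, n_points = 144, subdivide = FALSE)
  cut <- planar_cut(cyl, list(point = c(0, 0, 50), normal = c(0, 0, 1)))
  r <- sqrt(rowSums(cut$points[, 1:2]^2))
  expect_lt(max(abs(r - 150)), 0.4)          # chord tolerance of the 144-gon
  expect_error(planar_cut(cyl, list(point = c(0, 0, 500), normal = c(0, 0, 1))),
               "does not intersect")
  # tilted cut of a sphere (ellipsoid special case): circle of radius sqrt(R^2-d^2)
  zs <- seq(-48, 48, 4)
  sph <- build_torso_mesh(lapply(zs, function(z) circle_contour(sqrt(50^2 - z^2), z, 72)),
                          n_points = 72, subdivide = FALSE)
  n <- c(1, 0, 1) / sqrt(2)
  cut2 <- planar_cut(sph, list(point = c(0, 0, 0), normal = n))
  r2 <- sqrt(rowSums(cut2$points^2))
  expect_lt(max(abs(r2 - 50)), 1.2)          # all cut points near the sphere surface
  expect_lt(max(abs(cut2$points %*% n)), 1e-9)  # and exactly on the plane
})

test_that("ray correspondences pair concentric contours radially", {
  mri <- circle_contour(100, 0, n = 360)[, 1:2]
  tp <- circle_contour(120, 0, n = 360)[, 1:2]
  cs <- extract_ray_correspondences(mri, tp, c(0, 0), c(0, 1))
  expect_length(cs$angles, 12)               # 360 / 30 degree steps
  expect_lt(max(abs(sqrt(rowSums(cs$source^2)) - 100)), 0.1)
  expect_lt(max(abs(sqrt(rowSums(cs$target^2)) - 120)), 0.1)
  # angle-0 pair lies along the anterior direction (zero 2D cross product)
  expect_lt(abs(cs$source[1, 1] * 1 - cs$source[1, 2] * 0), 1e-6)
  expect_gt(cs$source[1, 2], 0)
  expect_error(extract_ray_correspondences(mri, tp, c(500, 0), c(0, 1)), "angle")
  expect_error(extract_ray_correspondences(mri, tp, c(0, 0), c(0, 1), angular_step = 25),
               "divide")
})

test_that("edge TPS reproduces identity, uniform scaling and exact interpolation", {
  mri <- circle_contour(100, 0, n = 360)[, 1:2]
  cs_id <- extract_ray_correspondences(mri, mri, c(0, 0), c(0, 1))
  m_id <- fit_edge_tps(cs_id, lambda = 0)
  held <- circle_contour(70, 0, n = 33)[, 1:2]
  expect_lt(max(abs(evaluate_tps(m_id, held) - held)), 1e-8)
  # uniform x1.2 scale about the center is affine: held-out points scale too
  tp <- circle_contour(120, 0, n = 360)[, 1:2]
  m_sc <- fit_edge_tps(extract_ray_correspondences(mri, tp, c(0, 0), c(0, 1)), lambda = 0)
  expect_lt(max(abs(evaluate_tps(m_sc, held) - 1.2 * held)), 1e-5)
  # seeded irregular contours: lambda = 0 reproduces targets at sources
  set.seed(12)
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  r1 <- 90 + 8 * sin(3 * th); r2 <- 110 + 6 * cos(2 * th)
  c1 <- cbind(r1 * cos(th), r1 * sin(th)); c2 <- cbind(r2 * cos(th), r2 * sin(th))
  cs <- extract_ray_correspondences(c1, c2, c(0, 0), c(0, 1))
  m <- fit_edge_tps(cs, lambda = 0)
  expect_lt(max(abs(evaluate_tps(m, cs$source) - cs$target)), 1e-8)
})

test_that("distance maps equal a brute-force nearest-border search", {
  set.seed(44)
  nx <- 64
  gx <- matrix(seq_len(nx), nx, nx); gy <- t(gx)
  torso <- ((gx - 33)^2 / 28^2 + (gy - 31)^2 / 24^2) <= 1
  vert <- ((gx - 33)^2 / 7^2 + (gy - 26)^2 / 5^2) <= 1
  dm <- distance_maps(torso, vert, pixel_size = 1)
  border_of <- function(mask) {
    b <- matrix(FALSE, nx, nx)
    for (i in seq_len(nx)) for (j in seq_len(nx)) {
      if (!mask[i, j]) next
      nb <- c(if (i > 1) mask[i - 1, j] else FALSE, if (i < nx) mask[i + 1, j] else FALSE,
              if (j > 1) mask[i, j - 1] else FALSE, if (j < nx) mask[i, j + 1] else FALSE)
      if (!all(nb)) b[i, j] <- TRUE
    }
    which(b, arr.ind = TRUE)
  }
  for (pair in list(list(vert, dm$d_vertebra), list(torso, dm$d_surface))) {
    bp <- border_of(pair[[1]])
    probe <- cbind(sample(nx, 40, TRUE), sample(nx, 40, TRUE))
    for (k in seq_len(40)) {
      bf <- sqrt(min((bp[, 1] - probe[k, 1])^2 + (bp[, 2] - probe[k, 2])^2))
      expect_equal(pair[[2]][probe[k, 1], probe[k, 2]], bf, tolerance = 1e-9)
    }
    # zero exactly on the border
    expect_true(all(pair[[2]][bp] == 0))
  }
  expect_error(distance_maps(torso, torso & !torso), "empty")
  expect_error(distance_maps(vert, torso), "contained")
})

test_that("weighted displacement obeys the three limit behaviors", {
  reg <- small_registration()$reg
  wd <- reg$deformation
  vm <- wd$vertebra_mask
  sp <- wd$spacing
  # identity inside the vertebra, exactly
  idx <- which(vm, arr.ind = TRUE)
  pts <- cbind((idx[, 1] - 1) * sp[1], (idx[, 2] - 1) * sp[2])
  expect_identical(weighted_displace(pts, wd), pts)
  # full edge-TPS displacement where d_surface = 0 (torso border)
  tb <- which(wd$d_surface == 0 & reg$slice$vertebra_mask == FALSE, arr.ind = TRUE)[1:20, ]
  ptb <- cbind((tb[, 1] - 1) * sp[1], (tb[, 2] - 1) * sp[2])
  expect_lt(max(abs(weighted_displace(ptb, wd) - evaluate_tps(wd$edge_model, ptb))), 1e-9)
  # half displacement where the two distances are equal
  eq <- which(abs(wd$d_vertebra - wd$d_surface) < 1e-12 & !vm &
                wd$d_vertebra > 0, arr.ind = TRUE)
  if (nrow(eq)) {
    pe <- cbind((eq[, 1] - 1) * sp[1], (eq[, 2] - 1) * sp[2])
    full <- evaluate_tps(wd$edge_model, pe)
    expect_lt(max(abs(weighted_displace(pe, wd) - (pe + 0.5 * (full - pe)))), 1e-9)
  }
  # blend weight bounds on the whole grid
  rho <- wd$d_vertebra / (wd$d_vertebra + wd$d_surface)
  rho[is.na(rho)] <- 0
  expect_true(all(rho >= 0 & rho <= 1))
})

test_that("the dense field is zero inside vertebrae and continuous", {
  reg <- small_registration()$reg
  f <- reg$field
  vm <- reg$deformation$vertebra_mask
  expect_true(all(f$ux[vm] == 0) && all(f$uy[vm] == 0))
  # no tearing: bounded displacement jumps between 4-adjacent pixels
  jump <- pmax(abs(diff(f$ux)), abs(diff(f$uy)))
  expect_lt(max(jump), 2 * max(abs(c(f$ux, f$uy))) / 10 + 2)
})

test_that("slice registration is exact when prone equals standing", {
  curv <- list(amplitude = 30, apex = "T9", axial_rot = 10)
  st <- generate_spine(curv, "standing", seed = 3,
                       prone_bounds = list(max_rot_deg = 0, max_trans_mm = 0))
  to_st <- generate_torso(st, list(n_theta = 72, n_z = 30))
  to_sl <- generate_axial_slices(st, to_st, inplane = 2)
  labels <- names(st$xray_landmarks)
  fx <- lapply(labels, function(l) frame_from_xray_landmarks(st$xray_landmarks[[l]], l))
  fm <- lapply(labels, function(l) frame_from_mri_landmarks(st$mri_landmarks[[l]], l))
  bone <- cross_modality_transforms(build_articulated(fm, "MRI"),
                                    build_articulated(fx, "Xray"))
  sl <- to_sl$slices[[16]]
  reg <- register_slice(sl, bone[[sl$vertebra]], to_st$surface, lambda = 0)
  # the deformation field is within rasterization noise of zero
  expect_lt(max(abs(c(reg$field$ux, reg$field$uy))), 2 * 2)  # < 2 px of 2 mm
  expect_gt(dice_2d(reg$slice$torso_mask, sl$torso_mask), 0.99)
})

test_that("soft-tissue refinement improves Dice over articulated-only on a deformed phantom", {
  ph <- small_phantom()
  rr <- small_registration()
  sl <- rr$slice; reg <- rr$reg
  s_art <- apply_articulated_to_slice(sl, ph$bone[[sl$vertebra]])
  dice_art <- dice_2d(s_art$torso_mask, reg$tp_mask)
  dice_prop <- dice_2d(reg$slice$torso_mask, reg$tp_mask)
  expect_gt(dice_prop, dice_art)
  expect_gt(dice_prop, 0.95)
  # rigidity through the full composition: vertebra pixel distances preserved
  idx <- which(sl$vertebra_mask, arr.ind = TRUE)[c(1, 10, 30), ]
  w0 <- t(apply(idx, 1, function(p)
    sl$origin + (p[1] - 1) * sl$spacing[1] * sl$e1 + (p[2] - 1) * sl$spacing[2] * sl$e2))
  s2 <- reg$slice
  uv <- cbind((idx[, 1] - 1) * s2$spacing[1], (idx[, 2] - 1) * s2$spacing[2])
  uv2 <- weighted_displace(uv, reg$deformation)   # identity inside vertebra
  w1 <- sweep(uv2[, 1, drop = FALSE] %*% rbind(s2$e1) +
                uv2[, 2, drop = FALSE] %*% rbind(s2$e2), 2, s2$origin, "+")
  expect_lt(max(abs(dist(w1) - dist(w0))), 1e-9)
  # control points land on the TP cut for an interpolating edge fit: the edge
  # TPS is exact there, and the blended map agrees up to the sub-pixel
  # distance-map interpolation at the torso border
  reg0 <- register_slice(sl, ph$bone[[sl$vertebra]], ph$torso_standing$surface, lambda = 0)
  expect_lt(max(abs(evaluate_tps(reg0$deformation$edge_model, reg0$correspondences$source) -
                      reg0$correspondences$target)), 1e-6)
  moved <- weighted_displace(reg0$correspondences$source, reg0$deformation)
  expect_lt(max(abs(moved - reg0$correspondences$target)), 0.5)
})
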