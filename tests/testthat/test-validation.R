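test_that("2D Dice matches its definition and rejects the undefined case", {
  m <- matrix(FALSE, 20, 20)
  a <- m; a[1:10, 1:10] <- TRUE
  expect_equal(dice_2d(a, a), 1.0)
  b <- m; b[11:20, 11:20] <- TRUE
  expect_equal(dice_2d(a, b), 0.0)
  c <- m; c[6:15, 1:10] <- TRUE           # |A|=|B|=100, overlap 50
  expect_equal(dice_2d(a, c), 0.5)
  expect_equal(dice_2d(a, c), dice_2d(c, a))
  expect_error(dice_2d(m, m), "undefined")
  expect_error(dice_2d(a, matrix(TRUE, 5, 5)), "identical shape")
})

test_that("contour stacks triangulate into watertight meshes with analytic area/volume", {
  rings <- list(circle_contour(80, 0), circle_contour(80, 12))
  cyl <- build_torso_mesh(rings, n_points = 72, subdivide = FALSE)
  expect_true(isTRUE(is_watertight(cyl)))
  tri_area <- function(mesh) {
    v <- mesh$vertices; f <- mesh$faces
    e1 <- v[f[, 2], ] - v[f[, 1], ]; e2 <- v[f[, 3], ] - v[f[, 1], ]
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    sum(sqrt(rowSums(cr^2))) / 2
  }
  lateral <- tri_area(cyl) - 2 * pi * 80^2 * (72 / (2 * pi)) * sin(2 * pi / 72)
  expect_lt(abs(lateral - 2 * pi * 80 * 12) / (2 * pi * 80 * 12), 0.02)
  # subdivision quadruples faces and stays on the original surface
  sub <- subdivide_mesh(cyl)
  expect_identical(nrow(sub$faces), 4L * nrow(cyl$faces))
  expect_true(isTRUE(is_watertight(sub)))
  expect_lt(abs(mesh_volume(sub) - mesh_volume(cyl)), 1e-6)
  # phantom stack: mesh volume within 3% of the analytic torso volume
  ph <- small_phantom()
  slices <- ph$torso_prone$slices
  contours <- lapply(slices, function(s) {
    uv <- mask_contour(s$torso_mask, s$spacing)
    cbind(uv[, 1] + s$origin[1], uv[, 2] + s$origin[2], s$origin[3])
  })
  mesh <- build_torso_mesh(contours, n_points = 72)
  p <- ph$torso_prone$params
  analytic <- pi * p$rx * p$ry * (1 + p$compression) / 2 *
    (slices[[length(slices)]]$origin[3] - slices[[1]]$origin[3])
  expect_lt(abs(mesh_volume(mesh) - analytic) / analytic, 0.03)
  expect_error(build_torso_mesh(contours[1]), "at least 2")
})

test_that("voxelization recovers analytic volumes at 1 x 1 x 3 mm", {
  # axis-aligned box 100 x 100 x 99
  box_rings <- lapply(c(0, 99), function(z)
    rbind(c(0, 0, z), c(100, 0, z), c(100, 100, z), c(0, 100, z)))
  box <- build_torso_mesh(box_rings, n_points = 40, subdivide = FALSE)
  vb <- voxelize(box)
  expect_equal(sum(vb$occupancy), 100 * 100 * 33, tolerance = 0.05)
  # sphere radius 50
  zs <- seq(-49.5, 49.5, 3)
  sph <- build_torso_mesh(lapply(zs, function(z) circle_contour(sqrt(50^2 - z^2), z, 72)),
                          n_points = 72, subdivide = FALSE)
  vs <- voxelize(sph)
  vol <- sum(vs$occupancy) * prod(vs$spacing)
  expect_lt(abs(vol - 4 / 3 * pi * 50^3) / (4 / 3 * pi * 50^3), 0.02)
  # translation invariance of the ones count (raster jitter below 0.5%)
  sph2 <- sph; sph2$vertices <- sweep(sph$vertices, 2, c(31.7, -12.3, 8.9), "+")
  expect_lt(abs(sum(voxelize(sph2)$occupancy) - sum(vs$occupancy)) / sum(vs$occupancy),
            0.005)
  open_mesh <- surface_mesh(sph$vertices, sph$faces[-1, ])
  expect_error(voxelize(open_mesh), "watertight")
})

test_that("3D Dice handles identity, containment and offset grids", {
  occ <- array(0L, c(10, 10, 10)); occ[3:8, 3:8, 3:8] <- 1L
  va <- voxel_volume(occ, spacing = c(1, 1, 3))
  expect_equal(dice_3d(va, va), 1.0)
  # volume fully containing another with half the count: dice = 2/3
  inner <- array(0L, c(10, 10, 10))
  idx <- which(occ == 1L)[seq_len(sum(occ) / 2)]
  inner[idx] <- 1L
  vi <- voxel_volume(inner, spacing = c(1, 1, 3))
  expect_equal(dice_3d(va, vi), 2 / 3)
  # same content on an offset grid still overlaps perfectly
  vb <- voxel_volume(occ, spacing = c(1, 1, 3), origin = c(2, 0, 0))
  vc <- voxel_volume(occ, spacing = c(1, 1, 3), origin = c(0, 0, 0))
  expect_lt(dice_3d(vb, vc), 1)
  expect_error(dice_3d(va, voxel_volume(occ, spacing = c(1, 1, 1))), "spacing")
})

test_that("Jacobian determinant matches analytic fields and a finite-difference oracle", {
  zero <- list(ux = matrix(0, 40, 40), uy = matrix(0, 40, 40), spacing = c(1, 1))
  expect_lt(max(abs(jacobian_determinant(zero) - 1)), 1e-12)
  # uniform 1.1 in-plane scale about the grid center -> det 1.21 in the interior
  g <- (seq_len(40) - 20.5)
  sc <- list(ux = matrix(0.1 * g, 40, 40), uy = matrix(0.1 * g, 40, 40, byrow = TRUE),
             spacing = c(1, 1))
  jd <- jacobian_determinant(sc)
  expect_lt(max(abs(jd[10:30, 10:30] - 1.21)), 1e-3)
  # seeded smooth random field on 32 x 32: central differences agree within 5% RMS
  set.seed(17)
  x <- outer(seq_len(32), rep(1, 32)); y <- t(x)
  ux <- 1.5 * sin(x / 6) * cos(y / 7) + 0.8 * cos(x / 9)
  uy <- 1.2 * cos(x / 8) * sin(y / 5) - 0.6 * sin(y / 11)
  jd <- jacobian_determinant(list(ux = ux, uy = uy, spacing = c(1, 1)))
  cd <- function(m, axis) {   # central differences, no smoothing
    n <- dim(m)[axis]
    if (axis == 1) (m[c(2:n, n), ] - m[c(1, 1:(n - 1)), ]) /
        matrix(c(1, rep(2, n - 2), 1), nrow(m), ncol(m))
    else (m[, c(2:n, n)] - m[, c(1, 1:(n - 1))]) /
        matrix(c(1, rep(2, n - 2), 1), nrow(m), ncol(m), byrow = TRUE)
  }
  jd_o <- (1 + cd(ux, 1)) * (1 + cd(uy, 2)) - cd(ux, 2) * cd(uy, 1)
  int <- 5:28
  rel <- sqrt(mean((jd[int, int] - jd_o[int, int])^2)) / sqrt(mean(jd_o[int, int]^2))
  expect_lt(rel, 0.05)
})

test_that("mask erosion keeps exactly the pixels with full square neighborhoods", {
  m <- matrix(FALSE, 12, 12); m[3:10, 3:10] <- TRUE
  e <- erode_mask(m, 2)
  expect_identical(which(e, arr.ind = TRUE),
                   which(row(m) >= 5 & row(m) <= 8 & col(m) >= 5 & col(m) <= 8 & m,
                         arr.ind = TRUE))
})

test_that("method comparison summarizes and tests paired Dice differences", {
  set.seed(50)
  base <- runif(20, 0.80, 0.90)
  reps <- list(rigid = dice_report(base, "rigid"),
               articulated = dice_report(base + 0.02, "articulated"),
               proposed = dice_report(base + 0.12, "proposed"))
  cmp <- compare_methods(reps)
  expect_identical(cmp$best, "proposed")
  expect_equal(cmp$summary$mean, sapply(reps, function(r) mean(r$per_slice$dice)),
               ignore_attr = TRUE)
  expect_lt(cmp$p_values["proposed", "rigid"], 0.01)
  # identical reports: p = 1, zero mean difference
  same <- compare_methods(list(a = dice_report(base, "a"), b = dice_report(base, "b")))
  expect_equal(same$p_values["a", "b"], 1)
  expect_equal(diff(same$summary$mean), 0)
  bad <- dice_report(base[1:10], "short")
  expect_error(compare_methods(list(a = reps$rigid, b = bad)), "slice index")
  cmp_t <- compare_methods(reps, test = "ttest")
  expect_lt(cmp_t$p_values["proposed", "rigid"], 0.01)
})
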