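test_that("rigid transform algebra composes, inverts and preserves distances", {
  t1 <- rigid_transform(rotation_xyz(rz = 30), c(3, 0, 0))
  t2 <- rigid_transform(translation = c(0, 0, 5))
  t3 <- compose_rigid(t2, rigid_transform(translation = c(3, 0, 0)))
  expect_equal(t3$translation, c(3, 0, 5))
  expect_equal(t3$rotation, diag(3))

  set.seed(42)
  for (rep in 1:20) {
    tf <- random_rigid()
    id <- compose_rigid(tf, invert_rigid(tf))
    expect_lt(norm(id$rotation - diag(3), "F"), 1e-9)
    expect_lt(max(abs(id$translation)), 1e-9)
    p <- matrix(rnorm(30, sd = 100), 10, 3)
    q <- apply_rigid(tf, p)
    expect_lt(max(abs(dist(q) - dist(p))), 1e-9)
  }
  expect_error(rigid_transform(matrix(rnorm(9), 3, 3)), "orthonormal")
})

test_that("composed chains act like sequential application", {
  set.seed(7)
  for (rep in 1:10) {
    chain <- replicate(5, random_rigid(), simplify = FALSE)
    p <- matrix(rnorm(15, sd = 50), 5, 3)
    seq_pts <- p
    for (tf in chain) seq_pts <- apply_rigid(tf, seq_pts)
    folded <- Reduce(function(acc, tf) compose_rigid(tf, acc), chain)
    expect_lt(max(abs(apply_rigid(folded, p) - seq_pts)), 1e-10)
  }
})

test_that("homogeneous-matrix and Euler conversions round-trip", {
  set.seed(3)
  tf <- random_rigid()
  expect_lt(max(abs(rigid_to_matrix(rigid_from_matrix(rigid_to_matrix(tf))) -
                      rigid_to_matrix(tf))), 1e-12)
  ang <- euler_angles(rigid_transform(rotation_xyz(10, -20, 35)))
  expect_equal(unname(ang), c(10, -20, 35), tolerance = 1e-8)
})

test_that("X-ray frame estimation recovers the canonical pose", {
  lm <- rbind(plate_sup = c(0, 0, 10), plate_inf = c(0, 0, -10),
              pedicle_sup_left = c(-8, -10, 4), pedicle_sup_right = c(8, -10, 4),
              pedicle_inf_left = c(-8, -10, -4), pedicle_inf_right = c(8, -10, -4))
  f <- frame_from_xray_landmarks(lm, "T5")
  expect_equal(f$center, colMeans(lm))
  expect_equal(f$axes, diag(3), tolerance = 1e-12)
  expect_identical(f$label, "T5")
})

test_that("frame estimation is rigidly equivariant and yields proper rotations", {
  set.seed(5)
  base6 <- rbind(plate_sup = c(0.4, 6.2, 12.1), plate_inf = c(-0.2, 5.8, -11.8),
                 pedicle_sup_left = c(-8.2, -3.1, 5.2), pedicle_sup_right = c(7.9, -2.8, 4.9),
                 pedicle_inf_left = c(-7.8, -3.2, -4.8), pedicle_inf_right = c(8.1, -3.1, -5.1))
  base8 <- rbind(left_sup = c(-6.1, 0.2, 12.2), right_sup = c(5.9, -0.1, 11.8),
                 left_inf = c(-5.8, 0.1, -11.9), right_inf = c(6.2, 0.2, -12.1),
                 left_ant = c(-6.2, 14.1, 0.3), right_ant = c(5.8, 13.8, -0.2),
                 left_post = c(-5.9, -14.2, 0.1), right_post = c(6.1, -13.9, -0.3))
  for (rep in 1:100) {
    g <- random_rigid()
    f0 <- frame_from_xray_landmarks(base6)
    f1 <- frame_from_xray_landmarks(apply_rigid(g, base6))
    expect_lt(max_frame_error(f1, transform_frame(g, f0)), 1e-9)
    # Gram check: orthonormal with det +1
    expect_lt(max(abs(crossprod(f1$axes) - diag(3))), 1e-10)
    expect_equal(det(f1$axes), 1, tolerance = 1e-10)
    m0 <- frame_from_mri_landmarks(base8)
    m1 <- frame_from_mri_landmarks(apply_rigid(g, base8))
    expect_lt(max_frame_error(m1, transform_frame(g, m0)), 1e-9)
  }
})

test_that("frame estimation ignores landmark row order and flags degeneracy", {
  ph <- small_phantom()
  lm <- ph$standing$xray_landmarks[["T7"]]
  f1 <- frame_from_xray_landmarks(lm)
  f2 <- frame_from_xray_landmarks(lm[sample(6), ])
  expect_lt(max_frame_error(f1, f2), 1e-12)
  bad <- lm; bad["plate_sup", ] <- bad["plate_inf", ]
  expect_error(frame_from_xray_landmarks(bad), "degenerate")
  expect_error(frame_from_xray_landmarks(lm[1:5, ]), "missing landmark")
})

test_that("6-point X-ray and 8-point MRI landmark sets of one phantom vertebra agree", {
  ph <- small_phantom()
  for (v in c("L5", "T9", "T1")) {
    fx <- frame_from_xray_landmarks(ph$standing$xray_landmarks[[v]], v)
    fm <- frame_from_mri_landmarks(ph$standing$mri_landmarks[[v]], v)
    expect_lt(max_frame_error(fx, fm), 1e-6)
    # both recover the generating phantom frame
    idx <- which(vapply(ph$standing$frames, function(f) f$label, "") == v)
    expect_lt(max_frame_error(fx, ph$standing$frames[[idx]]), 1e-6)
  }
})

test_that("rigid_between maps one frame exactly onto another", {
  ph <- small_phantom()
  fa <- ph$standing$frames[[4]]; fb <- ph$standing$frames[[11]]
  tf <- rigid_between(fa, fb)
  expect_lt(max(abs(apply_rigid(tf, fa$center) - fb$center)), 1e-10)
  expect_lt(max(abs(tf$rotation %*% fa$axes - fb$axes)), 1e-10)
  id <- rigid_between(fa, fa)
  expect_lt(norm(id$rotation - diag(3), "F"), 1e-12)
  expect_lt(max(abs(id$translation)), 1e-9)
})
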