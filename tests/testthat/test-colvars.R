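# Collective variables: values, conventions, analytic gradients, invariances.

test_that("every CV gradient matches central finite differences", {
  set.seed(101)
  ref <- matrix(rnorm(15, sd = 1.5), 5, 3)
  frame <- host_frame(origin = c(0.3, -0.2, 0.1))
  masses <- runif(5, 1, 20)
  kinds <- c("separation", "axis_projection", "theta", "phi",
             "Theta", "Phi", "Psi", "rmsd")
  for (rep in 1:3) {
    X <- matrix(rnorm(15, sd = 2), 5, 3)
    for (kind in kinds) {
      cv <- colvar(kind, frame = frame, ref = ref, axis = c(0.2, 0.5, -1))
      o <- cv_value(cv, X, masses)
      expect_false(o$degenerate)
      g_fd <- fd_gradient(function(Z) cv_value(cv, Z, masses)$value, X)
      expect_lt(max(abs(o$grad - g_fd)), 1e-6)
    }
    cvd <- colvar("rmsd", ref = ref, mode = "dmatrix")
    o <- cv_value(cvd, X)
    g_fd <- fd_gradient(function(Z) cv_value(cvd, Z)$value, X)
    expect_lt(max(abs(o$grad - g_fd)), 1e-6)
    X4 <- matrix(rnorm(12), 4, 3)
    cv4 <- colvar("dihedral", atoms = 1:4)
    o <- cv_value(cv4, X4)
    g_fd <- fd_gradient(function(Z) cv_value(cv4, Z)$value, X4)
    expect_lt(max(abs(o$grad - g_fd)), 1e-6)
  }
})

test_that("separation distance follows its reference geometry", {
  X <- rbind(c(30, 0, 0))
  expect_equal(separation_distance(X)$value, 30)
  o <- separation_distance(rbind(c(0, 0, 0)))
  expect_equal(o$value, 0)
  expect_true(o$degenerate)   # gradient undefined at coincidence
  # mass-weighted COM
  X2 <- rbind(c(2, 0, 0), c(6, 0, 0))
  expect_equal(separation_distance(X2, masses = c(3, 1))$value, 3)
})

test_that("polar angles follow the axis conventions and flag degeneracy", {
  on_z <- polar_angles(rbind(c(0, 0, 2)))
  expect_equal(on_z$theta, 0)
  expect_true(on_z$degenerate)
  expect_equal(on_z$phi, 0)    # returned by convention
  diag_xy <- polar_angles(rbind(c(1, 1, 0) / sqrt(2)))
  expect_equal(diag_xy$theta, 90)
  expect_equal(diag_xy$phi, 45)
})

test_that("best-fit rotation recovers known rotations and is always proper", {
  set.seed(7)
  ref <- matrix(rnorm(18), 6, 3)
  expect_equal(best_fit_rotation(ref, ref), diag(3), tolerance = 1e-12)
  for (i in 1:20) {
    R0 <- random_rotation()
    mov <- ref %*% t(R0)
    expect_lt(max(abs(best_fit_rotation(mov, ref) - R0)), 1e-10)
  }
  # a reflected planar point set must still yield det = +1
  planar <- cbind(matrix(rnorm(10), 5, 2), 0)
  mirrored <- planar %*% diag(c(1, 1, -1))   # improper candidate
  R <- best_fit_rotation(mirrored, planar)
  expect_equal(det(R), 1, tolerance = 1e-10)
  # collinear reference is rejected by name
  line <- cbind(1:5, 0, 0)
  expect_error(best_fit_rotation(line, line), "collinear")
})

test_that("ZYZ Euler angles round-trip through the rotation matrix", {
  set.seed(11)
  expect_equal(euler_angles(diag(3))$Theta, 0)
  expect_true(euler_angles(diag(3))$degenerate)
  for (i in 1:500) {
    R0 <- random_rotation()
    e <- euler_angles(R0)
    if (e$degenerate) next
    expect_lt(max(abs(rotation_from_euler(e) - R0)), 1e-8)
    expect_gte(e$Theta, 0); expect_lte(e$Theta, 180)
  }
  # gimbal lock: rotation about z keeps only Phi + Psi defined; convention
  # returns Phi = 0
  Rz90 <- rotation_from_euler(0, 0, 90)
  e <- euler_angles(Rz90)
  expect_true(e$degenerate)
  expect_equal(e$Phi, 0)
  expect_equal((e$Phi + e$Psi) %% 360, 90, tolerance = 1e-8)
})

test_that("RMSD modes agree on rigid motions and hand-computable cases", {
  set.seed(13)
  ref <- matrix(rnorm(12), 4, 3)
  expect_equal(rmsd_cv(ref, ref, "fitted")$value, 0, tolerance = 1e-12)
  expect_equal(rmsd_cv(ref, ref, "dmatrix")$value, 0, tolerance = 1e-12)
  moved <- sweep(ref %*% t(random_rotation()), 2, c(3, -1, 2), `+`)
  expect_equal(rmsd_cv(moved, ref, "fitted")$value, 0, tolerance = 1e-10)
  expect_equal(rmsd_cv(moved, ref, "dmatrix")$value, 0, tolerance = 1e-10)
  # 2-atom system, one atom displaced along the bond by delta: the single
  # pair distance changes by delta exactly
  two <- rbind(c(0, 0, 0), c(1, 0, 0))
  two_d <- rbind(c(0, 0, 0), c(1.3, 0, 0))
  expect_equal(rmsd_cv(two_d, two, "dmatrix")$value, 0.3, tolerance = 1e-12)
  expect_error(rmsd_cv(rbind(c(0, 0, 0)), rbind(c(0, 0, 0)), "dmatrix"))
})

test_that("dihedral sign convention: cis 0, trans 180, odd under mirror", {
  cis <- list(c(-1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0))
  expect_equal(do.call(dihedral_angle, cis)$value, 0)
  trans <- list(c(-1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0))
  expect_equal(do.call(dihedral_angle, trans)$value, 180)
  set.seed(17)
  for (i in 1:25) {
    P <- matrix(rnorm(12), 4, 3)
    v <- cv_value(colvar("dihedral", atoms = 1:4), P)
    Pm <- P %*% diag(c(1, 1, -1))
    vm <- cv_value(colvar("dihedral", atoms = 1:4), Pm)
    if (abs(abs(v$value) - 180) < 1e-6) next  # sign of 180 is conventional
    expect_equal(vm$value, -v$value, tolerance = 1e-8)
  }
  # collinear central bond is flagged
  coll <- dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_true(coll$degenerate)
})

test_that("angular CVs are translation invariant and co-rotation invariant", {
  set.seed(19)
  ref <- matrix(rnorm(12), 4, 3)
  X <- matrix(rnorm(12, sd = 2), 4, 3) + 3
  shift <- c(5, -2, 8)
  for (kind in c("theta", "phi", "Theta", "Phi", "Psi", "rmsd")) {
    cv0 <- colvar(kind, ref = ref)
    v0 <- cv_value(cv0, X)$value
    # translation of frame and guest together
    cv1 <- colvar(kind, frame = host_frame(origin = shift), ref = ref)
    v1 <- cv_value(cv1, sweep(X, 2, shift, `+`))$value
    expect_equal(v1, v0, tolerance = 1e-8)
    # co-rotation of guest and host frame
    R0 <- random_rotation()
    cv2 <- colvar(kind, frame = host_frame(rotation = t(R0)), ref = ref)
    v2 <- cv_value(cv2, X %*% t(R0))$value
    expect_equal(v2, v0, tolerance = 1e-7)
  }
})
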