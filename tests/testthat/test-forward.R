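# Complete-electrode-model forward solver and adjoint Jacobian.

test_that("homogeneous-disk boundary potentials match the analytic series", {
  # near-point electrodes, tiny contact impedance, opposite-pair drive
  mod <- eit3d:::disk_model_point_electrodes(16, 128, 12)
  sys <- eit3d:::cem_system(mod, rep(1, nrow(mod$elements)))
  rhs <- matrix(0, sys$N + sys$L + 1, 1)
  rhs[sys$N + 1] <- 1; rhs[sys$N + 9] <- -1
  V <- as.matrix(Matrix::solve(sys$K, rhs))[sys$N + 1:16]
  th <- 2 * pi * (0:15) / 16
  ua <- disk_analytic_potential(th, th[1], th[9], n_terms = 2000)
  idx <- setdiff(1:16, c(1, 9))
  Vc <- V[idx] - mean(V[idx]); uc <- ua[idx] - mean(ua[idx])
  expect_lt(max(abs(Vc - uc)) / max(abs(uc)), 0.02)
  # refinement monotonically reduces the error
  errs <- vapply(list(c(64L, 6L), c(128L, 12L), c(256L, 24L)), function(sz) {
    mm <- eit3d:::disk_model_point_electrodes(16, sz[1], sz[2])
    ss <- eit3d:::cem_system(mm, rep(1, nrow(mm$elements)))
    r2 <- matrix(0, ss$N + ss$L + 1, 1); r2[ss$N + 1] <- 1; r2[ss$N + 9] <- -1
    vv <- as.matrix(Matrix::solve(ss$K, r2))[ss$N + 1:16]
    vc <- vv[idx] - mean(vv[idx])
    max(abs(vc - uc)) / max(abs(uc))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("reciprocity holds to solver precision on the coarse models", {
  for (fw in list(disk16_forward(),
                  solve_forward(tank_coarse(), rep(1, nrow(tank_coarse()$elements)),
                                proto_tank()))) {
    V <- fw$electrode_potentials
    p <- if (ncol(V) == 16) proto16() else proto_tank()
    mp <- p$measurements
    asym <- 0
    for (a in seq_len(nrow(mp))) for (b in seq_len(nrow(mp))) {
      vab <- V[mp[b, 1], a] - V[mp[b, 2], a]
      vba <- V[mp[a, 1], b] - V[mp[a, 2], b]
      asym <- max(asym, abs(vab - vba) / max(abs(vab), 1e-12))
    }
    expect_lt(asym, 1e-6)
  }
})

test_that("electrode potentials obey the zero-sum gauge and scale laws", {
  fw <- disk16_forward()
  expect_lt(max(abs(colSums(fw$electrode_potentials))), 1e-10)
  # exact scaling invariance: sigma -> a sigma with z -> z / a gives V / a
  m <- disk16_coarse()
  m2 <- m; m2$contact_impedance <- m$contact_impedance / 2
  fw2 <- solve_forward(m2, rep(2, nrow(m$elements)), proto16())
  expect_equal(fw2$frame$values, fw$frame$values / 2, tolerance = 1e-9)
  # with fixed contact impedance the scaling is approximate but close
  fw3 <- solve_forward(m, rep(2, nrow(m$elements)), proto16())
  expect_equal(fw3$frame$values, fw$frame$values / 2, tolerance = 0.05)
})

test_that("degenerate conductivities are rejected", {
  m <- disk16_coarse()
  expect_error(solve_forward(m, rep(0, nrow(m$elements)), proto16()), "positive")
  expect_error(solve_forward(m, rep(1, 5), proto16()), "length")
})

test_that("adjoint Jacobian matches central finite differences", {
  m <- disk16_coarse()                            # 160 elements
  p <- proto16()
  J <- disk16_jacobian()
  set.seed(42)
  sig0 <- rep(1, nrow(m$elements))
  for (e in sample(nrow(m$elements), 6)) {
    h <- 1e-6
    s1 <- sig0; s1[e] <- 1 + h
    s2 <- sig0; s2[e] <- 1 - h
    fd <- (solve_forward(m, s1, p)$frame$values -
           solve_forward(m, s2, p)$frame$values) / (2 * h)
    expect_lt(max(abs(fd - J$matrix[, e])) / max(abs(fd)), 1e-3)
  }
})

test_that("Jacobian respects the rotational symmetry of the disk", {
  # the structured disk mesh is invariant under rotation by one electrode
  # pitch, so the sensitivity of injection i+1 is the rotated sensitivity of
  # injection i, element-for-element
  m <- disk16_coarse()
  J <- disk16_jacobian()
  cen <- eit3d:::element_centroids(m)
  rows <- eit3d:::protocol_rows(proto16())
  sens_of <- function(inj) colSums(abs(J$matrix[rows$injection == inj, , drop = FALSE]))
  a <- 2 * pi / 16
  rot <- cbind(cos(a) * cen[, 1] - sin(a) * cen[, 2],
               sin(a) * cen[, 1] + cos(a) * cen[, 2])
  partner <- vapply(seq_len(nrow(cen)), function(e) {
    which.min((cen[, 1] - rot[e, 1])^2 + (cen[, 2] - rot[e, 2])^2)
  }, integer(1))
  s1 <- sens_of(1); s2 <- sens_of(2)
  expect_lt(max(abs(s2[partner] - s1)) / max(s1), 1e-8)
})

test_that("first-order Taylor consistency of the Jacobian", {
  m <- disk16_coarse()
  p <- proto16()
  J <- disk16_jacobian()
  set.seed(9)
  delta <- rnorm(nrow(m$elements), 0, 0.002)
  dv <- solve_forward(m, 1 + delta, p)$frame$values - disk16_forward()$frame$values
  pred <- as.numeric(J$matrix %*% delta)
  expect_lt(sqrt(sum((dv - pred)^2)) / sqrt(sum(dv^2)), 0.02)
})
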