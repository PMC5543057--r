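# Mesh generation: tank and contour models, electrode patches, scene
# painting, contour perturbation, and the mesh-format round-trips.

test_that("tank models carry the right electrode layout and valid elements", {
  cases <- list(c(4, 8), c(1, 16), c(2, 4))
  for (cs in cases) {
    m <- build_tank_model(0.15, 0.3, cs[1], cs[2], "coarse")
    expect_length(m$electrodes, cs[1] * cs[2])
    expect_true(all(m$volumes > 0))
    expect_silent(eit3d:::validate_fe_model(m))
    # rings equally spaced in height (patch centroids near nominal centres),
    # electrodes equally spaced in angle
    zc <- vapply(m$electrodes, function(f) {
      mean(eit3d:::face_centroids(m$nodes, f)[, 3])
    }, numeric(1))
    nominal <- 0.3 * (2 * (ceiling(seq_along(zc) / cs[2])) - 1) / (2 * cs[1])
    expect_lt(max(abs(zc - nominal)), 0.5 * 0.3 / cs[1])
    ac <- vapply(m$electrodes, function(f) {
      ce <- colMeans(eit3d:::face_centroids(m$nodes, f))
      atan2(ce[2], ce[1]) %% (2 * pi)
    }, numeric(1))
    nominal_a <- 2 * pi * ((seq_along(ac) - 1) %% cs[2]) / cs[2]
    dd <- abs(((ac - nominal_a + pi) %% (2 * pi)) - pi)
    expect_lt(max(dd), 0.6 * pi / cs[2])
  }
})

test_that("fine density has at least 4x the elements of coarse", {
  mc <- tank_coarse()
  mf <- build_tank_model(0.15, 0.3, 4, 8, "fine")
  expect_gte(nrow(mf$elements), 4 * nrow(mc$elements))
  expect_gte(nrow(disk16_fine()$elements), 4 * nrow(disk16_coarse()$elements))
})

test_that("order-2 request substitutes a flagged refined mesh", {
  expect_message(m2 <- build_tank_model(0.15, 0.3, 1, 8, "coarse", order = 2L),
                 "order-1")
  m1 <- build_tank_model(0.15, 0.3, 1, 8, "coarse")
  expect_gte(nrow(m2$elements), 4 * nrow(m1$elements))
})

test_that("degenerate-circle contour model reduces to a disk", {
  m <- disk16_coarse()
  expect_length(m$electrodes, 16)
  bnd <- eit3d:::boundary_faces(m)
  r <- sqrt(m$nodes[unique(as.integer(bnd)), 1]^2 +
            m$nodes[unique(as.integer(bnd)), 2]^2)
  expect_lt(max(abs(r - 1)), 1e-9)
})

test_that("thorax contour boundary follows the generating curve at both densities", {
  co <- thorax_coefficients()
  for (dens in c("coarse", "fine")) {
    m <- build_contour_model(co, 16, dens)
    bnd <- unique(as.integer(eit3d:::boundary_faces(m)))
    th <- atan2(m$nodes[bnd, 2], m$nodes[bnd, 1])
    r <- sqrt(m$nodes[bnd, 1]^2 + m$nodes[bnd, 2]^2)
    expect_lt(max(abs(r - eit3d:::fourier_radius(co, th))), 1e-9)
  }
  # coarse and fine boundaries stay within mesh tolerance of each other
  mc <- build_contour_model(co, 16, "coarse")
  mf <- build_contour_model(co, 16, "fine")
  bc <- mc$nodes[unique(as.integer(eit3d:::boundary_faces(mc))), 1:2]
  bf <- mf$nodes[unique(as.integer(eit3d:::boundary_faces(mf))), 1:2]
  hausdorff <- max(apply(bc, 1, function(p) {
    min(sqrt((bf[, 1] - p[1])^2 + (bf[, 2] - p[2])^2))
  }))
  expect_lt(hausdorff, 0.05 * max(co$a[1], 1e-9))
})

test_that("self-intersecting contours are rejected", {
  bad <- list(a = c(0.1, 0, 0.2, rep(0, 6)), b = rep(0, 8))  # rho goes negative
  expect_error(build_contour_model(bad, 16, "coarse"), "self-intersect")
})

test_that("perturb_contour respects the weight bound and its seed", {
  co <- thorax_coefficients()
  expect_identical(perturb_contour(co, 0, seed = 1), co)
  p1 <- perturb_contour(co, 0.1, seed = 7)
  p2 <- perturb_contour(co, 0.1, seed = 7)
  p3 <- perturb_contour(co, 0.1, seed = 8)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  nz <- co$a != 0
  ratio <- p1$a[nz] / co$a[nz]
  expect_true(all(ratio >= 0.9 & ratio <= 1.1))
  # weight_bound -> 0 converges to the identity
  for (w in c(1e-2, 1e-4)) {
    pw <- perturb_contour(co, w, seed = 3)
    expect_lt(max(abs(pw$a - co$a)), w * max(abs(co$a)) + 1e-12)
  }
})

test_that("paint_scene paints targets by centroid and validates containment", {
  m <- disk16_fine()
  expect_equal(paint_scene(m, scene_spec(2))$values, rep(2, nrow(m$elements)))
  # area fraction close to the dense-sampling oracle
  sc <- scene_spec(1, list(list(shape = "circular-cylinder", center = c(0.2, -0.1, 0),
                                semi_axes = 0.3, conductivity = 0.1)))
  img <- paint_scene(m, sc)
  frac <- sum(m$volumes[img$values == 0.1]) / sum(m$volumes)
  th <- runif(20000, 0, 2 * pi); rr <- sqrt(runif(20000))
  oracle <- mean((rr * cos(th) - 0.2)^2 + (rr * sin(th) + 0.1)^2 <= 0.3^2)
  expect_lt(abs(frac - oracle), 0.02)
  # two disjoint cylinders -> two connected components
  sc2 <- scene_spec(1, list(
    list(shape = "circular-cylinder", center = c(0.45, 0, 0), semi_axes = 0.2,
         conductivity = 0.1),
    list(shape = "circular-cylinder", center = c(-0.45, 0, 0), semi_axes = 0.2,
         conductivity = 0.1)))
  img2 <- paint_scene(m, sc2)
  comp <- eit3d:::element_components(m, img2$values == 0.1)
  expect_equal(max(comp), 2L)
  # target outside the boundary errors with the target index
  bad <- scene_spec(1, list(list(shape = "circular-cylinder", center = c(0.9, 0, 0),
                                 semi_axes = 0.3, conductivity = 0.5)))
  expect_error(paint_scene(m, bad), "target 1")
})

test_that("paint_scene is idempotent and element-order independent", {
  m <- disk16_coarse()
  sc <- scene_spec(1, list(list(shape = "elliptical-cylinder", center = c(0.1, 0.2, 0),
                                semi_axes = c(0.3, 0.2), conductivity = 0.4)))
  a <- paint_scene(m, sc)
  expect_identical(a$values, paint_scene(m, sc)$values)
  perm <- sample(nrow(m$elements))
  mp <- m
  mp$elements <- m$elements[perm, , drop = FALSE]
  mp$volumes <- m$volumes[perm]
  expect_identical(paint_scene(mp, sc)$values, a$values[perm])
})

test_that("MSH and VTK files round-trip a model (0-based on disk)", {
  m <- disk16_coarse()
  for (fmt in c("msh", "vtk")) {
    path <- tempfile(fileext = paste0(".", fmt))
    if (fmt == "msh") write_msh(m, path) else write_vtk(m, path)
    # files use 0-based indices
    txt <- readLines(path)
    if (fmt == "msh") expect_true(any(grepl("^0 ", txt)))
    m2 <- if (fmt == "msh") read_msh(path) else read_vtk(path)
    expect_equal(m2$nodes, m$nodes, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(m2$elements, m$elements, ignore_attr = TRUE)
    expect_length(m2$electrodes, length(m$electrodes))
    expect_equal(m2$electrodes[[3]], m$electrodes[[3]], ignore_attr = TRUE)
    unlink(path)
  }
})

test_that("fe_model enforces the validity invariants", {
  m <- disk16_coarse()
  bad_el <- m$elements
  bad_el[1, 2] <- bad_el[1, 1]                  # repeated node
  expect_error(fe_model(m$nodes, bad_el, m$electrodes), "repeated")
  bad_el2 <- m$elements
  bad_el2[1, 1] <- nrow(m$nodes) + 5L           # out of range
  expect_error(fe_model(m$nodes, bad_el2, m$electrodes), "range")
  interior_edge <- matrix(m$elements[1, 1:2], 1)  # not a boundary face
  expect_error(fe_model(m$nodes, m$elements,
                        c(m$electrodes[-1], list(interior_edge))),
               "boundary")
})
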