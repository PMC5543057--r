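# Raster figures of merit: PE, |dRES|, SD, per-target matching.

test_that("rasterisation reproduces uniform images and disc areas", {
  m <- disk16_fine()
  u <- eit_image(rep(2, nrow(m$elements)), "element", m)
  r <- rasterize(u, m, G = 64)
  expect_true(all(abs(r$grid[r$inside_mask] - 2) < 1e-12))
  # indicator of a disc: rasterised area within a pixel ring of the truth
  sc <- scene_spec(1, list(list(shape = "circular-cylinder", center = c(0.25, -0.1, 0),
                                semi_axes = 0.3, conductivity = 2)))
  img <- paint_scene(m, sc)
  r2 <- rasterize(img, m, G = 96)
  area <- sum(r2$grid >= 1.5, na.rm = TRUE) * r2$pixel_size^2
  true_area <- pi * 0.3^2
  ring <- 2 * pi * 0.3 * 2 * r2$pixel_size       # one pixel ring each way
  expect_lt(abs(area - true_area), ring + 0.01)
  expect_error(rasterize(u, tank_coarse(), height = 99), "outside")
})

test_that("quarter-amplitude set follows its definition", {
  r <- disc_raster(c(0, 0), 0.001, G = 32)       # single-pixel impulse
  r$grid[16, 16] <- 1
  qs <- quarter_amplitude_set(r)
  expect_equal(sum(qs), sum(r$grid >= 0.25, na.rm = TRUE))
  # binary image: all nonzero pixels are in the set
  rb <- disc_raster(c(0.2, 0.1), 0.4, G = 64)
  expect_equal(sum(quarter_amplitude_set(rb)), sum(rb$grid == 1, na.rm = TRUE))
  # Gaussian blob: set area grows with blob width
  areas <- vapply(c(0.1, 0.2, 0.3), function(w) {
    g <- disc_raster(c(0, 0), 0.1, G = 64)
    px <- outer(g$y, g$x, function(y, x) exp(-(x^2 + y^2) / (2 * w^2)))
    g$grid <- px; g$grid[!g$inside_mask] <- NA
    sum(quarter_amplitude_set(g))
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
  # all-zero raster flags an empty set
  z <- disc_raster(c(0, 0), 0.2, G = 32, value = 0)
  expect_true(attr(quarter_amplitude_set(z), "flagged"))
})

test_that("identity, translation and dilation give the closed-form metrics", {
  truth <- disc_raster(c(-0.2, 0.1), 0.25, G = 64)
  idm <- compute_metrics(truth, truth)
  expect_equal(idm$per_target$pe, 0)
  expect_equal(idm$dres, 0)
  expect_equal(idm$sd, 0, tolerance = 1e-12)
  # translation by d pixels: PE = d * pixel_size / radius * 100, |dRES| = 0
  G <- 64; d <- 4
  shifted <- truth
  shifted$grid <- cbind(matrix(0, G, d), truth$grid[, 1:(G - d)])
  shifted$grid[!shifted$inside_mask] <- NA
  shifted$grid[is.na(shifted$grid) & shifted$inside_mask] <- 0
  tm <- compute_metrics(shifted, truth)
  expect_equal(tm$per_target$pe, 100 * d * truth$pixel_size / 1, tolerance = 1e-6)
  expect_equal(tm$dres, 0)
  # dilation to twice the area: |dRES| = (sqrt(2) - 1) * RES(true) * 100
  dil <- disc_raster(c(-0.2, 0.1), 0.25 * sqrt(2), G = 64)
  dm <- compute_metrics(dil, truth)
  res_true <- sqrt(sum(quarter_amplitude_set(truth)) / sum(truth$inside_mask))
  expect_equal(dm$dres, 100 * (sqrt(2) - 1) * res_true, tolerance = 0.06 * 100 * res_true)
  expect_lt(dm$per_target$pe, 1)
})

test_that("metrics are invariant to positive scaling of the reconstruction", {
  set.seed(12)
  truth <- disc_raster(c(0.1, -0.3), 0.2, G = 48)
  recon <- disc_raster(c(0.15, -0.25), 0.3, G = 48, value = 0.4)
  m1 <- compute_metrics(recon, truth)
  recon2 <- recon; recon2$grid <- recon$grid * 137
  m2 <- compute_metrics(recon2, truth)
  expect_equal(m1$per_target$pe, m2$per_target$pe)
  expect_equal(m1$dres, m2$dres)
  expect_equal(m1$sd, m2$sd)
})

test_that("two-target matching assigns components to their nearest truth", {
  set.seed(13)
  for (rep in 1:10) {
    c1 <- c(runif(1, -0.6, -0.2), runif(1, -0.3, 0.3))
    c2 <- c(runif(1, 0.2, 0.6), runif(1, -0.3, 0.3))
    truth <- disc_raster(c1, 0.15, G = 64)
    t2 <- disc_raster(c2, 0.15, G = 64)
    truth$grid <- pmax(truth$grid, t2$grid)
    jitter <- function(c) c + runif(2, -0.05, 0.05)
    r1 <- disc_raster(jitter(c1), 0.17, G = 64)
    r2 <- disc_raster(jitter(c2), 0.13, G = 64)
    recon <- r1; recon$grid <- pmax(r1$grid, r2$grid)
    mt <- compute_metrics(recon, truth)
    expect_equal(nrow(mt$per_target), 2)
    expect_true(all(is.finite(mt$per_target$pe)))
    # brute-force matching oracle: each component CoG nearer its own target
    expect_true(all(mt$per_target$pe < 100 * 0.1))
  }
})

test_that("a missing reconstructed target is flagged, not fabricated", {
  truth <- disc_raster(c(-0.4, 0), 0.15, G = 64)
  t2 <- disc_raster(c(0.4, 0), 0.15, G = 64)
  truth$grid <- pmax(truth$grid, t2$grid)
  recon <- disc_raster(c(-0.4, 0), 0.15, G = 64)  # only one target found
  mt <- compute_metrics(recon, truth)
  expect_true(any(is.na(mt$per_target$pe)))
  expect_equal(mt$flagged, which(is.na(mt$per_target$pe)))
})

test_that("metrics are stable under grid refinement on a painted fixture", {
  m <- disk16_fine()
  sc <- scene_spec(1, list(list(shape = "circular-cylinder", center = c(0.3, 0.2, 0),
                                semi_axes = 0.22, conductivity = 0.2)))
  img <- element_to_node(eit3d:::scene_on_model(m, sc), m)
  mets <- lapply(c(64L, 128L), function(G) {
    r <- rasterize(img, m, G = G)
    compute_metrics(r, r)  # identity at each grid: PE/dres exact zeros
  })
  expect_equal(mets[[1]]$per_target$pe, mets[[2]]$per_target$pe)
  # and a dilated pair converges across grids within one percentage point
  vals <- vapply(c(64L, 128L), function(G) {
    truth <- disc_raster(c(0.1, 0), 0.2, G = G)
    dil <- disc_raster(c(0.1, 0), 0.2 * sqrt(2), G = G)
    compute_metrics(dil, truth)$dres
  }, numeric(1))
  expect_lt(abs(vals[1] - vals[2]), 1)
})

test_that("metrics reports serialise to CSV and JSON", {
  truth <- disc_raster(c(0, 0.2), 0.2, G = 48)
  mt <- compute_metrics(truth, truth)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_metrics(mt, csv); write_metrics(mt, js)
  expect_equal(utils::read.csv(csv)$pe, 0)
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$dres, 0)
  unlink(c(csv, js))
})
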