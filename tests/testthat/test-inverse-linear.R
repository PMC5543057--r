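# One-step GN matrix, NOSER prior, and element/node interpolation.

test_that("p = 0 reduces to the ridge oracle on a random system", {
  set.seed(7)
  J <- matrix(rnorm(200), 10, 20)
  lam <- 0.3
  M <- build_gn_matrix(J, lam, p = 0)
  oracle <- solve(crossprod(J) + lam^2 * diag(20), t(J))
  expect_lt(max(abs(M$matrix - oracle)), 1e-8)
})

test_that("regularisation limits behave", {
  set.seed(8)
  J <- matrix(rnorm(300), 30, 10)
  expect_lt(norm(build_gn_matrix(J, 1e6)$matrix, "F"), 1e-6)
  # recovery of the top right-singular direction improves as lambda drops
  d <- svd(J)$v[, 1]
  errs <- vapply(c(1e-1, 1e-2, 1e-3), function(l) {
    M <- build_gn_matrix(J, l, 0.5)
    sqrt(sum((M$matrix %*% (J %*% d) - d)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
})

test_that("reconstruction is a linear, deterministic matrix product", {
  J <- disk16_jacobian()
  M <- build_gn_matrix(J, choose_lambda(J))
  p <- proto16()
  z <- eit_frame(rep(0, p$frame_length), p, kind = "difference")
  expect_equal(reconstruct_gn(M, z)$values, rep(0, ncol(J$matrix)))
  set.seed(9)
  v1 <- rnorm(p$frame_length); v2 <- rnorm(p$frame_length)
  f1 <- eit_frame(v1, p, "difference"); f2 <- eit_frame(v2, p, "difference")
  lin <- reconstruct_gn(M, eit_frame(2 * v1 - 3 * v2, p, "difference"))$values
  expect_equal(lin, 2 * reconstruct_gn(M, f1)$values - 3 * reconstruct_gn(M, f2)$values,
               tolerance = 1e-10)
  expect_error(reconstruct_gn(M, eit_frame(v1, p, "absolute")), "difference")
})

test_that("reconstruction commutes with element permutations", {
  m <- disk16_coarse()
  p <- proto16()
  J <- disk16_jacobian()
  lam <- choose_lambda(J)
  set.seed(10)
  dv <- eit_frame(rnorm(p$frame_length, 0, 1e-5), p, "difference")
  x <- reconstruct_gn(build_gn_matrix(J, lam), dv)$values
  perm <- sample(ncol(J$matrix))
  Jp <- J; Jp$matrix <- J$matrix[, perm]
  xp <- reconstruct_gn(build_gn_matrix(Jp, lam), dv)$values
  expect_equal(xp, x[perm], tolerance = 1e-8)
})

test_that("noise-figure calibration hits its target and is monotone", {
  J <- disk16_jacobian()
  lam <- choose_lambda(J, nf_target = 0.5)
  # recompute the noise figure at the chosen lambda
  nf_at <- function(l) {
    Jm <- J$matrix
    d <- colSums(Jm^2)
    v_t <- as.numeric(Jm %*% as.numeric(d >= quantile(d, 0.9)))
    M <- solve(crossprod(Jm) + diag(l^2 * d^0.5, ncol(Jm)), t(Jm))
    (mean(abs(v_t))) / (mean(abs(M %*% v_t)) / sqrt(mean(rowSums(M^2))))
  }
  expect_lt(abs(nf_at(lam) - 0.5), 0.02)
  expect_gt(nf_at(lam / 10), nf_at(lam))          # lighter reg -> higher NF
})

test_that("element/node interpolation preserves constants and local values", {
  m <- disk16_coarse()
  u <- eit_image(rep(3.5, nrow(m$elements)), "element", m)
  un <- element_to_node(u, m)
  expect_equal(un$values, rep(3.5, nrow(m$nodes)))
  # node interior to a single-valued region gets exactly that value
  img <- eit_image(ifelse(eit3d:::element_centroids(m)[, 1] > 0, 2, 5), "element", m)
  nodal <- element_to_node(img, m)
  deep <- which(m$nodes[, 1] > 0.4)               # away from the x = 0 interface
  expect_true(all(nodal$values[deep] == 2))
  # round trip node -> element -> node on a smooth field stays within
  # mesh-size x gradient
  f <- eit_image(sin(2 * m$nodes[, 1]) + m$nodes[, 2], "node", m)
  back <- element_to_node(node_to_element(f, m), m)
  h <- max(sqrt(m$volumes))                        # ~ element size
  expect_lt(max(abs(back$values - f$values)), 3 * h)
})
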